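#' Classifier backends
#'
#' Thin wrappers over established implementations (MASS, e1071, class,
#' nnet, ranger, xgboost, base glm) exposing a uniform
#' fit/score interface to the evaluation harness. Scores are continuous
#' and oriented so that larger means more PNES-like (class 1); only their
#' ranks and a calibrated threshold are ever used downstream.
#'
#' @param name One of `"knn"`, `"nb"`, `"lda"`, `"lr"`, `"svm"`, `"rf"`,
#'   `"mlp"`, `"xgb"`.
#' @return `classifier_names()`: supported names. `classifier_grid()`:
#'   list of tunable parameter combinations (possibly of length 1).
#' @export
classifier_names <- function() c("knn", "nb", "lda", "lr", "svm", "rf", "mlp", "xgb")

#' @rdname classifier_names
#' @export
classifier_grid <- function(name) {
  name <- match.arg(name, classifier_names())
  switch(name,
    knn = list(list(k = 3), list(k = 5), list(k = 9)),
    svm = list(list(cost = 0.1), list(cost = 1), list(cost = 10)),
    xgb = list(list(nrounds = 50, max_depth = 2, eta = 0.1),
               list(nrounds = 50, max_depth = 4, eta = 0.1)),
    mlp = list(list(size = 5, decay = 0.1)),
    rf = list(list(num_trees = 100)),
    list(list()))
}

#' Fit a classifier on a feature matrix
#'
#' @param name Backend name, see [classifier_names()].
#' @param x Numeric feature matrix (rows = epochs).
#' @param y Integer labels, 0/1.
#' @param params Parameter list (one element of [classifier_grid()]).
#' @param seed Integer seed consumed by stochastic backends (RF, MLP) so
#'   fits are reproducible.
#' @return A fitted model wrapper for [predict_scores()].
#' @export
fit_classifier <- function(name, x, y, params = list(), seed = 1L) {
  name <- match.arg(name, classifier_names())
  y <- as.integer(y)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  fit <- switch(name,
    knn = list(train = x, cl = factor(y, levels = c(0, 1)),
               k = params$k %||% 5),
    nb = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    lda = suppressWarnings(MASS::lda(x, grouping = factor(y, levels = c(0, 1)))),
    lr = suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                         family = stats::binomial())),
    svm = e1071::svm(x, factor(y, levels = c(0, 1)),
                     kernel = "radial", cost = params$cost %||% 1,
                     scale = FALSE),
    rf = ranger::ranger(y = factor(y, levels = c(0, 1)), x = as.data.frame(x),
                        probability = TRUE,
                        num.trees = params$num_trees %||% 100,
                        seed = seed, num.threads = 1),
    mlp = { set.seed(seed)
            nnet::nnet(x, y, size = params$size %||% 5,
                       decay = params$decay %||% 0.1, maxit = 200,
                       entropy = TRUE, trace = FALSE) },
    xgb = xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                           nrounds = params$nrounds %||% 50,
                           max_depth = params$max_depth %||% 3,
                           learning_rate = params$eta %||% 0.1,
                           nthreads = 1, seed = seed, verbosity = 0))
  structure(list(name = name, fit = fit, ncol = ncol(x)), class = "szy_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score new epochs with a fitted classifier
#'
#' @param model A fitted wrapper from [fit_classifier()].
#' @param x Feature matrix with the training column count.
#' @return Numeric scores, larger = more class-1-like.
#' @export
predict_scores <- function(model, x) {
  stopifnot(ncol(x) == model$ncol)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  fit <- model$fit
  switch(model$name,
    knn = { pr <- class::knn(fit$train, x, fit$cl, k = fit$k, prob = TRUE)
            wp <- attr(pr, "prob")
            ifelse(pr == "1", wp, 1 - wp) },
    nb = stats::predict(fit, x, type = "raw")[, "1"],
    lda = stats::predict(fit, x)$posterior[, "1"],
    lr = { cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
           as.numeric(stats::plogis(cbind(1, x) %*% cf)) },
    svm = { dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                       "decision.values")
            s <- as.numeric(dv)
            if (grepl("^0/1", colnames(dv)[1])) -s else s },
    rf = stats::predict(fit, as.data.frame(x), num.threads = 1)$predictions[, "1"],
    mlp = as.numeric(stats::predict(fit, x)),
    xgb = as.numeric(stats::predict(fit, x, type = "response")))
}
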