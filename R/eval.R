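#' Epoch-level AUC by the rank formula
#'
#' Area under the ROC curve computed from rank sums (midrank ties), the
#' probability that a random class-1 score exceeds a random class-0
#' score.
#'
#' @param scores Numeric scores.
#' @param labels Integer 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(rank(scores)[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject; training rows never share a subject with the
#' held-out rows.
#'
#' @param design An `entropy_design` with at least 3 subjects and both
#'   classes.
#' @return Character vector of held-out subject ids (one per fold).
#' @export
loso_folds <- function(design) {
  sids <- unique(design$subject)
  if (length(sids) < 3) stop("need at least 3 subjects")
  if (length(unique(design$label)) < 2) stop("single-class cohort")
  sids
}

#' Train-only z-scoring
#'
#' Column means and SDs are estimated on the training rows only and the
#' identical transform is applied to the held-out rows; a zero-SD channel
#' gets SD 1 with a warning.
#'
#' @param train,test Numeric matrices with matching columns.
#' @return List with `train`, `test`, `center`, `scale`.
#' @export
zscore_train_apply <- function(train, test) {
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  if (any(scale == 0)) {
    warning("zero-SD channel(s); scale set to 1")
    scale[scale == 0] <- 1
  }
  list(train = sweep(sweep(train, 2, center), 2, scale, "/"),
       test = sweep(sweep(test, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Subject-level random undersampling
#'
#' Equalises subjects per class by removing whole subjects from the
#' majority class (never individual epochs, preserving within-subject
#' structure). Deterministic given `seed`; an already balanced design is
#' returned unchanged.
#'
#' @param design An `entropy_design` with both classes.
#' @param seed Integer seed.
#' @return The undersampled `entropy_design`.
#' @export
undersample_subjects <- function(design, seed = 1L) {
  sids <- unique(design$subject)
  lab <- vapply(sids, function(s) design$label[match(s, design$subject)],
                integer(1))
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 == n0) return(design)
  set.seed(seed)
  maj <- if (n1 > n0) 1L else 0L
  keep_maj <- sample(sids[lab == maj], min(n1, n0))
  keep <- design$subject %in% c(sids[lab != maj], keep_maj)
  design$x <- design$x[keep, , drop = FALSE]
  design$label <- design$label[keep]
  design$subject <- design$subject[keep]
  design
}

# stratified assignment of subjects to k inner folds, deterministic given seed
.inner_fold_ids <- function(design, k = 5, seed = 1L) {
  sids <- unique(design$subject)
  lab <- vapply(sids, function(s) design$label[match(s, design$subject)],
                integer(1))
  set.seed(seed)
  fold <- integer(length(sids))
  for (cl in unique(lab)) {
    idx <- sample(which(lab == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  stats::setNames(fold, sids)
}

#' Inner cross-validated AUC
#'
#' Mean epoch-level AUC over k subject-grouped, class-stratified inner
#' validation folds (no subject straddles folds). Folds whose validation
#' part has one class are skipped with a warning.
#'
#' @param design Training `entropy_design` (already standardised).
#' @param classifier Backend name.
#' @param params Classifier parameters.
#' @param k Inner folds.
#' @param seed Integer seed (fold assignment + stochastic fits).
#' @return Mean AUC.
#' @export
inner_cv_auc <- function(design, classifier, params = list(), k = 5,
                         seed = 1L) {
  folds <- .inner_fold_ids(design, k, seed)
  aucs <- vapply(seq_len(k), function(f) {
    va <- design$subject %in% names(folds)[folds == f]
    if (length(unique(design$label[va])) < 2) {
      warning("inner fold with a single class skipped")
      return(NA_real_)
    }
    mod <- fit_classifier(classifier, design$x[!va, , drop = FALSE],
                          design$label[!va], params, seed = seed + f)
    auc_score(predict_scores(mod, design$x[va, , drop = FALSE]),
              design$label[va])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Permutation channel importance over inner folds
#'
#' For each inner fold a model is fitted on the inner-training subjects
#' and scored on the validation subjects; each channel is then permuted
#' within the validation fold `repeats` times and the mean AUC drop
#' (baseline minus permuted) is that fold's importance for the channel.
#'
#' @inheritParams inner_cv_auc
#' @param repeats Permutations per channel per fold.
#' @return Folds-by-channels matrix of importances (rows for skipped
#'   one-class folds are `NA`).
#' @export
permutation_importance <- function(design, classifier, params = list(),
                                   repeats = 10, k = 5, seed = 1L) {
  folds <- .inner_fold_ids(design, k, seed)
  nc <- ncol(design$x)
  imp <- matrix(NA_real_, k, nc, dimnames = list(NULL, design$channels))
  for (f in seq_len(k)) {
    va <- design$subject %in% names(folds)[folds == f]
    if (length(unique(design$label[va])) < 2) next
    mod <- fit_classifier(classifier, design$x[!va, , drop = FALSE],
                          design$label[!va], params, seed = seed + f)
    xv <- design$x[va, , drop = FALSE]
    yv <- design$label[va]
    base <- auc_score(predict_scores(mod, xv), yv)
    set.seed(seed * 17 + f)
    for (ch in seq_len(nc)) {
      drops <- vapply(seq_len(repeats), function(rp) {
        xp <- xv
        xp[, ch] <- xv[sample(nrow(xv)), ch]
        base - auc_score(predict_scores(mod, xp), yv)
      }, numeric(1))
      imp[f, ch] <- mean(drops)
    }
  }
  imp
}

#' Retain consistently important channels
#'
#' Keeps channels whose permutation importance is strictly positive in
#' every inner fold (`rule = "every_fold"`), or whose overall mean is
#' positive (`rule = "overall"`). If no channel qualifies, falls back to
#' the single best channel by overall mean with a warning.
#'
#' @param importances Folds-by-channels matrix from
#'   [permutation_importance()].
#' @param rule Retention rule.
#' @return Character vector of retained channel labels.
#' @export
select_channels <- function(importances, rule = c("every_fold", "overall")) {
  rule <- match.arg(rule)
  ok <- !apply(importances, 1, function(r) all(is.na(r)))
  imp <- importances[ok, , drop = FALSE]
  keep <- if (rule == "every_fold") apply(imp > 0, 2, all)
          else colMeans(imp) > 0
  if (!any(keep)) {
    warning("no consistently important channel; falling back to top-1")
    keep <- seq_len(ncol(imp)) == which.max(colMeans(imp))
  }
  colnames(importances)[keep]
}

#' Calibrate a decision threshold by the geometric mean of sensitivity
#' and specificity
#'
#' Scans candidate thresholds (midpoints between adjacent distinct
#' scores, plus outer candidates) and returns the one maximising
#' `sqrt(sensitivity * specificity)` of the rule `score >= threshold`;
#' ties are broken toward the candidate nearest 0.5. One-class labels
#' return 0.5 with a warning.
#'
#' @param scores Validation scores.
#' @param labels Integer 0/1 labels.
#' @return The calibrated threshold (attribute `gmean` carries the
#'   achieved value).
#' @export
calibrate_threshold <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    warning("one-class labels; threshold defaults to 0.5")
    return(structure(0.5, gmean = NA_real_))
  }
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  gm <- vapply(cand, function(t) {
    pred <- as.integer(scores >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    sqrt(sens * spec)
  }, numeric(1))
  best <- which(gm >= max(gm) - 1e-12)
  thr <- cand[best[which.min(abs(cand[best] - 0.5))]]
  structure(thr, gmean = max(gm))
}

#' Hard-vote aggregation of epoch predictions
#'
#' Majority vote over a subject's epoch labels; an exact tie (possible
#' with 12 epochs) is broken by comparing the subject's mean calibrated
#' score against the threshold.
#'
#' @param epoch_labels Integer 0/1 epoch predictions.
#' @param mean_score Mean calibrated score (used only on ties).
#' @param threshold Calibrated threshold (used only on ties).
#' @return Subject-level label, 0 or 1.
#' @export
hard_vote <- function(epoch_labels, mean_score = 0.5, threshold = 0.5) {
  stopifnot(length(epoch_labels) >= 1)
  n1 <- sum(epoch_labels == 1); n0 <- sum(epoch_labels == 0)
  if (n1 > n0) return(1L)
  if (n0 > n1) return(0L)
  as.integer(mean_score >= threshold)
}

#' Pooled confusion metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy
#' (their mean) and F1 `2TP/(2TP+FP+FN)`, in percent, from confusion
#' counts pooled over all LOSO folds. Ratios with zero denominators are
#' `NA`.
#'
#' @param tp,tn,fp,fn Pooled confusion counts.
#' @return Named list of percentages.
#' @export
pooled_metrics <- function(tp, tn, fp, fn) {
  div <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(c(sens, spec)),
       f1 = div(2 * tp, 2 * tp + fp + fn))
}

#' Run one leave-one-subject-out fold
#'
#' The full leakage-free per-fold protocol: subject-level undersampling
#' of the training cohort, train-only z-scoring, optional entropy-config
#' selection across candidate designs by inner AUC, nested hyperparameter
#' tuning, permutation-importance channel selection, threshold
#' calibration on inner out-of-sample scores, final refit, epoch
#' prediction for the held-out subject and a hard vote. Every
#' training-derived artifact is a pure function of the training rows.
#'
#' @param designs An `entropy_design` or a named list of candidate
#'   designs (same subjects/labels, different entropy parameters); with
#'   more than one, the fold picks the config with the best mean inner
#'   AUC for this classifier.
#' @param test_subject Held-out subject id.
#' @param classifier Backend name.
#' @param seed Fold seed (derive from the experiment seed and fold
#'   index).
#' @param inner_k Inner folds for tuning/importance/calibration.
#' @param perm_repeats Permutations per channel per fold.
#' @param select_rule Channel-retention rule, see [select_channels()].
#' @param undersample,tune,select Stage switches.
#' @return A `fold_outcome` list: artifacts (`center`, `scale`,
#'   `train_subjects`, `entropy_config`, `tuned_params`,
#'   `retained_channels`, `threshold`), `epoch_scores`, `epoch_labels`,
#'   `subject_prediction`, `truth`, `confusion_increment`.
#' @export
loso_fold <- function(designs, test_subject, classifier = "lda", seed = 1L,
                      inner_k = 5, perm_repeats = 10,
                      select_rule = "every_fold", undersample = TRUE,
                      tune = TRUE, select = TRUE) {
  if (inherits(designs, "entropy_design")) designs <- list(default = designs)
  d1 <- designs[[1]]
  stopifnot(test_subject %in% d1$subject)
  split_one <- function(d) {
    tr_rows <- d$subject != test_subject
    tr <- d
    tr$x <- d$x[tr_rows, , drop = FALSE]
    tr$label <- d$label[tr_rows]; tr$subject <- d$subject[tr_rows]
    list(train = tr, test_x = d$x[!tr_rows, , drop = FALSE])
  }
  splits <- lapply(designs, split_one)

  # undersample once at subject level; the same subject set for every
  # candidate design so configs are compared on identical cohorts
  tr1 <- splits[[1]]$train
  if (undersample) tr1 <- undersample_subjects(tr1, seed)
  keep_subjects <- unique(tr1$subject)

  prep <- lapply(splits, function(sp) {
    tr <- sp$train
    kr <- tr$subject %in% keep_subjects
    tr$x <- tr$x[kr, , drop = FALSE]
    tr$label <- tr$label[kr]; tr$subject <- tr$subject[kr]
    zs <- zscore_train_apply(tr$x, sp$test_x)
    tr$x <- zs$train
    list(train = tr, test_x = zs$test, center = zs$center, scale = zs$scale)
  })

  # entropy-config selection inside the training fold
  cfg <- 1L
  if (length(prep) > 1) {
    cfg_auc <- vapply(prep, function(p)
      inner_cv_auc(p$train, classifier, list(), inner_k, seed), numeric(1))
    cfg <- which.max(cfg_auc)
  }
  train <- prep[[cfg]]$train
  test_x <- prep[[cfg]]$test_x

  params <- list()
  if (tune) {
    grid <- classifier_grid(classifier)
    if (length(grid) > 1) {
      auc <- vapply(grid, function(g)
        inner_cv_auc(train, classifier, g, inner_k, seed), numeric(1))
      params <- grid[[which.max(auc)]]
    } else params <- grid[[1]]
  }

  channels <- train$channels
  if (select) {
    imp <- suppressWarnings(
      permutation_importance(train, classifier, params, perm_repeats,
                             inner_k, seed))
    channels <- select_channels(imp, select_rule)
  }
  ch_idx <- match(channels, train$channels)

  # inner out-of-sample scores on the selected channels for calibration
  folds <- .inner_fold_ids(train, inner_k, seed)
  val_scores <- numeric(0); val_labels <- integer(0)
  for (f in seq_len(inner_k)) {
    va <- train$subject %in% names(folds)[folds == f]
    if (length(unique(train$label[va])) < 2 || !any(va)) next
    mod <- fit_classifier(classifier, train$x[!va, ch_idx, drop = FALSE],
                          train$label[!va], params, seed = seed + f)
    val_scores <- c(val_scores,
                    predict_scores(mod, train$x[va, ch_idx, drop = FALSE]))
    val_labels <- c(val_labels, train$label[va])
  }
  threshold <- calibrate_threshold(val_scores, val_labels)

  final <- fit_classifier(classifier, train$x[, ch_idx, drop = FALSE],
                          train$label, params, seed = seed)
  scores <- predict_scores(final, test_x[, ch_idx, drop = FALSE])
  epoch_labels <- as.integer(scores >= as.numeric(threshold))
  pred <- hard_vote(epoch_labels, mean(scores), as.numeric(threshold))
  truth <- d1$label[match(test_subject, d1$subject)]
  ci <- if (truth == 1 && pred == 1) "TP" else if (truth == 0 && pred == 0)
    "TN" else if (truth == 0 && pred == 1) "FP" else "FN"
  structure(list(
    held_out_subject = test_subject,
    center = prep[[cfg]]$center, scale = prep[[cfg]]$scale,
    train_subjects = sort(keep_subjects),
    entropy_config = names(designs)[cfg],
    tuned_params = params, retained_channels = channels,
    threshold = as.numeric(threshold),
    epoch_scores = scores, epoch_labels = epoch_labels,
    subject_prediction = pred, truth = truth, confusion_increment = ci
  ), class = "fold_outcome")
}

#' Leave-one-subject-out evaluation of one classifier
#'
#' Runs [loso_fold()] for every subject and pools the confusion counts
#' (Equations for sensitivity, specificity, balanced accuracy and F1 are
#' applied to the pooled counts).
#'
#' @inheritParams loso_fold
#' @param designs An `entropy_design` or named list of candidate designs.
#' @param seed Experiment seed; fold seeds are derived as
#'   `seed * 1000 + fold`.
#' @param ... Passed to [loso_fold()].
#' @return A `loso_result`: list with `classifier`, `measure`, `state`,
#'   `confusion` (TP/TN/FP/FN), `metrics`, `folds`.
#' @export
loso_evaluate <- function(designs, classifier = "lda", seed = 1L, ...) {
  d1 <- if (inherits(designs, "entropy_design")) designs else designs[[1]]
  subjects <- loso_folds(d1)
  folds <- lapply(seq_along(subjects), function(i)
    loso_fold(designs, subjects[i], classifier,
              seed = seed * 1000L + i, ...))
  ci <- vapply(folds, function(f) f$confusion_increment, character(1))
  conf <- c(TP = sum(ci == "TP"), TN = sum(ci == "TN"),
            FP = sum(ci == "FP"), FN = sum(ci == "FN"))
  structure(list(classifier = classifier, measure = d1$measure,
                 state = d1$state, confusion = conf,
                 metrics = pooled_metrics(conf["TP"], conf["TN"],
                                          conf["FP"], conf["FN"]),
                 folds = folds),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<loso_result> %s on %s/%s: BA %.2f%%, F1 %.2f%%, sens %.2f%%, spec %.2f%% (TP %d TN %d FP %d FN %d)\n",
    x$classifier, x$measure, x$state, m$balanced_accuracy, m$f1,
    m$sensitivity, m$specificity,
    x$confusion["TP"], x$confusion["TN"], x$confusion["FP"],
    x$confusion["FN"]))
  invisible(x)
}

#' Run a multi-classifier experiment on one design
#'
#' Evaluates each classifier with the full LOSO harness and tabulates
#' pooled metrics. Deterministic given `seed`.
#'
#' @inheritParams loso_evaluate
#' @param classifiers Character vector of backend names.
#' @return data.frame: measure, state, classifier, balanced_accuracy,
#'   f1, sensitivity, specificity.
#' @export
run_experiment <- function(designs, classifiers = c("lda", "lr"), seed = 1L,
                           ...) {
  rows <- lapply(classifiers, function(cl) {
    res <- loso_evaluate(designs, cl, seed, ...)
    data.frame(measure = res$measure, state = res$state, classifier = cl,
               balanced_accuracy = res$metrics$balanced_accuracy,
               f1 = res$metrics$f1, sensitivity = res$metrics$sensitivity,
               specificity = res$metrics$specificity)
  })
  do.call(rbind, rows)
}
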