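# LOSO harness: folds, scaling, undersampling, AUC, importance, channel
# retention, calibration, voting, pooled metrics and the leakage
# guarantees.

test_that("LOSO folds keep train and test subjects disjoint", {
  d <- synthetic_design(ns = 5, seed = 50)
  folds <- loso_folds(d)
  expect_length(folds, 10)
  for (s in folds) {
    tr <- unique(d$subject[d$subject != s])
    expect_false(s %in% tr)
  }
  one_class <- d
  one_class$label[] <- 1L
  expect_error(loso_folds(one_class), "single-class")
  expect_error(loso_folds(synthetic_design(ns = 1)), "at least 3")
})

test_that("train-only z-scoring standardises and never touches test rows", {
  tr <- cbind(c(1, 2, 3), c(10, 20, 30))
  te <- cbind(c(2, 4), c(0, 5))
  zs <- zscore_train_apply(tr, te)
  expect_equal(zs$train[, 1], c(-1, 0, 1))
  expect_equal(colMeans(zs$train), c(0, 0))
  expect_equal(apply(zs$train, 2, sd), c(1, 1))
  # params are a function of the training rows only
  zs2 <- zscore_train_apply(tr, te * 100 + 7)
  expect_identical(zs$center, zs2$center)
  expect_identical(zs$scale, zs2$scale)
  # round trip recovers the originals
  back <- sweep(sweep(zs$test, 2, zs$scale, "*"), 2, zs$center, "+")
  expect_equal(back, te)
  expect_warning(zscore_train_apply(cbind(c(1, 1, 1)), cbind(2)), "zero-SD")
})

test_that("undersampling removes whole majority-class subjects only", {
  d <- synthetic_design(ns = 9, seed = 51) # start balanced 9/9
  keep <- unique(d$subject)[1:15]          # 9 PNES / 6 ES
  d$x <- d$x[d$subject %in% keep, ]
  d$label <- d$label[d$subject %in% keep]
  d$subject <- d$subject[d$subject %in% keep]
  u <- undersample_subjects(d, seed = 3)
  lab <- vapply(unique(u$subject), function(s) u$label[match(s, u$subject)],
                integer(1))
  expect_equal(sum(lab == 1), 6)
  expect_equal(sum(lab == 0), 6)
  # every retained subject keeps its intact 12-row block
  for (s in unique(u$subject))
    expect_equal(u$x[u$subject == s, ], d$x[d$subject == s, ])
  # deterministic given seed; balanced input unchanged
  expect_identical(undersample_subjects(d, seed = 3)$subject, u$subject)
  bal <- synthetic_design(ns = 4, seed = 52)
  expect_identical(undersample_subjects(bal, 1), bal)
})

test_that("rank AUC agrees with exhaustive pair counting and is monotone-invariant", {
  set.seed(53)
  for (i in 1:20) {
    s <- rnorm(30)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), o_auc(s, y), tolerance = 1e-12)
    expect_equal(auc_score(plogis(3 * s + 1), y), auc_score(s, y))
  }
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_true(is.na(auc_score(1:4, rep(1, 4))))
})

test_that("inner CV is subject-grouped and near chance on null features", {
  d <- synthetic_design(ns = 10, seed = 54)
  a <- inner_cv_auc(d, "lda", k = 5, seed = 1)
  expect_gt(a, 0.3); expect_lt(a, 0.7)
  # perfectly separable feature gives AUC 1
  d2 <- synthetic_design(ns = 6, shift = 50, seed = 55)
  expect_equal(inner_cv_auc(d2, "lda", k = 3, seed = 1), 1, tolerance = 1e-9)
})

test_that("permutation importance singles out the informative channel", {
  d <- synthetic_design(ns = 10, shift = 2.5, on = "O1",
                        channels = c("O1", "O2", "Cz", "Pz"), seed = 56)
  imp <- permutation_importance(d, "lda", repeats = 10, k = 5, seed = 2)
  expect_equal(dim(imp), c(5, 4))
  means <- colMeans(imp, na.rm = TRUE)
  expect_equal(names(which.max(means)), "O1")
  expect_true(all(imp[, "O1"] > 0))
  # uninformative channels hover near zero
  expect_lt(max(abs(means[c("O2", "Cz", "Pz")])), means["O1"] / 2)
  sel <- select_channels(imp)
  expect_true("O1" %in% sel)
  # all-noise importances fall back to top-1 with a warning
  d0 <- synthetic_design(ns = 8, channels = c("O1", "O2", "Cz"), seed = 57)
  imp0 <- permutation_importance(d0, "lda", repeats = 5, k = 4, seed = 3)
  expect_warning(sel0 <- select_channels(imp0), "top-1")
  expect_length(sel0, 1)
})

test_that("threshold calibration maximises the sensitivity-specificity gmean", {
  # perfectly separated: gmean 1, threshold inside the gap
  thr <- calibrate_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_gt(as.numeric(thr), 0.2); expect_lt(as.numeric(thr), 0.8)
  expect_equal(attr(thr, "gmean"), 1)
  set.seed(58)
  y <- rbinom(60, 1, 0.5)
  s <- y + rnorm(60, sd = 0.2)
  thr2 <- calibrate_threshold(s, y)
  expect_gt(attr(thr2, "gmean"), 0.9)
  # argmax property over an exhaustive candidate sweep
  gm <- function(t) {
    pred <- as.integer(s >= t)
    sqrt(sum(pred & y) / sum(y) * sum(!pred & !y) / sum(!y))
  }
  for (t in seq(min(s) - 0.1, max(s) + 0.1, length.out = 200))
    expect_gte(attr(thr2, "gmean") + 1e-12, gm(t))
  expect_warning(t1 <- calibrate_threshold(1:5, rep(1, 5)), "one-class")
  expect_equal(as.numeric(t1), 0.5)
})

test_that("hard voting follows the majority with a documented tie rule", {
  expect_equal(hard_vote(c(rep(1, 8), rep(0, 4))), 1L)
  expect_equal(hard_vote(rep(0, 12)), 0L)
  expect_equal(hard_vote(rep(c(0, 1), 6), mean_score = 0.7, threshold = 0.5), 1L)
  expect_equal(hard_vote(rep(c(0, 1), 6), mean_score = 0.3, threshold = 0.5), 0L)
})

test_that("pooled metrics reproduce the headline arithmetic", {
  # printed sensitivity/specificity pair -> printed balanced accuracy
  expect_equal(mean(c(74.47, 70.37)), 72.42)
  m <- pooled_metrics(10, 10, 0, 0)
  expect_equal(unlist(m), c(sensitivity = 100, specificity = 100,
                            balanced_accuracy = 100, f1 = 100))
  m2 <- pooled_metrics(3, 4, 2, 1)
  expect_equal(m2$sensitivity, 75)
  expect_equal(m2$specificity, 200 / 3, tolerance = 1e-10)
  expect_equal(m2$balanced_accuracy, (75 + 200 / 3) / 2, tolerance = 1e-10)
  expect_equal(m2$f1, 200 / 3, tolerance = 1e-10)
  expect_true(is.na(pooled_metrics(0, 5, 0, 0)$sensitivity))
})

test_that("every classifier backend fits, scores and separates a clear signal", {
  set.seed(59)
  n <- 120
  x <- matrix(rnorm(n * 3), n, 3)
  y <- as.integer(x[, 1] + 0.3 * rnorm(n) > 0)
  xt <- matrix(rnorm(40 * 3), 40, 3)
  yt <- as.integer(xt[, 1] > 0)
  for (cl in classifier_names()) {
    mod <- fit_classifier(cl, x, y, classifier_grid(cl)[[1]], seed = 4)
    sc <- predict_scores(mod, xt)
    expect_length(sc, 40)
    expect_gt(auc_score(sc, yt), 0.85)
  }
})

test_that("a LOSO fold's training artifacts ignore the held-out subject entirely", {
  d <- synthetic_design(ns = 6, shift = 1, on = c("O1", "O2"),
                        channels = c("O1", "O2", "Cz", "Pz", "T5"), seed = 60)
  test_subject <- unique(d$subject)[2]
  run <- function(design) suppressWarnings(
    loso_fold(design, test_subject, "lda", seed = 11, inner_k = 3,
              perm_repeats = 5))
  f1 <- run(d)
  # perturb the held-out subject's raw values wildly
  d2 <- d
  d2$x[d2$subject == test_subject, ] <-
    d2$x[d2$subject == test_subject, ] * 50 + 1000
  f2 <- run(d2)
  expect_identical(f1$center, f2$center)
  expect_identical(f1$scale, f2$scale)
  expect_identical(f1$train_subjects, f2$train_subjects)
  expect_identical(f1$tuned_params, f2$tuned_params)
  expect_identical(f1$retained_channels, f2$retained_channels)
  expect_identical(f1$threshold, f2$threshold)
  # and the fold is reproducible
  f3 <- run(d)
  expect_identical(f1$epoch_scores, f3$epoch_scores)
  expect_identical(f1$subject_prediction, f3$subject_prediction)
})

test_that("subject epochs never straddle the inner folds", {
  d <- synthetic_design(ns = 8, seed = 61)
  folds <- seizentropy:::.inner_fold_ids(d, 5, 1)
  expect_setequal(names(folds), unique(d$subject))
  # stratification: each fold's subjects include both classes where possible
  for (f in 1:5) {
    subj <- names(folds)[folds == f]
    expect_gt(length(subj), 0)
  }
})

test_that("the LOSO harness is near chance on exchangeable data and strong on signal", {
  d0 <- synthetic_design(ns = 8, channels = c("O1", "O2", "Cz", "Pz"),
                         seed = 62)
  r0 <- suppressWarnings(loso_evaluate(d0, "lda", seed = 5, inner_k = 3,
                                       perm_repeats = 5))
  expect_equal(sum(r0$confusion), 16)
  expect_gte(r0$metrics$balanced_accuracy, 20)
  expect_lte(r0$metrics$balanced_accuracy, 80)
  d1 <- synthetic_design(ns = 8, shift = 2, on = c("O1", "O2"),
                         channels = c("O1", "O2", "Cz", "Pz"), seed = 63)
  r1 <- suppressWarnings(loso_evaluate(d1, "lda", seed = 5, inner_k = 3,
                                       perm_repeats = 5))
  expect_gte(r1$metrics$balanced_accuracy, 90)
  # deterministic re-run yields the identical table
  r1b <- suppressWarnings(loso_evaluate(d1, "lda", seed = 5, inner_k = 3,
                                        perm_repeats = 5))
  expect_identical(r1$confusion, r1b$confusion)
  expect_identical(r1$metrics, r1b$metrics)
})

test_that("entropy-config selection inside the fold picks the informative design", {
  base <- synthetic_design(ns = 6, channels = c("O1", "O2", "Cz"), seed = 64)
  good <- synthetic_design(ns = 6, shift = 3, on = c("O1", "O2"),
                           channels = c("O1", "O2", "Cz"), seed = 64)
  f <- suppressWarnings(
    loso_fold(list(noise = base, signal = good), unique(base$subject)[1],
              "lda", seed = 9, inner_k = 3, perm_repeats = 3))
  expect_equal(f$entropy_config, "signal")
})
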