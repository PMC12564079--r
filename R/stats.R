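#' Per-subject summaries of a design matrix
#'
#' Reduces a stacked design to one value per subject (global scope: mean
#' over epochs and channels) or one value per subject and channel
#' (channel scope: mean over epochs). Undefined (`NA`) entries are
#' excluded from the means with a message reporting how many.
#'
#' @param design An `entropy_design`.
#' @param scope `"global"` or `"channel"`.
#' @return List with `subject`, `label` (one per subject) and `values`
#'   (vector for global scope, subjects-by-channels matrix for channel
#'   scope).
#' @export
subject_summary <- function(design, scope = c("global", "channel")) {
  scope <- match.arg(scope)
  n_na <- sum(is.na(design$x))
  if (n_na > 0)
    message(n_na, " undefined entropy value(s) excluded from summaries")
  sids <- unique(design$subject)
  label <- vapply(sids, function(s)
    design$label[match(s, design$subject)], integer(1))
  if (scope == "global") {
    values <- vapply(sids, function(s)
      mean(design$x[design$subject == s, ], na.rm = TRUE), numeric(1))
  } else {
    values <- t(vapply(sids, function(s)
      colMeans(design$x[design$subject == s, , drop = FALSE], na.rm = TRUE),
      numeric(ncol(design$x))))
    colnames(values) <- design$channels
  }
  list(subject = sids, label = label, values = values)
}

#' Mann-Whitney U test with z-score and rank-biserial effect size
#'
#' Rank-sum test of two independent samples: `U` counts pairs in which
#' the first sample exceeds the second (midrank ties count 1/2), `z` is
#' the normal approximation with tie-corrected variance and continuity
#' correction, `p` is two-sided, and `r_rb = 1 - 2U/(n1*n2)` is the
#' rank-biserial correlation (positive when the first group is
#' stochastically smaller).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return One-row data.frame with `U`, `z`, `p`, `r_rb`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (stats::sd(c(a, b)) == 0)
    return(data.frame(U = U, z = 0, p = 1, r_rb = 0, n1 = n1, n2 = n2))
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  mu <- n1 * n2 / 2
  cc <- if (U != mu) 0.5 * sign(U - mu) else 0
  z <- (U - mu - cc) / sqrt(sigma2)
  data.frame(U = U, z = z, p = min(1, 2 * stats::pnorm(-abs(z))),
             r_rb = 1 - 2 * U / (n1 * n2), n1 = n1, n2 = n2)
}

#' Rank-biserial correlation from a U statistic
#'
#' @param U Mann-Whitney U, `0 <= U <= n1*n2`.
#' @param n1,n2 Group sizes.
#' @return `1 - 2U/(n1*n2)`, in `[-1, 1]`.
#' @export
rank_biserial <- function(U, n1, n2) {
  stopifnot(U >= 0, U <= n1 * n2)
  1 - 2 * U / (n1 * n2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; never decreases a
#' p-value and is idempotent.
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Kolmogorov-Smirnov normality screen
#'
#' Two-sided KS test of the sample against a normal with the sample mean
#' and SD. A zero-variance sample rejects normality by convention
#' (returns p = 0).
#'
#' @param values Numeric vector, length >= 5.
#' @return p-value.
#' @export
ks_normality <- function(values) {
  stopifnot(length(values) >= 5)
  if (stats::sd(values) == 0) return(0)
  suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' via [stats::t.test()]. Two constant groups with equal means return
#' `t = 0, p = 1`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p = if (eq) 1 else 0))
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson chi-square with 1 degree of freedom via [stats::chisq.test()].
#' Yates continuity correction is applied by default (the convention that
#' reproduces printed sex-distribution statistics for small tables); set
#' `yates = FALSE` for the uncorrected statistic.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param yates Apply the continuity correction?
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab, yates = TRUE) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  if (any(ct$expected <= 0)) stop("non-positive expected count")
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Per-channel topographic group comparison
#'
#' Subject-level channel means are compared between groups channel by
#' channel with [mann_whitney_u()]; q-values are BH-adjusted across the
#' channels of this one measure/state. The `z` column is the topographic
#' map (positive z: first group, PNES, larger).
#'
#' @param design An `entropy_design`.
#' @return data.frame keyed by channel label with `U`, `z`, `p`, `q`,
#'   `r_rb`.
#' @export
topographic_z <- function(design) {
  ss <- subject_summary(design, "channel")
  rows <- lapply(seq_along(design$channels), function(ch) {
    mw <- mann_whitney_u(ss$values[ss$label == 1, ch],
                         ss$values[ss$label == 0, ch])
    cbind(data.frame(channel = design$channels[ch]), mw)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[, c("channel", "U", "z", "p", "q", "r_rb")]
}

#' Global group comparison of a design matrix
#'
#' Subject-level global means compared between PNES and ES:
#' KS normality per group, Mann-Whitney U with z and rank-biserial r, and
#' group medians.
#'
#' @param design An `entropy_design`.
#' @return One-row data.frame.
#' @export
global_stats <- function(design) {
  ss <- subject_summary(design, "global")
  a <- ss$values[ss$label == 1]; b <- ss$values[ss$label == 0]
  mw <- mann_whitney_u(a, b)
  ks <- function(v) if (length(v) >= 5) ks_normality(v) else NA_real_
  cbind(data.frame(measure = design$measure, state = design$state,
                   median_pnes = stats::median(a), median_es = stats::median(b),
                   ks_p_pnes = ks(a), ks_p_es = ks(b)),
        mw)
}
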