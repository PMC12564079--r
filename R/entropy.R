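#' @useDynLib seizentropy, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sample entropy
#'
#' Negative log conditional probability that two templates of length `m`
#' that match within tolerance `r` (Chebyshev distance, self-matches
#' excluded) still match when extended by one sample:
#' `-ln(A/B)` with `B` the m-length and `A` the (m+1)-length match counts.
#' `r` is given as a fraction of the epoch's standard deviation and
#' converted internally. With zero matches at either length the estimate
#' is undefined and `NA` is returned (never a fabricated finite value);
#' a zero-variance signal returns 0 (all templates identical).
#'
#' @param x Numeric signal, `length(x) > m + 1`.
#' @param m Embedding dimension.
#' @param r Tolerance as a fraction of `sd(x)`.
#' @return Entropy in nats, or `NA_real_` when undefined.
#' @export
samp_en <- function(x, m = 2, r = 0.2) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  stopifnot(length(x) > m + 1)
  cnt <- sampen_counts(as.numeric(x), as.integer(m), r * s)
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[2] / cnt[1])
}

#' Fuzzy entropy
#'
#' Like sample entropy but with baseline-centred templates and a fuzzy
#' membership `exp(-(d/r)^n)` in place of the hard match rule, so the
#' estimate is finite for any non-constant signal:
#' `ln(phi_m) - ln(phi_{m+1})` where `phi` are mean pairwise memberships.
#'
#' @inheritParams samp_en
#' @param n Fuzzy power controlling membership sharpness.
#' @return Entropy in nats.
#' @export
fuzzy_en <- function(x, m = 2, r = 0.2, n = 2) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  stopifnot(length(x) > m + 1)
  phi <- fuzzyen_phis(as.numeric(x), as.integer(m), r * s, n)
  log(phi[1]) - log(phi[2])
}

# ordinal pattern ids for windows of length m, delay tau; ties broken by
# order of occurrence (stable sort)
.ordinal_patterns <- function(x, m, tau) {
  n_pat <- length(x) - (m - 1) * tau
  vapply(seq_len(n_pat), function(i) {
    w <- x[i + (0:(m - 1)) * tau]
    paste(order(w), collapse = ".")
  }, character(1))
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal patterns (local rank
#' orderings) of embedded windows, optionally normalised by `ln(m!)`.
#' Ties are broken by order of occurrence.
#'
#' @inheritParams samp_en
#' @param tau Embedding delay in samples.
#' @param normalise Divide by `ln(m!)`?
#' @return Entropy (dimensionless in `[0, 1]` when normalised).
#' @export
perm_en <- function(x, m = 3, tau = 1, normalise = TRUE) {
  stopifnot(length(x) >= m * tau + 1)
  p <- table(.ordinal_patterns(x, m, tau))
  p <- p / sum(p)
  H <- -sum(p * log(p))
  if (normalise) H / log(factorial(m)) else H
}

# normal-CDF symbolisation of a standardised signal into classes 1..c
.dispersion_symbols <- function(x, c) {
  y <- stats::pnorm((x - mean(x)) / stats::sd(x))
  pmin(pmax(ceiling(c * y), 1L), c)
}

.symbol_pattern_entropy <- function(z, m, tau, n_pat = NULL) {
  if (is.null(n_pat)) n_pat <- length(z) - (m - 1) * tau
  pat <- vapply(seq_len(n_pat), function(i)
    paste(z[i + (0:(m - 1)) * tau], collapse = "."), character(1))
  p <- table(pat) / n_pat
  -sum(p * log(p))
}

#' Dispersion entropy
#'
#' Samples are mapped to `c` classes by a normal-CDF transform of the
#' standardised signal followed by uniform quantisation; the Shannon
#' entropy of the resulting length-`m` dispersion-pattern distribution is
#' reported, normalised by `ln(c^m)`.
#'
#' @inheritParams perm_en
#' @param c Number of symbol classes.
#' @return Entropy (in `[0, 1]` when normalised).
#' @export
disp_en <- function(x, m = 2, c = 6, tau = 1, normalise = TRUE) {
  if (stats::sd(x) == 0) return(0)
  H <- .symbol_pattern_entropy(.dispersion_symbols(x, c), m, tau)
  if (normalise) H / log(c^m) else H
}

#' Conditional entropy
#'
#' Average uncertainty of the next symbol given the current length-(m-1)
#' state of the dispersion-symbolised sequence:
#' `H(patterns of length m) - H(patterns of length m - 1)`, in nats. The
#' (m-1)-pattern marginal is taken over the same window positions as the
#' m-patterns, so the difference equals the conditional next-symbol
#' entropy exactly and is bounded by `[0, ln(c)]`.
#'
#' @inheritParams disp_en
#' @return Entropy in nats, in `[0, ln(c)]`.
#' @export
cond_en <- function(x, m = 2, c = 6) {
  stopifnot(m >= 2)
  if (stats::sd(x) == 0) return(0)
  z <- .dispersion_symbols(x, c)
  nw <- length(z) - m + 1
  .symbol_pattern_entropy(z, m, 1) -
    .symbol_pattern_entropy(z, m - 1, 1, n_pat = nw)
}

# analytic signal via FFT (Hilbert transform)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase entropy
#'
#' Shannon entropy of the instantaneous-phase histogram of the analytic
#' signal (Hilbert transform), with `k` equal sectors over `(-pi, pi]`,
#' normalised by `ln(k)`. Low values indicate phase locking; a uniform
#' phase distribution gives 1. A constant signal returns 0 by convention.
#'
#' @inheritParams samp_en
#' @param k Number of phase bins.
#' @return Entropy in `[0, 1]`.
#' @export
phas_en <- function(x, k = 8) {
  if (stats::sd(x) == 0) return(0)
  phi <- Arg(.analytic(x - mean(x)))
  bins <- pmin(pmax(ceiling((phi + pi) / (2 * pi / k)), 1L), k)
  p <- tabulate(bins, k)
  p <- p[p > 0] / length(bins)
  -sum(p * log(p)) / log(k)
}

# one-sided FFT power spectrum, DC excluded, normalised to sum 1
.spec_p <- function(x) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  p <- P[2:(floor(n / 2) + 1)]
  if (sum(p) == 0) return(NULL)
  p / sum(p)
}

#' Spectral entropy
#'
#' Shannon entropy of the normalised one-sided FFT power spectrum (DC
#' excluded), normalised by the log of the number of bins. A single
#' on-bin tone gives 0; white noise approaches 1.
#'
#' @inheritParams perm_en
#' @return Entropy (in `[0, 1]` when normalised).
#' @export
spec_en <- function(x, normalise = TRUE) {
  p <- .spec_p(x)
  if (is.null(p)) return(0)
  q <- p[p > 0]
  H <- -sum(q * log(q))
  if (normalise) H / log(length(p)) else H
}

#' Renyi entropy of a probability distribution
#'
#' `ln(sum(p^alpha)) / (1 - alpha)`; for `alpha = 2`, `-ln(sum(p^2))`.
#'
#' @param p Probability vector (normalised internally).
#' @param alpha Order, `alpha > 0`, `alpha != 1`.
#' @return Entropy in nats.
#' @export
renyi_entropy_p <- function(p, alpha = 2) {
  stopifnot(alpha > 0, alpha != 1)
  p <- p[p > 0] / sum(p)
  log(sum(p^alpha)) / (1 - alpha)
}

#' Renyi spectral entropy
#'
#' Renyi entropy of order `alpha` of the same normalised power-spectrum
#' distribution used by [spec_en()] (the spectral lineage of this
#' measure in the EEG literature; an amplitude-histogram variant is not
#' provided). Zero signal returns 0 by convention.
#'
#' @inheritParams samp_en
#' @param alpha Renyi order (default 2).
#' @return Entropy in nats.
#' @export
renyi_en <- function(x, alpha = 2) {
  p <- .spec_p(x)
  if (is.null(p)) return(0)
  renyi_entropy_p(p, alpha)
}

#' Morlet scalogram scale energies
#'
#' Continuous wavelet transform with an analytic Morlet wavelet (centre
#' frequency parameter `omega0`) at `n_scales` log-spaced scales whose
#' centre frequencies cover `[flo, fhi]` Hz; returns total energy per
#' scale.
#'
#' @inheritParams samp_en
#' @param fs Sampling rate, Hz.
#' @param n_scales Number of scales.
#' @param flo,fhi Frequency coverage, Hz.
#' @param omega0 Morlet centre-frequency parameter.
#' @return Named numeric vector of per-scale energies (names = centre
#'   frequency in Hz).
#' @export
morlet_energies <- function(x, fs = 128, n_scales = 16, flo = 0.5, fhi = 40,
                            omega0 = 6) {
  n <- length(x)
  freqs <- exp(seq(log(flo), log(fhi), length.out = n_scales))
  scales <- omega0 / (2 * pi * freqs) * fs # in samples
  nfft <- stats::nextn(2 * n, c(2, 3, 5))
  X <- stats::fft(c(x - mean(x), rep(0, nfft - n)))
  w <- 2 * pi * (seq_len(nfft) - 1) / nfft # rad/sample
  E <- numeric(n_scales)
  for (j in seq_len(n_scales)) {
    psi <- numeric(nfft)
    pos <- w > 0 & w <= pi
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * scales[j]) *
      exp(-(scales[j] * w[pos] - omega0)^2 / 2)
    W <- stats::fft(X * psi, inverse = TRUE) / nfft
    E[j] <- sum(Mod(W[seq_len(n)])^2)
  }
  stats::setNames(E, formatC(freqs, digits = 4, format = "g"))
}

#' Wavelet entropy
#'
#' Shannon entropy of the relative energies across Morlet wavelet scales
#' (see [morlet_energies()]), normalised by the log of the number of
#' scales: energy concentrated at one scale gives ~0, an even spread
#' gives ~1.
#'
#' @inheritParams morlet_energies
#' @return Entropy in `[0, 1]`.
#' @export
wave_en <- function(x, fs = 128, n_scales = 16, flo = 0.5, fhi = 40,
                    omega0 = 6) {
  if (stats::sd(x) == 0) return(0)
  E <- morlet_energies(x, fs, n_scales, flo, fhi, omega0)
  e <- E / sum(E)
  e <- e[e > 0]
  -sum(e * log(e)) / log(n_scales)
}

#' Entropy measure registry and parameters
#'
#' `entropy_measures()` lists the nine supported measures.
#' `entropy_params()` builds a validated parameter list for one measure;
#' unsupplied fields take the measure's defaults. `entropy_grid()` returns
#' the tuning grid searched during nested parameter selection, and
#' `default_entropy_params()` the per-state selected defaults used for all
#' headline analyses (phase entropy uses k = 16 for the preictal and
#' dynamic states and k = 8 interictally, outside its own tuning grid;
#' both are supported).
#'
#' @param measure Measure name.
#' @param m,r,n,tau,c,k,alpha,n_scales,flo,fhi,omega0 Optional parameter
#'   overrides; unsupplied ones keep the measure's defaults.
#' @param state For `default_entropy_params()`: `"preictal"`,
#'   `"interictal"` or `"dynamic"`.
#' @return A named list of parameters (or list of grids / defaults).
#' @export
entropy_measures <- function() {
  c("SampEn", "FuzzyEn", "PermEn", "DispEn", "CondEn",
    "PhasEn", "SpecEn", "RenEn", "WaveEn")
}

#' @rdname entropy_measures
#' @export
entropy_params <- function(measure, m = NULL, r = NULL, n = NULL, tau = NULL,
                           c = NULL, k = NULL, alpha = NULL, n_scales = NULL,
                           flo = NULL, fhi = NULL, omega0 = NULL) {
  measure <- match.arg(measure, entropy_measures())
  defaults <- switch(measure,
    SampEn = list(m = 2, r = 0.2),
    FuzzyEn = list(m = 2, r = 0.2, n = 2),
    PermEn = list(m = 3, tau = 1),
    DispEn = list(m = 2, c = 6, tau = 1),
    CondEn = list(m = 2, c = 6),
    PhasEn = list(k = 8),
    SpecEn = list(),
    RenEn = list(alpha = 2),
    WaveEn = list(n_scales = 16, flo = 0.5, fhi = 40, omega0 = 6))
  ov <- list(m = m, r = r, n = n, tau = tau, c = c, k = k, alpha = alpha,
             n_scales = n_scales, flo = flo, fhi = fhi, omega0 = omega0)
  ov <- ov[!vapply(ov, is.null, logical(1))]
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop("unknown parameter(s) for ", measure, ": ",
                        paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  p <- defaults
  if (!is.null(p$m) && p$m < 1) stop("m must be >= 1")
  if (!is.null(p$r) && p$r <= 0) stop("r must be > 0")
  if (!is.null(p$c) && p$c < 2) stop("c must be >= 2")
  if (!is.null(p$k) && p$k < 2) stop("k must be >= 2")
  if (!is.null(p$alpha) && (p$alpha <= 0 || p$alpha == 1))
    stop("alpha must be > 0 and != 1")
  c(list(measure = measure), p)
}

#' @rdname entropy_measures
#' @export
entropy_grid <- function(measure) {
  measure <- match.arg(measure, entropy_measures())
  switch(measure,
    SampEn = list(list(m = 1, r = 0.1), list(m = 1, r = 0.2),
                  list(m = 2, r = 0.1), list(m = 2, r = 0.2)),
    FuzzyEn = list(list(m = 1, r = 0.1), list(m = 1, r = 0.2),
                   list(m = 2, r = 0.1), list(m = 2, r = 0.2)),
    PermEn = list(list(m = 3), list(m = 4), list(m = 5)),
    DispEn = list(list(m = 2, c = 5), list(m = 2, c = 6), list(m = 2, c = 7)),
    CondEn = list(list(m = 2, c = 5), list(m = 2, c = 6), list(m = 2, c = 7)),
    PhasEn = list(list(k = 4), list(k = 8), list(k = 12)),
    list())
}

#' @rdname entropy_measures
#' @export
default_entropy_params <- function(state = c("preictal", "interictal", "dynamic")) {
  state <- match.arg(state)
  sel <- switch(state,
    preictal = list(SampEn = list(m = 1, r = 0.2), FuzzyEn = list(m = 2, r = 0.2),
                    PermEn = list(m = 3), DispEn = list(c = 7),
                    CondEn = list(c = 6), PhasEn = list(k = 16)),
    interictal = list(SampEn = list(m = 2, r = 0.2), FuzzyEn = list(m = 2, r = 0.2),
                      PermEn = list(m = 5), DispEn = list(c = 5),
                      CondEn = list(c = 6), PhasEn = list(k = 8)),
    dynamic = list(SampEn = list(m = 2, r = 0.1), FuzzyEn = list(m = 2, r = 0.1),
                   PermEn = list(m = 5), DispEn = list(c = 6),
                   CondEn = list(c = 6), PhasEn = list(k = 16)))
  out <- lapply(entropy_measures(), function(ms) {
    do.call(entropy_params, c(list(measure = ms), sel[[ms]]))
  })
  stats::setNames(out, entropy_measures())
}

#' Evaluate one entropy measure on one signal
#'
#' @param x Numeric signal (one channel of one epoch).
#' @param params Parameter list from [entropy_params()].
#' @param fs Sampling rate (used by WaveEn only).
#' @return Scalar entropy value (possibly `NA` for undefined SampEn).
#' @export
compute_entropy <- function(x, params, fs = 128) {
  switch(params$measure,
    SampEn = samp_en(x, params$m, params$r),
    FuzzyEn = fuzzy_en(x, params$m, params$r, params$n),
    PermEn = perm_en(x, params$m, params$tau),
    DispEn = disp_en(x, params$m, params$c, params$tau),
    CondEn = cond_en(x, params$m, params$c),
    PhasEn = phas_en(x, params$k),
    SpecEn = spec_en(x),
    RenEn = renyi_en(x, params$alpha),
    WaveEn = wave_en(x, fs, params$n_scales, params$flo, params$fhi,
                     params$omega0))
}

#' Per-epoch, per-channel entropy matrix
#'
#' Applies one estimator to every (epoch, channel) pair of an analysis
#' `epoch_set`, yielding the epochs-by-channels entropy matrix (12 x 17
#' for a full clean minute of 5-s epochs on the canonical montage).
#' Undefined estimates propagate as `NA`, never silently imputed.
#' Rejected epochs must have been removed by [reassemble()].
#'
#' @param es An `epoch_set` of analysis epochs.
#' @param params Parameter list from [entropy_params()].
#' @param epoch_len_s Required epoch length; a mismatching set is
#'   rejected.
#' @param subject_id,state Optional provenance attached as attributes.
#' @return An `entropy_matrix`: epochs x channels with attributes
#'   `measure`, `params`, `subject_id`, `state`, `channels`.
#' @export
entropy_matrix <- function(es, params, epoch_len_s = 5,
                           subject_id = NA_character_, state = NA_character_) {
  stopifnot(inherits(es, "epoch_set"))
  if (abs(es$epoch_len_s - epoch_len_s) > 1e-9)
    stop("epoch length ", es$epoch_len_s, " s; expected ", epoch_len_s, " s")
  ne <- dim(es$data)[1]; nc <- dim(es$data)[2]
  out <- matrix(NA_real_, ne, nc, dimnames = list(NULL, es$channels))
  for (e in seq_len(ne))
    for (ch in seq_len(nc))
      out[e, ch] <- compute_entropy(es$data[e, ch, ], params, es$fs)
  structure(out, class = c("entropy_matrix", "matrix"),
            measure = params$measure, params = params,
            subject_id = subject_id, state = state, channels = es$channels)
}
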