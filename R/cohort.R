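#' Specification of a synthetic two-group, two-state EEG cohort
#'
#' Defines the generative conditions for a cohort of PNES and ES subjects,
#' each contributing one interictal and one preictal multichannel recording.
#' Every channel is a mixture of 1/f^beta coloured noise and an alpha-band
#' sinusoid; the sinusoid mixing fraction is the complexity control knob
#' (more periodic signal means lower irregularity, hence lower entropy).
#' PNES preictal recordings have their mixing fraction raised by
#' `effect * spatial_profile[channel]`, emulating the preictal entropy drop
#' of the PNES group; ES subjects draw both states from the same law.
#'
#' @param n_pnes,n_es Subjects per group (both >= 1).
#' @param fs Sampling rate in Hz (default 128, the post-resampling rate;
#'   use 256 to exercise the resampler).
#' @param duration_s Seconds per state recording; `duration_s * fs` must be
#'   an integer (default 60).
#' @param channels Ordered subset of [eeg_channels()], no duplicates.
#' @param effect Dimensionless entropy-shift magnitude `delta >= 0` applied
#'   to PNES preictal mixing fractions.
#' @param spatial_profile Named per-channel weight in `[0, 1]` scaling
#'   `effect`; defaults to uniform.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param amplitude_sd Target signal standard deviation in microvolts.
#' @param mix_base,mix_sd Mean and SD of the subject-specific baseline
#'   mixing fraction (Beta-distributed); gives between-subject variance so
#'   leave-one-subject-out evaluation is meaningful.
#' @param seed Master integer seed; per-subject streams are derived by a
#'   fixed counter offset so generation is reproducible and order-free.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pnes = 46L, n_es = 28L, fs = 128, duration_s = 60,
                        channels = eeg_channels(), effect = 0,
                        spatial_profile = NULL, noise_exponent = 1,
                        amplitude_sd = 20, mix_base = 0.30, mix_sd = 0.06,
                        seed = 1L) {
  if (n_pnes < 1 || n_es < 1) stop("n_pnes and n_es must both be >= 1")
  n_samp <- duration_s * fs
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("duration_s * fs must be an integer sample count")
  if (anyDuplicated(channels)) stop("duplicate channel labels")
  if (effect < 0) stop("effect must be >= 0")
  if (is.null(spatial_profile)) spatial_profile <- spatial_profile_uniform(channels)
  if (is.null(names(spatial_profile)) || !all(channels %in% names(spatial_profile)))
    stop("spatial_profile must be named by channel label")
  spatial_profile <- spatial_profile[channels]
  if (any(spatial_profile < 0 | spatial_profile > 1))
    stop("spatial_profile weights must lie in [0, 1]")
  structure(list(
    n_pnes = as.integer(n_pnes), n_es = as.integer(n_es),
    fs = fs, duration_s = duration_s, channels = channels,
    effect = effect, spatial_profile = spatial_profile,
    noise_exponent = noise_exponent, amplitude_sd = amplitude_sd,
    mix_base = mix_base, mix_sd = mix_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# 1/f^beta coloured noise of length n, unit variance, via spectral shaping.
.colored_noise <- function(n, beta) {
  w <- stats::rnorm(n)
  if (beta == 0) return(w)
  f <- seq_len(n) - 1
  f[1] <- 1 # leave DC unscaled; removed by mean-centring below
  scale <- c(1, 1 / pmin(f[-1], n - f[-1])^(beta / 2))
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

# Beta draw parameterised by mean/sd, clipped away from the borders.
.rbeta_ms <- function(n, mean, sd) {
  v <- sd^2
  v <- min(v, mean * (1 - mean) * 0.95)
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Generate a synthetic cohort
#'
#' Draws two recordings (interictal, preictal) for every subject of a
#' [cohort_spec()]. Deterministic given `spec$seed`: subject `i` always
#' consumes the stream seeded by `seed + 7919 * i`, independent of
#' generation order.
#'
#' @param spec A [cohort_spec()].
#' @return List of `eeg_recording` objects, two per subject, PNES first.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_pnes + spec$n_es
  groups <- rep(c("PNES", "ES"), c(spec$n_pnes, spec$n_es))
  recs <- vector("list", 2L * n_total)
  for (i in seq_len(n_total)) {
    sid <- sprintf("S%03d", i)
    sub_seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    set.seed(sub_seed)
    p0 <- .rbeta_ms(1, spec$mix_base, spec$mix_sd)
    f_sin <- 10 + stats::rnorm(1, sd = 0.5) # alpha-band carrier, Hz
    for (s in c("interictal", "preictal")) {
      bump <- if (groups[i] == "PNES" && s == "preictal")
        spec$effect * spec$spatial_profile else rep(0, length(spec$channels))
      x <- .generate_recording_data(spec, p0, bump, f_sin)
      recs[[2L * (i - 1L) + if (s == "interictal") 1L else 2L]] <-
        new_recording(sid, groups[i], s, x, spec$fs, spec$channels)
    }
  }
  recs
}

.generate_recording_data <- function(spec, p0, bump, f_sin) {
  n <- as.integer(round(spec$duration_s * spec$fs))
  nc <- length(spec$channels)
  t <- (seq_len(n) - 1) / spec$fs
  x <- matrix(0, nc, n, dimnames = list(spec$channels, NULL))
  for (ch in seq_len(nc)) {
    p <- min(p0 + bump[ch], 0.95)
    noise <- .colored_noise(n, spec$noise_exponent)
    phi <- stats::runif(1, 0, 2 * pi)
    sine <- sqrt(2) * sin(2 * pi * f_sin * t + phi) # unit variance
    sig <- (1 - p) * noise + p * sine
    x[ch, ] <- spec$amplitude_sd * sig / stats::sd(sig)
  }
  x
}

#' Construct a single-subject recording
#'
#' @param subject_id Opaque subject identifier.
#' @param group `"PNES"` or `"ES"`.
#' @param state `"preictal"` or `"interictal"`.
#' @param data Channels-by-samples numeric matrix, microvolts.
#' @param fs Sampling rate, Hz.
#' @param channels Channel labels (defaults to `rownames(data)`).
#' @return An `eeg_recording`.
#' @export
new_recording <- function(subject_id, group, state, data, fs,
                          channels = rownames(data)) {
  stopifnot(is.matrix(data), all(is.finite(data)))
  group <- match.arg(group, c("PNES", "ES"))
  state <- match.arg(state, c("preictal", "interictal"))
  rownames(data) <- channels
  structure(list(subject_id = subject_id, group = group, state = state,
                 data = data, fs = fs, channels = channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s, %s] %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$group, x$state, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
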