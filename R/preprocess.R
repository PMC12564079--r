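#' Fixed-length epoch container
#'
#' @param data Numeric array `epochs x channels x samples`.
#' @param fs Sampling rate, Hz.
#' @param epoch_len_s Epoch length in seconds.
#' @param flags Per-epoch status, one of `"clean"`, `"repaired"`,
#'   `"rejected"`.
#' @param channels Channel labels.
#' @return An `epoch_set`.
#' @export
new_epoch_set <- function(data, fs, epoch_len_s, flags = NULL,
                          channels = dimnames(data)[[2]]) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(flags)) flags <- rep("clean", dim(data)[1])
  stopifnot(length(flags) == dim(data)[1],
            all(flags %in% c("clean", "repaired", "rejected")))
  structure(list(data = data, fs = fs, epoch_len_s = epoch_len_s,
                 flags = flags, channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples (%g s @ %g Hz); %s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$epoch_len_s, x$fs,
              paste(names(table(x$flags)), table(x$flags),
                    sep = ":", collapse = " ")))
  invisible(x)
}

# Frequency-domain resampling of one signal; up/down are coprime integers.
.fft_resample_1d <- function(x, up, down, pad) {
  n <- length(x)
  # reflect-pad both ends; extend right so padded length divides `down`
  extra <- (down - (n + 2L * pad) %% down) %% down
  left <- rev(x[2:(pad + 1)])
  right_n <- pad + extra
  right <- rev(x[(n - right_n):(n - 1)])
  xp <- c(left, x, right)
  L <- length(xp)
  L2 <- L * up / down
  X <- stats::fft(xp)
  Y <- complex(L2)
  half <- floor(L2 / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (L2 %% 2 == 0) Y[half + 1] <- complex(real = Re(X[half + 1]))
  if (half > 1) Y[(L2 - half + 2):L2] <- X[(L - half + 2):L]
  y <- Re(stats::fft(Y, inverse = TRUE)) / L
  start <- pad * up / down
  y[(start + 1):(start + round(n * up / down))]
}

#' Resample a recording
#'
#' Downsamples every channel to `target_fs` by frequency-domain
#' interpolation with reflective edge padding (default), or by polyphase
#' filtering via [signal::resample()]. Output sample count is
#' `round(samples * target_fs / fs)`. Upsampling is rejected.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target rate, Hz; must not exceed `rec$fs`.
#' @param method `"fft"` or `"polyphase"`.
#' @return A resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_fs, method = c("fft", "polyphase")) {
  method <- match.arg(method)
  if (target_fs <= 0 || rec$fs <= 0) stop("rates must be positive")
  if (target_fs > rec$fs) stop("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  up <- as.integer(round(target_fs)); down <- as.integer(round(rec$fs))
  if (abs(up - target_fs) > 1e-9 || abs(down - rec$fs) > 1e-9)
    stop("non-integer sampling rates are not supported")
  g <- .gcd(up, down); up <- up %/% g; down <- down %/% g
  n <- ncol(rec$data)
  if (method == "polyphase") {
    y <- t(apply(rec$data, 1, function(v) signal::resample(v, up, down)))
    y <- y[, seq_len(round(n * up / down)), drop = FALSE]
  } else {
    pad <- as.integer(min(n - 2L, down * ceiling(rec$fs / down)))
    y <- t(apply(rec$data, 1, .fft_resample_1d, up = up, down = down,
                 pad = pad))
  }
  new_recording(rec$subject_id, rec$group, rec$state, y, target_fs,
                rec$channels)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Design a zero-phase band-pass FIR filter
#'
#' Hamming-windowed linear-phase FIR whose length follows the 3.3/transition
#' rule: `odd(ceiling(3.3 / min_transition_bw_Hz * fs))`, with the lower
#' transition bandwidth `min(max(lo/4, 2), lo)` Hz and the upper
#' `min(max(hi/4, 2), fs/2 - hi)` Hz. The ideal response has -6 dB points
#' at `lo - tbw_lo/2` and `hi + tbw_hi/2`; at fs = 128 Hz and a
#' 0.5-40 Hz band this yields 845 taps. Apply with
#' [filter_zerophase()] (forwards-backwards) for zero phase.
#'
#' @param fs Sampling rate, Hz.
#' @param lo,hi Band edges, Hz, `0 < lo < hi < fs/2`.
#' @return Numeric vector of taps with attributes `fs`, `band`.
#' @export
design_bandpass <- function(fs, lo, hi) {
  if (!(lo > 0 && lo < hi && hi < fs / 2)) stop("degenerate band")
  tbw_lo <- min(max(lo * 0.25, 2), lo)
  tbw_hi <- min(max(hi * 0.25, 2), fs / 2 - hi)
  L <- ceiling(3.3 / min(tbw_lo, tbw_hi) * fs)
  if (L %% 2 == 0) L <- L + 1
  M <- (L - 1) / 2
  k <- seq_len(L) - 1 - M
  fc1 <- (lo - tbw_lo / 2) / fs
  fc2 <- (hi + tbw_hi / 2) / fs
  sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))
  h <- 2 * fc2 * sinc(2 * fc2 * k) - 2 * fc1 * sinc(2 * fc1 * k)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  h <- h * w
  # unity gain at the band's geometric centre
  f0 <- sqrt(lo * hi)
  h <- h / abs(sum(h * exp(-2i * pi * f0 / fs * k)))
  attr(h, "fs") <- fs
  attr(h, "band") <- c(lo, hi)
  h
}

#' Evaluate an FIR filter's amplitude response
#'
#' @param taps FIR taps from [design_bandpass()].
#' @param f Frequencies, Hz.
#' @param fs Sampling rate (defaults to the taps' `fs` attribute).
#' @param zero_phase If `TRUE`, the response of the forwards-backwards
#'   application, i.e. the squared magnitude.
#' @return Amplitude gain at each frequency.
#' @export
fir_response <- function(taps, f, fs = attr(taps, "fs"), zero_phase = TRUE) {
  k <- seq_along(taps) - 1
  H <- vapply(f, function(fi) abs(sum(taps * exp(-2i * pi * fi / fs * k))),
              numeric(1))
  if (zero_phase) H^2 else H
}

#' Apply an FIR filter forwards and backwards (zero phase)
#'
#' FFT-based convolution applied twice with reflective edge padding; the
#' group delay cancels, so a symmetric pulse keeps its peak index.
#'
#' @param x Numeric vector or channels-by-samples matrix.
#' @param taps FIR taps.
#' @return Filtered signal, same shape as `x`.
#' @export
filter_zerophase <- function(x, taps) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, filter_zerophase, taps = taps))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  L <- length(taps)
  pad <- min(n - 1, L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  np <- length(xp)
  nfft <- stats::nextn(np + 2 * (L - 1), c(2, 3, 5))
  H <- stats::fft(c(taps, rep(0, nfft - L)))
  y <- Re(stats::fft(stats::fft(c(xp, rep(0, nfft - np))) * H * H,
                     inverse = TRUE)) / nfft
  y[(pad + L):(pad + L - 1 + n)]
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' @param rec An `eeg_recording`.
#' @param epoch_len_s Epoch length, seconds; any residual tail is dropped.
#' @return An `epoch_set` with all flags `"clean"`.
#' @export
epoch_fixed <- function(rec, epoch_len_s = 1) {
  spe <- as.integer(round(epoch_len_s * rec$fs))
  n <- ncol(rec$data)
  if (n < spe) stop("recording shorter than one epoch")
  ne <- n %/% spe
  a <- array(0, c(ne, nrow(rec$data), spe),
             dimnames = list(NULL, rec$channels, NULL))
  for (e in seq_len(ne))
    a[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe)]
  new_epoch_set(a, rec$fs, epoch_len_s, channels = rec$channels)
}

#' Reject near-flat epochs
#'
#' An epoch is flagged rejected iff its peak-to-peak amplitude is below
#' `ptp_min` on every channel (i.e. the maximum across channels falls
#' short): a single flat channel is a channel problem, not an epoch
#' problem, so one live channel keeps the epoch.
#'
#' @param es An `epoch_set`.
#' @param ptp_min Minimum peak-to-peak amplitude, microvolts.
#' @return The `epoch_set` with sub-threshold epochs flagged `"rejected"`.
#' @export
drop_flat <- function(es, ptp_min = 1) {
  stopifnot(dim(es$data)[1] >= 1)
  ptp <- apply(es$data, c(1, 2), function(v) max(v) - min(v))
  flat <- apply(ptp, 1, max) < ptp_min
  es$flags[flat] <- "rejected"
  es
}

.epoch_ptp <- function(es) apply(es$data, c(1, 2), function(v) max(v) - min(v))

# deterministic interleaved fold assignment for epochs
.epoch_folds <- function(n, k) rep_len(seq_len(k), n)

# inverse-distance weights over the 3 nearest repairable channels
.repair_channel <- function(epoch_mat, bad_ch, good_idx, channels) {
  lay <- .channel_layout()
  if (channels[bad_ch] %in% rownames(lay) &&
      all(channels[good_idx] %in% rownames(lay))) {
    d <- sqrt(colSums((t(lay[channels[good_idx], , drop = FALSE]) -
                         lay[channels[bad_ch], ])^2))
    nb <- good_idx[order(d)][seq_len(min(3, length(good_idx)))]
    w <- 1 / pmax(sort(d)[seq_along(nb)], 1e-6)
  } else {
    nb <- good_idx
    w <- rep(1, length(nb))
  }
  colSums(epoch_mat[nb, , drop = FALSE] * (w / sum(w)))
}

#' Learn rejection thresholds and repair or reject artifact epochs
#'
#' A desk-scale stand-in for cross-validated artifact repair: per-channel
#' peak-to-peak rejection thresholds are picked from a quantile grid by
#' K-fold cross-validation (minimising the distance between the mean of
#' retained training epochs and the pointwise median of held-out epochs);
#' epochs whose supra-threshold channel count is at most `rho` have those
#' channels replaced by an inverse-distance-weighted average of the three
#' nearest clean channels; epochs with more than `kappa` bad channels are
#' rejected; in between, the worst `rho` channels are repaired and the
#' epoch kept. `(rho, kappa)` are themselves selected on the same CV
#' objective over a small grid.
#'
#' @param es An `epoch_set` of short (typically 1-s) epochs.
#' @param cv_folds Number of CV folds; there must be at least that many
#'   epochs.
#' @param rho_grid,kappa_grid Candidate values for the repair budget and
#'   the rejection limit.
#' @param threshold_probs Quantile grid the per-channel threshold is drawn
#'   from (a no-rejection candidate above the channel maximum is always
#'   included).
#' @return List with `epochs` (flagged/repaired `epoch_set`) and `params`
#'   (`thresholds`, `rho`, `kappa`).
#' @export
clean_epochs <- function(es, cv_folds = 4,
                         rho_grid = c(1L, 2L), kappa_grid = c(4L, 8L),
                         threshold_probs = c(0.6, 0.7, 0.8, 0.9, 0.95)) {
  ne <- dim(es$data)[1]; nc <- dim(es$data)[2]
  if (ne < cv_folds) stop("fewer epochs than CV folds")
  keep <- es$flags != "rejected"
  idx <- which(keep)
  ptp <- .epoch_ptp(es)[idx, , drop = FALSE]
  dat <- es$data[idx, , , drop = FALSE]
  folds <- .epoch_folds(length(idx), cv_folds)

  thr <- numeric(nc)
  for (ch in seq_len(nc)) {
    cand <- unique(c(stats::quantile(ptp[, ch], threshold_probs, names = FALSE),
                     max(ptp[, ch]) * 1.01))
    errs <- vapply(cand, function(t) {
      mean(vapply(seq_len(cv_folds), function(f) {
        tr <- which(folds != f & ptp[, ch] <= t)
        te <- which(folds == f)
        if (length(tr) == 0) return(Inf)
        mhat <- colMeans(dat[tr, ch, , drop = FALSE][, 1, ])
        med <- apply(dat[te, ch, , drop = FALSE][, 1, , drop = FALSE], 3,
                     stats::median)
        sqrt(mean((mhat - med)^2))
      }, numeric(1)))
    }, numeric(1))
    thr[ch] <- max(cand[errs <= min(errs) + 1e-12])
  }

  bad <- sweep(ptp, 2, thr, ">")
  apply_rk <- function(dat_in, bad_in, rho, kappa) {
    ne_in <- dim(dat_in)[1]
    flags <- rep("clean", ne_in)
    out <- dat_in
    for (e in seq_len(ne_in)) {
      nb <- sum(bad_in[e, ])
      if (nb == 0) next
      if (nb > kappa) { flags[e] <- "rejected"; next }
      flags[e] <- "repaired"
      worst <- order(ptp[e, ] - thr, decreasing = TRUE)[seq_len(min(nb, rho))]
      worst <- worst[bad_in[e, worst]]
      good <- which(!bad_in[e, ])
      if (length(good) == 0) { flags[e] <- "rejected"; next }
      for (ch in worst)
        out[e, ch, ] <- .repair_channel(dat_in[e, , ], ch, good, es$channels)
    }
    list(data = out, flags = flags)
  }

  grid <- expand.grid(rho = rho_grid, kappa = kappa_grid)
  obj <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(cv_folds), function(f) {
      tr <- which(folds != f)
      res <- apply_rk(dat[tr, , , drop = FALSE], bad[tr, , drop = FALSE],
                      grid$rho[i], grid$kappa[i])
      ok <- res$flags != "rejected"
      if (!any(ok)) return(Inf)
      mhat <- apply(res$data[ok, , , drop = FALSE], c(2, 3), mean)
      med <- apply(dat[folds == f, , , drop = FALSE], c(2, 3), stats::median)
      sqrt(mean((mhat - med)^2))
    }, numeric(1)))
  }, numeric(1))
  best <- which.min(obj)
  rho <- grid$rho[best]; kappa <- grid$kappa[best]

  res <- apply_rk(dat, bad, rho, kappa)
  out <- es
  out$data[idx, , ] <- res$data
  out$flags[idx] <- res$flags
  list(epochs = out,
       params = list(thresholds = stats::setNames(thr, es$channels),
                     rho = rho, kappa = kappa))
}

#' Reassemble clean short epochs into longer analysis epochs
#'
#' Concatenates maximal consecutive runs of non-rejected epochs and cuts
#' each run into non-overlapping `out_len_s` epochs (residuals dropped).
#' A full clean minute of 1-s epochs yields exactly twelve 5-s epochs;
#' shorter sets are returned short with a warning.
#'
#' @param es An `epoch_set` of short epochs (flags respected).
#' @param out_len_s Output epoch length in seconds; must be a multiple of
#'   the input length.
#' @return An `epoch_set` of `out_len_s` epochs.
#' @export
reassemble <- function(es, out_len_s = 5) {
  k <- out_len_s / es$epoch_len_s
  stopifnot(abs(k - round(k)) < 1e-9)
  k <- as.integer(round(k))
  ok <- es$flags != "rejected"
  ne <- length(ok); nc <- dim(es$data)[2]; spe <- dim(es$data)[3]
  full_target <- ne %/% k
  runs <- rle(ok)
  groups <- list()
  pos <- 0L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (runs$values[i]) {
      for (j in seq_len(len %/% k))
        groups[[length(groups) + 1L]] <- pos + ((j - 1L) * k + 1L):(j * k)
    }
    pos <- pos + len
  }
  n_out <- length(groups)
  if (n_out == 0) {
    warning("no clean runs long enough; returning empty epoch set")
    return(new_epoch_set(array(0, c(0, nc, k * spe)), es$fs, out_len_s,
                         flags = character(0), channels = es$channels))
  }
  if (n_out < full_target)
    warning(sprintf("only %d of %d possible %g-s epochs could be assembled",
                    n_out, full_target, out_len_s))
  a <- array(0, c(n_out, nc, k * spe), dimnames = list(NULL, es$channels, NULL))
  for (g in seq_len(n_out))
    for (j in seq_len(k))
      a[g, , ((j - 1L) * spe + 1L):(j * spe)] <- es$data[groups[[g]][j], , ]
  new_epoch_set(a, es$fs, out_len_s, channels = es$channels)
}

#' Standard preprocessing chain for one recording
#'
#' Resample (if needed), zero-phase band-pass, 1-s epoching, flat-epoch
#' rejection, optional cross-validated cleaning, and reassembly into 5-s
#' analysis epochs.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Analysis rate, Hz.
#' @param band Length-2 band edges, Hz.
#' @param flat_ptp_uv Flat-epoch peak-to-peak floor, microvolts.
#' @param clean `"cv"` to run [clean_epochs()], `"off"` to skip.
#' @param out_len_s Analysis epoch length, seconds.
#' @return An `epoch_set` of analysis epochs.
#' @export
preprocess_recording <- function(rec, target_fs = 128, band = c(0.5, 40),
                                 flat_ptp_uv = 1, clean = c("off", "cv"),
                                 out_len_s = 5) {
  clean <- match.arg(clean)
  if (rec$fs > target_fs) rec <- resample_recording(rec, target_fs)
  taps <- design_bandpass(rec$fs, band[1], band[2])
  rec$data <- filter_zerophase(rec$data, taps)
  es <- epoch_fixed(rec, 1)
  es <- drop_flat(es, flat_ptp_uv)
  if (clean == "cv") es <- clean_epochs(es)$epochs
  reassemble(es, out_len_s)
}
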