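#' Canonical 17-channel montage
#'
#' The fixed channel set used throughout the pipeline: seventeen 10-20
#' electrodes covering frontal, central, temporal, parietal and occipital
#' regions, in the canonical order shared by every module. All tables and
#' matrices key channels by these labels, never by index.
#'
#' @return Character vector of 17 channel labels.
#' @export
eeg_channels <- function() {
  c("F7", "T3", "T5", "O1", "F3", "C3", "P3", "Fz", "Cz",
    "F8", "T4", "T6", "O2", "F4", "C4", "P4", "Pz")
}

# Schematic 2-D 10-20 layout (x: left-negative, y: anterior-positive),
# used only for inverse-distance neighbour weights during epoch repair.
.channel_layout <- function() {
  pos <- rbind(
    F7 = c(-0.59,  0.59), T3 = c(-0.81,  0.00), T5 = c(-0.59, -0.59),
    O1 = c(-0.26, -0.80), F3 = c(-0.34,  0.54), C3 = c(-0.40,  0.00),
    P3 = c(-0.34, -0.54), Fz = c( 0.00,  0.52), Cz = c( 0.00,  0.00),
    F8 = c( 0.59,  0.59), T4 = c( 0.81,  0.00), T6 = c( 0.59, -0.59),
    O2 = c( 0.26, -0.80), F4 = c( 0.34,  0.54), C4 = c( 0.40,  0.00),
    P4 = c( 0.34, -0.54), Pz = c( 0.00, -0.52)
  )
  colnames(pos) <- c("x", "y")
  pos[eeg_channels(), , drop = FALSE]
}

#' Spatial effect profiles
#'
#' Convenience constructors for the per-channel weight vector of
#' [cohort_spec()]: a uniform profile, a profile concentrated on a named
#' channel subset, or a posterior-graded profile that is strongest over
#' occipital/temporal sites and fades frontally.
#'
#' @param channels Channel labels the profile is defined over.
#' @param on For `spatial_profile_subset()`, the channels receiving weight 1.
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
spatial_profile_uniform <- function(channels = eeg_channels()) {
  stats::setNames(rep(1, length(channels)), channels)
}

#' @rdname spatial_profile_uniform
#' @export
spatial_profile_subset <- function(on, channels = eeg_channels()) {
  stopifnot(all(on %in% channels))
  stats::setNames(as.numeric(channels %in% on), channels)
}

#' @rdname spatial_profile_uniform
#' @export
spatial_profile_posterior <- function(channels = eeg_channels()) {
  pos <- .channel_layout()[channels, , drop = FALSE]
  # linear ramp from anterior (0.25) to posterior (1)
  y <- pos[, "y"]
  w <- 1 - 0.75 * (y - min(y)) / (max(y) - min(y))
  stats::setNames(as.numeric(w), channels)
}
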