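# Small deterministic fixtures shared across test files.

tiny_cohort <- function(n = 3, effect = 0, duration_s = 20, seed = 1,
                        profile = NULL, fs = 128) {
  spec <- cohort_spec(n_pnes = n, n_es = n, fs = fs, duration_s = duration_s,
                      effect = effect, spatial_profile = profile, seed = seed)
  generate_cohort(spec)
}

# an epoch_set of gaussian noise epochs: ne epochs x channels x (len_s*fs)
noise_epochs <- function(ne = 10, channels = c("O1", "O2", "Cz"), len_s = 1,
                         fs = 128, sd = 10, seed = 1) {
  set.seed(seed)
  a <- array(rnorm(ne * length(channels) * len_s * fs, sd = sd),
             c(ne, length(channels), len_s * fs),
             dimnames = list(NULL, channels, NULL))
  new_epoch_set(a, fs, len_s, channels = channels)
}

# a synthetic entropy design with ns subjects per class, ne epochs, and an
# optional group separation on selected channels
synthetic_design <- function(ns = 10, ne = 12, channels = eeg_channels(),
                             shift = 0, on = channels, seed = 1,
                             state = "dynamic", measure = "SampEn") {
  set.seed(seed)
  mats <- list(); groups <- character(0)
  for (i in seq_len(2 * ns)) {
    g <- if (i <= ns) "PNES" else "ES"
    m <- matrix(rnorm(ne * length(channels)), ne, length(channels),
                dimnames = list(NULL, channels))
    if (g == "PNES" && shift != 0)
      m[, colnames(m) %in% on] <- m[, colnames(m) %in% on] - shift
    mats[[i]] <- structure(m, class = c("entropy_matrix", "matrix"),
                           measure = measure, subject_id = sprintf("S%02d", i),
                           state = state, channels = channels)
    groups <- c(groups, g)
  }
  stack_design(mats, groups)
}
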