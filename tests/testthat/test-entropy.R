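# The nine estimators against independent brute-force oracles and their
# defining analytic cases.

test_that("sample entropy matches exhaustive pair counting", {
  # periodic example, m = 1: expected value from the double-loop oracle
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3)
  expect_equal(samp_en(x, m = 1, r = 0.1), o_sampen(x, 1, 0.1),
               tolerance = 1e-12)
  expect_equal(samp_en(rep(5, 50), 2, 0.2), 0) # constant: all templates match
  set.seed(11)
  for (i in 1:30) {
    x <- rnorm(40 + i)
    expect_equal(samp_en(x, 2, 0.2), o_sampen(x, 2, 0.2), tolerance = 1e-10)
  }
})

test_that("sample entropy returns NA (not a fabricated value) with no matches", {
  # (0,0) templates match each other but every extension differs hugely:
  # B > 0, A = 0, so the ratio is undefined
  x <- c(0, 0, 5, 0, 0, -5, 0, 0, 10, 0, 0, -10)
  expect_true(is.na(samp_en(x, 2, 0.2)))
  # fuzzy entropy stays finite on the same input
  expect_true(is.finite(fuzzy_en(x, 2, 0.2)))
})

test_that("fuzzy entropy matches the brute-force membership oracle", {
  x <- seq(0, 1, length.out = 20) # ramp
  expect_equal(fuzzy_en(x, 2, 0.2), o_fuzzyen(x, 2, 0.2), tolerance = 1e-10)
  expect_equal(fuzzy_en(rep(2, 30)), 0)
  set.seed(12)
  for (i in 1:30) {
    x <- rnorm(35 + i)
    expect_equal(fuzzy_en(x, 2, 0.2, 2), o_fuzzyen(x, 2, 0.2, 2),
                 tolerance = 1e-10)
  }
})

test_that("permutation entropy counts ordinal patterns exactly", {
  # hand-enumerated: 4 rising and 2 falling pairs of 6
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(perm_en(x, m = 2),
               -((4 / 6) * log(4 / 6) + (2 / 6) * log(2 / 6)) / log(2),
               tolerance = 1e-12)
  expect_equal(perm_en(1:50, m = 3), 0) # single ordinal pattern
  set.seed(13)
  expect_gt(perm_en(sample(0:10000), m = 3), 0.999) # near-uniform patterns
  for (i in 1:30) {
    x <- rnorm(30 + i)
    expect_equal(perm_en(x, 3), o_permen(x, 3), tolerance = 1e-10)
  }
})

test_that("dispersion entropy matches exhaustive pattern enumeration", {
  expect_equal(disp_en(rep(1, 20), 2, 3), 0)
  x12 <- c(0.1, 2, -1.4, 0.3, 2.2, -2, 0.5, 1.1, -0.6, 0.2, 1.9, -1.1)
  expect_equal(disp_en(x12, 2, 3), o_dispen(x12, 2, 3), tolerance = 1e-12)
  set.seed(14)
  expect_gt(disp_en(rnorm(10000), 2, 5), 0.98) # iid gaussian near maximal
  for (i in 1:30) {
    x <- rnorm(30 + i)
    expect_equal(disp_en(x, 2, 6), o_dispen(x, 2, 6), tolerance = 1e-10)
  }
})

test_that("conditional entropy equals the direct conditional histogram", {
  # deterministic symbol cycle: next symbol fully determined
  x <- rep(c(-3, 0, 3), 10) + seq(-0.01, 0.01, length.out = 30)
  expect_equal(cond_en(x, 2, 3), o_conden(x, 2, 3), tolerance = 1e-12)
  expect_lt(cond_en(rep(c(-3, 0, 3), 20), 2, 3), 1e-12)
  set.seed(15)
  # iid symbols approach the ln(c) limit with growing N
  expect_equal(cond_en(rnorm(50000), 2, 3), log(3), tolerance = 0.01)
  for (i in 1:30) {
    x <- rnorm(30 + i)
    expect_equal(cond_en(x, 2, 5), o_conden(x, 2, 5), tolerance = 1e-10)
  }
})

test_that("phase entropy reflects phase-histogram uniformity", {
  fs <- 64
  t <- (0:(fs * 4 - 1)) / fs
  tone <- sin(2 * pi * 8 * t) # integer cycles: uniform phase sweep
  expect_gt(phas_en(tone, 8), 0.99)
  # narrowband burst concentrates phases relative to the steady tone
  burst <- exp(-((t - 2) / 0.15)^2) * sin(2 * pi * 8 * t)
  expect_lt(phas_en(burst, 8), phas_en(tone, 8))
  expect_equal(phas_en(rep(1, 64), 8), 0)
  set.seed(16)
  for (i in 1:20) {
    x <- rnorm(30 + i)
    expect_equal(phas_en(x, 8), o_phasen(x, 8), tolerance = 1e-8)
  }
})

test_that("spectral entropy has its analytic values on tones", {
  n <- 128
  t <- 0:(n - 1)
  expect_lt(spec_en(sin(2 * pi * 8 * t / n)), 1e-6) # one-point spectrum
  two <- sin(2 * pi * 8 * t / n) + sin(2 * pi * 20 * t / n)
  expect_equal(spec_en(two), log(2) / log(n / 2), tolerance = 1e-9)
  expect_equal(spec_en(rep(0, 64)), 0)
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(30 + i)
    expect_equal(spec_en(x), o_specen(x), tolerance = 1e-8)
  }
})

test_that("Renyi entropy follows its closed form", {
  expect_equal(renyi_entropy_p(rep(1 / 8, 8), 2), log(8), tolerance = 1e-12)
  expect_equal(renyi_entropy_p(c(1, 0, 0, 0), 2), 0)
  p <- c(0.4, 0.2, 0.1, 0.1, 0.08, 0.06, 0.04, 0.02)
  expect_equal(renyi_entropy_p(p, 2), -log(sum(p^2)), tolerance = 1e-12)
  n <- 128; t <- 0:(n - 1)
  expect_lt(renyi_en(sin(2 * pi * 8 * t / n)), 1e-6)
  set.seed(18)
  for (i in 1:20) {
    x <- rnorm(30 + i)
    expect_equal(renyi_en(x, 2), o_renyien(x, 2), tolerance = 1e-8)
  }
})

test_that("wavelet entropy tracks scalogram energy dispersion", {
  fs <- 128
  t <- (0:639) / fs
  expect_lt(wave_en(sin(2 * pi * 10 * t), fs), 0.35) # concentrated energy
  # chirp spreads energy across scales; value equals recomputation from
  # the scalogram energies
  chirp <- sin(2 * pi * (1 + (40 - 1) * t / max(t) / 2) * t)
  expect_equal(wave_en(chirp, fs), o_waveen(chirp, fs), tolerance = 1e-10)
  expect_gt(wave_en(chirp, fs), wave_en(sin(2 * pi * 10 * t), fs))
  expect_equal(wave_en(rep(0, 640), fs), 0)
  # uniform limit: equal energies constructed in the scale domain
  e <- rep(1 / 16, 16)
  expect_equal(-sum(e * log(e)) / log(16), 1, tolerance = 1e-12)
})

test_that("every estimator agrees with its oracle on many random short signals", {
  set.seed(99)
  n_cases <- 0
  for (i in 1:110) {
    n <- sample(30:60, 1)
    x <- rnorm(n) * runif(1, 0.5, 20)
    expect_equal(samp_en(x, 2, 0.25), o_sampen(x, 2, 0.25), tolerance = 1e-10)
    expect_equal(fuzzy_en(x, 2, 0.2), o_fuzzyen(x, 2, 0.2), tolerance = 1e-10)
    expect_equal(perm_en(x, 3), o_permen(x, 3), tolerance = 1e-10)
    expect_equal(disp_en(x, 2, 5), o_dispen(x, 2, 5), tolerance = 1e-10)
    expect_equal(cond_en(x, 2, 6), o_conden(x, 2, 6), tolerance = 1e-10)
    expect_equal(phas_en(x, 8), o_phasen(x, 8), tolerance = 1e-8)
    expect_equal(spec_en(x), o_specen(x), tolerance = 1e-8)
    expect_equal(renyi_en(x, 2), o_renyien(x, 2), tolerance = 1e-8)
    expect_equal(wave_en(x, 64), o_waveen(x, 64), tolerance = 1e-8)
    n_cases <- n_cases + 1
  }
  expect_gte(n_cases, 100)
})

test_that("estimators respect scale/shape invariances and ranges", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(60)
    a <- runif(1, 0.5, 5); b <- runif(1, -10, 10)
    y <- a * x + b
    # r scales with sd: template measures are affine invariant
    expect_equal(samp_en(x, 2, 0.2), samp_en(y, 2, 0.2), tolerance = 1e-9)
    expect_equal(fuzzy_en(x, 2, 0.2), fuzzy_en(y, 2, 0.2), tolerance = 1e-9)
    # symbol/rank measures invariant to monotone increasing transforms
    expect_equal(perm_en(x, 3), perm_en(exp(x), 3), tolerance = 1e-12)
    expect_equal(disp_en(x, 2, 6), disp_en(y, 2, 6), tolerance = 1e-12)
    expect_equal(cond_en(x, 2, 6), cond_en(y, 2, 6), tolerance = 1e-12)
    # normalised estimators stay within [0, 1]
    for (v in c(perm_en(x, 3), disp_en(x, 2, 6), phas_en(x, 8), spec_en(x),
                wave_en(x, 128)))
      expect_true(v >= 0 && v <= 1 + 1e-9)
  }
})

test_that("a wider tolerance can only gain template matches, lowering SampEn", {
  # the counting property is exact: both match counts are non-decreasing
  # in r; the entropy itself is non-increasing in r at the pipeline's
  # epoch length, where the match ratio is well resolved
  set.seed(22)
  x <- rnorm(60)
  s <- sd(x)
  count_matches <- function(x, m, r) {
    nt <- length(x) - m
    B <- 0; A <- 0
    for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
    c(B, A)
  }
  cnt <- sapply(c(0.1, 0.2, 0.4, 0.8), function(r)
    count_matches(x, 2, r * s))
  expect_true(all(diff(cnt[1, ]) >= 0)) # B
  expect_true(all(diff(cnt[2, ]) >= 0)) # A
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(640)
    vals <- sapply(c(0.1, 0.15, 0.2, 0.3, 0.5), function(r) samp_en(x, 2, r))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("entropy parameter validation and per-state defaults hold", {
  expect_error(entropy_params("SampEn", r = -1), "r must be")
  expect_error(entropy_params("DispEn", c = 1), "c must be")
  expect_error(entropy_params("RenEn", alpha = 1), "alpha")
  expect_error(entropy_params("SampEn", k = 4), "unknown parameter")
  pre <- default_entropy_params("preictal")
  expect_equal(pre$SampEn$m, 1)
  expect_equal(pre$PhasEn$k, 16)
  int <- default_entropy_params("interictal")
  expect_equal(int$PermEn$m, 5)
  expect_equal(int$PhasEn$k, 8)
  expect_equal(length(entropy_grid("SampEn")), 4)
  expect_equal(length(entropy_grid("PermEn")), 3)
})

test_that("entropy_matrix maps epochs x channels and propagates NA", {
  es <- noise_epochs(ne = 4, len_s = 5, seed = 3)
  em <- entropy_matrix(es, entropy_params("SpecEn"))
  expect_equal(dim(em), c(4, 3))
  # identical epochs give identical rows
  es$data[2, , ] <- es$data[1, , ]
  em2 <- entropy_matrix(es, entropy_params("SpecEn"))
  expect_equal(em2[1, ], em2[2, ])
  # wrong epoch length rejected
  es1 <- noise_epochs(ne = 2, len_s = 1)
  expect_error(entropy_matrix(es1, entropy_params("SpecEn")), "epoch length")
  # noise row exceeds pure-tone row for SpecEn on every channel
  fs <- 128
  tone <- sin(2 * pi * 10 * (0:(5 * fs - 1)) / fs)
  a <- array(0, c(2, 2, 5 * fs), dimnames = list(NULL, c("O1", "O2"), NULL))
  set.seed(4)
  a[1, 1, ] <- rnorm(5 * fs); a[1, 2, ] <- rnorm(5 * fs)
  a[2, 1, ] <- tone; a[2, 2, ] <- tone
  em3 <- entropy_matrix(new_epoch_set(a, fs, 5), entropy_params("SpecEn"))
  expect_true(all(em3[1, ] > em3[2, ]))
})
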