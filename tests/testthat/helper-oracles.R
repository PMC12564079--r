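# Independent brute-force oracles for the entropy estimators. These are
# deliberately written as literal double loops / direct formula sums, not
# shared with the package implementations.

o_sampen <- function(x, m, r_frac) {
  s <- sd(x)
  if (s == 0) return(0)
  r <- r_frac * s
  n <- length(x)
  nt <- n - m
  B <- 0; A <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

o_fuzzyen <- function(x, m, r_frac, p = 2) {
  s <- sd(x)
  if (s == 0) return(0)
  r <- r_frac * s
  n <- length(x)
  nt <- n - m
  phim <- 0; phim1 <- 0; np <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      a <- x[i:(i + m - 1)]; b <- x[j:(j + m - 1)]
      d <- max(abs((a - mean(a)) - (b - mean(b))))
      phim <- phim + exp(-(d / r)^p)
      a <- x[i:(i + m)]; b <- x[j:(j + m)]
      d <- max(abs((a - mean(a)) - (b - mean(b))))
      phim1 <- phim1 + exp(-(d / r)^p)
      np <- np + 1
    }
  }
  log(phim / np) - log(phim1 / np)
}

o_permen <- function(x, m, tau = 1) {
  n_pat <- length(x) - (m - 1) * tau
  pats <- character(n_pat)
  for (i in 1:n_pat)
    pats[i] <- paste(rank(x[i + (0:(m - 1)) * tau], ties.method = "first"),
                     collapse = "-")
  p <- as.vector(table(pats)) / n_pat
  -sum(p * log(p)) / log(factorial(m))
}

o_symbols <- function(x, c) {
  y <- pnorm((x - mean(x)) / sd(x))
  z <- ceiling(c * y)
  z[z < 1] <- 1; z[z > c] <- c
  z
}

o_dispen <- function(x, m, c, tau = 1) {
  if (sd(x) == 0) return(0)
  z <- o_symbols(x, c)
  n_pat <- length(z) - (m - 1) * tau
  id <- integer(n_pat)
  for (i in 1:n_pat)
    id[i] <- sum((z[i + (0:(m - 1)) * tau] - 1) * c^(0:(m - 1)))
  p <- as.vector(table(id)) / n_pat
  -sum(p * log(p)) / log(c^m)
}

# direct conditional-histogram computation of next-symbol uncertainty
o_conden <- function(x, m, c) {
  if (sd(x) == 0) return(0)
  z <- o_symbols(x, c)
  nw <- length(z) - m + 1
  states <- vapply(1:nw, function(i) paste(z[i:(i + m - 2)], collapse = "-"),
                   character(1))
  nxt <- z[(1:nw) + m - 1]
  H <- 0
  for (s in unique(states)) {
    idx <- states == s
    ps <- mean(idx)
    pn <- as.vector(table(nxt[idx])) / sum(idx)
    H <- H + ps * (-sum(pn * log(pn)))
  }
  H
}

# analytic-signal phase via an explicit DFT sum (no fft())
o_phasen <- function(x, k) {
  if (sd(x) == 0) return(0)
  x <- x - mean(x)
  n <- length(x)
  j <- 0:(n - 1)
  X <- vapply(0:(n - 1), function(kk)
    sum(x * exp(-2i * pi * kk * j / n)), complex(1))
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  a <- vapply(j, function(t)
    sum(X * h * exp(2i * pi * (0:(n - 1)) * t / n)) / n, complex(1))
  phi <- Arg(a)
  b <- ceiling((phi + pi) / (2 * pi / k))
  b[b < 1] <- 1; b[b > k] <- k
  p <- as.vector(table(b)) / n
  -sum(p * log(p)) / log(k)
}

# periodogram by explicit DFT sums
o_spec_p <- function(x) {
  n <- length(x)
  j <- 0:(n - 1)
  P <- vapply(1:floor(n / 2), function(kk)
    Mod(sum(x * exp(-2i * pi * kk * j / n)))^2, numeric(1))
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

o_specen <- function(x) {
  p <- o_spec_p(x)
  if (is.null(p)) return(0)
  q <- p[p > 0]
  -sum(q * log(q)) / log(length(p))
}

o_renyien <- function(x, alpha = 2) {
  p <- o_spec_p(x)
  if (is.null(p)) return(0)
  log(sum(p^alpha)) / (1 - alpha)
}

# entropy recomputed directly from the transform's scalogram energies
o_waveen <- function(x, fs, n_scales = 16) {
  E <- seizentropy::morlet_energies(x, fs, n_scales)
  e <- E / sum(E)
  e <- e[e > 0]
  -sum(e * log(e)) / log(n_scales)
}

# exhaustive-pair AUC oracle
o_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}
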