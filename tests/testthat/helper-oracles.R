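# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package internals: plain double loops and explicit
# vector construction.

# Brute-force multivariate sample entropy: build every composite delay vector
# and every one-element channel extension explicitly, then count Chebyshev
# matches by exhaustive double loop.
oracle_msampen <- function(seg, M, tau, r) {
  if (is.vector(seg)) seg <- matrix(seg, ncol = 1)
  n <- ncol(seg); N <- nrow(seg)
  M <- rep_len(M, n); tau <- rep_len(tau, n)
  delta <- max(M) * max(tau)
  P <- N - delta
  Xm <- do.call(cbind, lapply(seq_len(n), function(k)
    sapply(0:(M[k] - 1), function(l) seg[(1:P) + l * tau[k], k])))
  Xext <- do.call(rbind, lapply(seq_len(n), function(k)
    cbind(Xm, seg[(1:P) + M[k] * tau[k], k])))
  count_pairs <- function(X) {
    s <- 0L
    for (i in seq_len(nrow(X) - 1L))
      for (j in (i + 1L):nrow(X))
        if (max(abs(X[i, ] - X[j, ])) <= r) s <- s + 1L
    s
  }
  B_m <- 2 * count_pairs(Xm) / (P * (P - 1))
  B_m1 <- 2 * count_pairs(Xext) / (n * P * (n * P - 1))
  list(B_m = B_m, B_m1 = B_m1,
       value = if (B_m > 0 && B_m1 > 0) -log(B_m1 / B_m) else NA_real_)
}

# Brute-force classic univariate sample entropy (Richman-Moorman counting
# with N - m*tau template vectors at both dimensions), written independently
# of the multivariate oracle.
oracle_sampen_uni <- function(x, m = 2L, tau = 1L, r) {
  N <- length(x)
  P <- N - m * tau
  hits <- c(0L, 0L)
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      ok_m <- TRUE
      for (l in 0:(m - 1L))
        if (abs(x[i + l * tau] - x[j + l * tau]) > r) { ok_m <- FALSE; break }
      if (ok_m) {
        hits[1] <- hits[1] + 1L
        if (abs(x[i + m * tau] - x[j + m * tau]) <= r) hits[2] <- hits[2] + 1L
      }
    }
  }
  -log(hits[2] / hits[1])
}

# brute-force Takens delay embedding for one channel
oracle_embed_uni <- function(x, m, tau, n_vectors) {
  out <- matrix(NA_real_, n_vectors, m)
  for (i in seq_len(n_vectors))
    for (l in seq_len(m))
      out[i, l] <- x[i + (l - 1L) * tau]
  out
}

# two-channel tone mixture for decomposition tests
tone_pair_signal <- function(f_high = 4, f_low = 0.5, fs = 100, dur_s = 30) {
  t <- seq(1 / fs, dur_s, by = 1 / fs)
  multichannel_signal(
    cbind(sin(2 * pi * f_high * t) + 0.8 * sin(2 * pi * f_low * t),
          cos(2 * pi * f_high * t) + sin(2 * pi * f_low * t + 1)),
    fs, c("a", "b"))
}

logistic_map <- function(n, x0 = 0.4, mu = 3.9) {
  x <- numeric(n); x[1] <- x0
  for (i in 2:n) x[i] <- mu * x[i - 1] * (1 - x[i - 1])
  x
}

reconstruction_relerr <- function(dec, x) {
  rec <- Reduce(`+`, c(dec$imfs, list(dec$residual)))
  norm(rec - unclass(x), "F") / norm(unclass(x), "F")
}
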