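#' Low-discrepancy direction vectors on the unit hypersphere
#'
#' Deterministic direction sets for multivariate EMD envelope construction.
#' A Hammersley point set in the unit hypercube \eqn{[0,1]^{n-1}} is mapped
#' area-uniformly onto the unit \eqn{(n-1)}-sphere through the angular
#' parameterization: each successive coordinate is drawn through the inverse
#' CDF of the marginal of a uniform point on the remaining sub-sphere (a
#' symmetric Beta law), and the final two coordinates through the polar angle.
#' The result is deterministic for fixed `(n_dim, count)` and markedly more
#' even than uniform random directions.
#'
#' @param n_dim dimension of the direction vectors (number of signal
#'   channels); must be >= 2. Univariate signals do not use projections and
#'   are decomposed by classic EMD instead.
#' @param count number of directions K (>= 1).
#' @return An object of class `direction_set`: list with `vectors` (a
#'   `count x n_dim` matrix of unit vectors, one direction per row) and
#'   `angles` (the `count x (n_dim - 1)` generating angles).
#' @examples
#' d <- generate_directions(3, 16)
#' range(sqrt(rowSums(d$vectors^2)))
#' @export
generate_directions <- function(n_dim, count) {
  if (!is.numeric(n_dim) || n_dim < 2)
    stop("`n_dim` must be >= 2: univariate input must route to plain EMD")
  if (!is.numeric(count) || count < 1) stop("`count` must be >= 1")
  n_dim <- as.integer(n_dim); count <- as.integer(count)
  u <- hammersley_points(count, n_dim - 1L)

  vecs <- matrix(0, count, n_dim)
  angs <- matrix(0, count, n_dim - 1L)
  radius <- rep(1, count)
  if (n_dim > 2) {
    for (j in seq_len(n_dim - 2L)) {
      # first coordinate of a uniform point on S^(q-1): (x+1)/2 ~ Beta(a, a)
      a <- (n_dim - j) / 2
      s <- 2 * qbeta(u[, j], a, a) - 1
      angs[, j] <- acos(s)
      vecs[, j] <- radius * s
      radius <- radius * sqrt(pmax(0, 1 - s^2))
    }
  }
  phi <- 2 * pi * u[, n_dim - 1L]
  angs[, n_dim - 1L] <- phi
  vecs[, n_dim - 1L] <- radius * cos(phi)
  vecs[, n_dim] <- radius * sin(phi)
  # guard against accumulated rounding: renormalize to unit norm
  vecs <- vecs / sqrt(rowSums(vecs^2))
  structure(list(vectors = vecs, angles = angs), class = "direction_set")
}

# Hammersley sequence: first coordinate a centered uniform grid, remaining
# coordinates van der Corput radical inverses in successive prime bases.
hammersley_points <- function(count, dims) {
  u <- matrix(0, count, dims)
  u[, 1] <- (seq_len(count) - 0.5) / count
  if (dims > 1) {
    bases <- primes_first(dims - 1L)
    for (j in 2:dims) u[, j] <- vapply(seq_len(count), radical_inverse,
                                       numeric(1), base = bases[j - 1L])
  }
  u
}

radical_inverse <- function(i, base) {
  out <- 0; f <- 1 / base
  while (i > 0) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

primes_first <- function(k) {
  known <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L,
             43L, 47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L, 89L, 97L,
             101L, 103L, 107L, 109L, 113L)
  if (k > length(known)) stop("direction sets beyond ", length(known) + 1,
                              " channels are not supported")
  known[seq_len(k)]
}

#' Project a multichannel signal along a direction
#'
#' @param x an [multichannel_signal()] (or plain matrix, samples x channels).
#' @param direction numeric vector of length `n_channels(x)`.
#' @return Numeric vector of length `nrow(x)`: the per-sample inner product.
#' @export
project_signal <- function(x, direction) {
  m <- unclass(x)
  if (length(direction) != ncol(m))
    stop("direction has length ", length(direction),
         " but the signal has ", ncol(m), " channels")
  as.vector(m %*% direction)
}

#' Mean of directional maxima envelopes
#'
#' For each direction the signal is projected, the projection's local maxima
#' located (plateaus take their midpoint), the multichannel samples at those
#' instants mirror-extended (two extrema reflected at each end) and
#' interpolated with a natural cubic spline per channel; the K envelopes are
#' averaged. Directions whose projection has fewer than 3 maxima are skipped.
#'
#' @param x signal matrix (samples x channels) or `mc_signal`.
#' @param directions a [generate_directions()] set with matching dimension.
#' @return List with `mean` (samples x channels local-mean matrix) and
#'   `n_valid` (directions that contributed). `n_valid = 0` signals a
#'   monotonic residual: no direction admits 3 maxima.
#' @export
envelope_local_mean <- function(x, directions) {
  stopifnot(inherits(directions, "direction_set"))
  m <- unclass(x)
  res <- envelope_mean_cpp(m, t(directions$vectors))
  if (res$n_valid == 0L) res$mean <- NULL
  res
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterates the detail `d <- d - local_mean(d)` until the sift-difference
#' criterion `sum(m^2) / sum(d^2) < sd_threshold` is met or `max_sift`
#' iterations have run.
#'
#' @param x signal matrix or `mc_signal` (the current remainder).
#' @param directions direction set for envelope construction.
#' @param sd_threshold stoppage threshold on the normalized sift difference
#'   (default 0.2). `Inf` forces exactly one sifting iteration.
#' @param max_sift hard cap on sifting iterations per mode (default 15).
#' @return List with `mode` (the extracted IMF matrix), `remainder`
#'   (`x - mode`, exact), and `n_sift`; or `NULL` when `x` is a monotonic
#'   residual (no projection has 3 maxima at the first iteration).
#' @export
sift_mode <- function(x, directions, sd_threshold = 0.2, max_sift = 15L) {
  v <- unclass(x)
  d <- v
  n_sift <- 0L
  repeat {
    em <- envelope_local_mean(d, directions)
    if (em$n_valid == 0L) {
      if (n_sift == 0L) return(NULL)  # monotonic residual
      break
    }
    m <- em$mean
    crit <- sum(m^2) / sum(d^2)
    d <- d - m
    n_sift <- n_sift + 1L
    if (crit < sd_threshold || n_sift >= max_sift) break
  }
  list(mode = d, remainder = v - d, n_sift = n_sift)
}

#' Multivariate empirical mode decomposition
#'
#' Decomposes an n-channel signal jointly into at most `max_modes`
#' scale-aligned intrinsic mode functions plus a residual, by projecting
#' along a low-discrepancy direction set, averaging the directional maxima
#' envelopes, and sifting (fine-to-coarse). Every channel receives the same
#' number of modes (mode alignment), and the modes plus residual reconstruct
#' the input exactly up to floating-point subtraction. Single-channel inputs
#' route to classic univariate EMD (upper/lower extrema envelopes).
#'
#' @param x an [multichannel_signal()] or numeric matrix.
#' @param n_directions number of projection directions K (default 64).
#' @param max_modes maximum number of modes to extract (default 6; with the
#'   residual kept as the coarsest scale this yields 7 analysis scales).
#' @param sd_threshold,max_sift sifting stoppage controls, see [sift_mode()].
#' @param rate,labels metadata when `x` is a bare matrix.
#' @return An object of class `imf_decomposition`: list with `imfs` (list of
#'   T x n mode matrices), `residual` (T x n), `rate`, `labels`.
#' @examples
#' t <- seq(0, 3, by = 0.01)
#' x <- multichannel_signal(cbind(sin(2 * pi * 4 * t) + sin(2 * pi * 0.5 * t),
#'                                cos(2 * pi * 4 * t)), 100, c("a", "b"))
#' dec <- memd(x, n_directions = 16, max_modes = 3)
#' length(dec$imfs)
#' @export
memd <- function(x, n_directions = 64L, max_modes = 6L,
                 sd_threshold = 0.2, max_sift = 15L,
                 rate = NULL, labels = NULL) {
  if (inherits(x, "mc_signal")) {
    rate <- signal_rate(x); labels <- channel_labels(x)
  } else {
    if (is.null(rate)) rate <- 1
    if (is.null(labels)) labels <- colnames(x)
  }
  m <- unclass(as.matrix(x))
  if (!all(is.finite(m))) stop("signal contains non-finite samples")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(m)))
  if (ncol(m) == 1L)
    return(emd_univariate(m, max_modes, sd_threshold, max_sift, rate, labels))

  directions <- generate_directions(ncol(m), n_directions)
  imfs <- list()
  remainder <- m
  for (k in seq_len(max_modes)) {
    s <- sift_mode(remainder, directions, sd_threshold, max_sift)
    if (is.null(s)) break
    imfs[[k]] <- s$mode
    remainder <- s$remainder
  }
  new_imf_decomposition(imfs, remainder, rate, labels)
}

new_imf_decomposition <- function(imfs, residual, rate, labels) {
  structure(list(imfs = imfs, residual = residual, rate = rate,
                 labels = labels),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d modes + residual, %d samples x %d channels\n",
              length(x$imfs), nrow(x$residual), ncol(x$residual)))
  invisible(x)
}

# classic univariate EMD: local mean = average of the maxima and minima
# cubic-spline envelopes, same mirror extension and stoppage as the
# multivariate driver
emd_univariate <- function(m, max_modes, sd_threshold, max_sift, rate, labels) {
  imfs <- list()
  remainder <- m
  for (k in seq_len(max_modes)) {
    d <- remainder
    n_sift <- 0L
    mono <- FALSE
    repeat {
      lm <- univariate_local_mean(d[, 1])
      if (is.null(lm)) { mono <- n_sift == 0L; break }
      crit <- sum(lm^2) / sum(d^2)
      d <- d - lm
      n_sift <- n_sift + 1L
      if (crit < sd_threshold || n_sift >= max_sift) break
    }
    if (mono) break
    imfs[[k]] <- d
    remainder <- remainder - d
  }
  new_imf_decomposition(imfs, remainder, rate, labels)
}

univariate_local_mean <- function(v) {
  up <- extrema_indices(v)
  lo <- extrema_indices(-v)
  if (length(up) < 3L || length(lo) < 3L) return(NULL)
  (spline_envelope(up, v) + spline_envelope(lo, v)) / 2
}

# strict local maxima with plateau midpoints (R mirror of the C++ rule)
extrema_indices <- function(v) {
  T <- length(v)
  out <- integer(0)
  i <- 2L
  while (i <= T - 1L) {
    if (v[i] > v[i - 1L]) {
      if (v[i] > v[i + 1L]) { out <- c(out, i); i <- i + 1L; next }
      if (v[i] == v[i + 1L]) {
        j <- i
        while (j + 1L <= T && v[j + 1L] == v[i]) j <- j + 1L
        if (j < T && v[j + 1L] < v[i]) out <- c(out, (i + j) %/% 2L)
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  out
}

spline_envelope <- function(ext, v) {
  t0 <- ext - 1L  # 0-based times to mirror about the signal ends
  Tn <- length(v) - 1L
  xt <- c(-t0[2], -t0[1], t0, 2 * Tn - t0[length(t0)], 2 * Tn - t0[length(t0) - 1L])
  yv <- v[c(ext[2], ext[1], ext, ext[length(ext)], ext[length(ext) - 1L])]
  keep <- !duplicated(xt)
  spline(xt[keep], yv[keep], xout = 0:Tn, method = "natural")$y
}

#' Append Gaussian white-noise channels for noise-assisted MEMD
#'
#' Augments a multichannel EMG signal with independent Gaussian white-noise
#' channels before decomposition. Joint decomposition with broadband noise
#' channels counteracts mode mixing; the noise channels are stripped again
#' afterwards with [strip_noise_channels()]. Each noise channel is scaled to
#' the mean standard deviation of the existing channels so it carries
#' comparable energy across all modes.
#'
#' @param x an [multichannel_signal()].
#' @param n_noise number of noise channels to append (default 6, turning the
#'   16-channel bilateral EMG montage into a 22-channel composite).
#' @param seed integer seed; the augmentation is bit-reproducible.
#' @return An `mc_signal` with `n_noise` extra channels labelled `WN1..`.
#' @export
add_noise_channels <- function(x, n_noise = 6L, seed = 1L) {
  stopifnot(inherits(x, "mc_signal"))
  if (n_noise < 0) stop("`n_noise` must be >= 0")
  n_noise <- as.integer(n_noise)
  if (n_noise == 0L) return(x)
  amp <- mean(apply(unclass(x), 2L, sd))
  noise <- with_seed_local(seed,
    matrix(rnorm(nrow(x) * n_noise, sd = amp), nrow(x), n_noise))
  multichannel_signal(cbind(unclass(x), noise), signal_rate(x),
                      c(channel_labels(x), paste0("WN", seq_len(n_noise))))
}

#' Drop trailing noise channels from a decomposition
#'
#' @param dec an `imf_decomposition` from [memd()] on a noise-augmented input.
#' @param n_noise how many trailing channels to strip.
#' @return The decomposition restricted to the first
#'   `ncol - n_noise` channels; mode count unchanged.
#' @export
strip_noise_channels <- function(dec, n_noise) {
  stopifnot(inherits(dec, "imf_decomposition"))
  n <- ncol(dec$residual)
  if (n_noise < 0) stop("`n_noise` must be >= 0")
  if (n_noise >= n) stop("cannot strip ", n_noise, " channels from a ",
                         n, "-channel decomposition")
  if (n_noise == 0L) return(dec)
  keep <- seq_len(n - n_noise)
  new_imf_decomposition(
    lapply(dec$imfs, function(m) m[, keep, drop = FALSE]),
    dec$residual[, keep, drop = FALSE],
    dec$rate, dec$labels[keep]
  )
}

#' Cumulative-IMF analysis scales
#'
#' Builds the fine-to-coarse scale sequence used for MEMD-enhanced MMSE:
#' scale n is the sum of all modes from order n upwards including the
#' residual, i.e. the signal with its finest n-1 modes removed. Scale 1
#' reconstructs the input; the last scale (`n_modes + 1`) is the residual
#' alone.
#'
#' @param dec an `imf_decomposition`.
#' @param n_scales number of scales to return (default: mode count + 1).
#' @return An object of class `cumulative_scales`: list of T x n matrices,
#'   ordered fine to coarse, each with attribute `scale_factor`.
#' @export
cumulative_scales <- function(dec, n_scales = length(dec$imfs) + 1L) {
  stopifnot(inherits(dec, "imf_decomposition"))
  N <- length(dec$imfs)
  if (n_scales < 1) stop("`n_scales` must be >= 1")
  if (n_scales > N + 1L)
    stop("`n_scales` (", n_scales, ") exceeds mode count + 1 (", N + 1L, ")")
  scales <- vector("list", N + 1L)
  acc <- dec$residual
  scales[[N + 1L]] <- acc
  for (i in rev(seq_len(N))) {
    acc <- scales[[i + 1L]] + dec$imfs[[i]]
    scales[[i]] <- acc
  }
  scales <- scales[seq_len(n_scales)]
  for (i in seq_along(scales)) attr(scales[[i]], "scale_factor") <- i
  structure(scales, class = "cumulative_scales")
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
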