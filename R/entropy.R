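#' Composite delay-vector embedding
#'
#' Builds the multivariate embedded reconstruction underlying multivariate
#' sample entropy: for an N x n segment, the i-th composite delay vector
#' concatenates, channel by channel, the lagged samples
#' `x[k, i], x[k, i + tau_k], ..., x[k, i + (m_k - 1) tau_k]`. With
#' `delta = max(M) * max(tau)` there are exactly `N - delta` such vectors,
#' each of total dimension `m = sum(M)`.
#'
#' @param segment numeric matrix, N samples x n channels (a vector is one
#'   channel).
#' @param M integer per-channel embedding dimensions (recycled to n).
#' @param tau integer per-channel time lags (recycled to n).
#' @return A `(N - delta) x sum(M)` matrix of composite delay vectors, rows
#'   ordered by origin index.
#' @export
embed_delay <- function(segment, M = 2L, tau = 1L) {
  if (is.vector(segment)) segment <- matrix(segment, ncol = 1)
  segment <- unclass(as.matrix(segment))
  n <- ncol(segment); N <- nrow(segment)
  M <- as.integer(rep_len(M, n)); tau <- as.integer(rep_len(tau, n))
  if (any(M < 1) || any(tau < 1)) stop("M and tau entries must be >= 1")
  delta <- max(M) * max(tau)
  if (N <= delta)
    stop("segment too short: need more than delta = max(M)*max(tau) = ",
         delta, " samples, got ", N)
  P <- N - delta
  cols <- lapply(seq_len(n), function(k) {
    vapply(0:(M[k] - 1L), function(l) segment[seq_len(P) + l * tau[k], k],
           numeric(P))
  })
  do.call(cbind, cols)
}

#' Multivariate sample entropy
#'
#' MSampEn of an N x n segment: the negative log of the conditional
#' probability that composite delay vectors within Chebyshev distance `r` of
#' each other at embedding dimension `m = sum(M)` remain within `r` when the
#' embedding is extended by one element in each channel in turn (giving
#' `n * (N - delta)` candidate vectors at dimension m + 1). Matches use
#' `d <= r` with self-matches excluded. Zero matches at either dimension
#' yield a flagged undefined estimate rather than a numeric value.
#'
#' @param segment numeric matrix (N x n) or vector (univariate case, where
#'   MSampEn reduces exactly to classic sample entropy).
#' @param M,tau per-channel embedding dimensions and lags (default 2 and 1
#'   for every channel).
#' @param r similarity tolerance, in the amplitude units of `segment`;
#'   typically from [tolerance_from_raw()].
#' @return An object of class `msampen_est`: list with `value` (numeric, or
#'   `NA` when undefined), `defined` (logical), `B_m`, `B_m1`, `n_vectors_m`,
#'   `n_vectors_m1`.
#' @examples
#' set.seed(1)
#' seg <- matrix(rnorm(200), ncol = 2)
#' msampen(seg, M = 2, tau = 1, r = 0.2 * sum(apply(seg, 2, sd)))
#' @export
msampen <- function(segment, M = 2L, tau = 1L, r) {
  if (is.vector(segment)) segment <- matrix(segment, ncol = 1)
  segment <- unclass(as.matrix(segment))
  if (!all(is.finite(segment))) stop("segment contains non-finite values")
  if (!is.numeric(r) || length(r) != 1L || r < 0)
    stop("`r` must be a single non-negative tolerance")
  n <- ncol(segment)
  M <- as.integer(rep_len(M, n)); tau <- as.integer(rep_len(tau, n))
  cnt <- msampen_counts_cpp(segment, M, tau, r)
  defined <- cnt$B_m > 0 && cnt$B_m1 > 0
  structure(list(
    value = if (defined) -log(cnt$B_m1 / cnt$B_m) else NA_real_,
    defined = defined,
    B_m = cnt$B_m, B_m1 = cnt$B_m1,
    n_vectors_m = cnt$n_vectors_m, n_vectors_m1 = cnt$n_vectors_m1
  ), class = "msampen_est")
}

#' @export
print.msampen_est <- function(x, ...) {
  if (x$defined)
    cat(sprintf("MSampEn = %.6f  (B_m = %.4g, B_m+1 = %.4g)\n",
                x$value, x$B_m, x$B_m1))
  else
    cat(sprintf("MSampEn undefined (B_m = %.4g, B_m+1 = %.4g)\n",
                x$B_m, x$B_m1))
  invisible(x)
}

#' Similarity tolerance from the raw segment
#'
#' The MSampEn tolerance convention for surface EMG coactivation analysis:
#' \code{r = factor * sum_k SD(channel_k)}, with the standard deviations taken on
#' the raw (pre-decomposition) segment of every channel entering the
#' computation. The same `r` is then applied to every cumulative scale of
#' that segment.
#'
#' @param raw_channels numeric matrix (samples x channels) or vector.
#' @param factor tolerance factor (default 0.2).
#' @return The tolerance r (same amplitude units as the data). All-constant
#'   input yields \code{r = 0} with a warning (matches then require exact
#'   equality).
#' @export
tolerance_from_raw <- function(raw_channels, factor = 0.2) {
  if (is.vector(raw_channels)) raw_channels <- matrix(raw_channels, ncol = 1)
  raw_channels <- unclass(as.matrix(raw_channels))
  if (nrow(raw_channels) < 2L) stop("need at least 2 samples to compute SDs")
  r <- factor * sum(apply(raw_channels, 2L, sd))
  if (r == 0) warning("all channels constant: r = 0, matches are exact-equality only")
  r
}

#' MMSE curve over cumulative-IMF scales
#'
#' Computes the multivariate multiscale entropy curve of one data segment:
#' the tolerance is derived once from the raw segment (not per scale) and
#' MSampEn is evaluated on each cumulative-IMF scale, fine to coarse.
#'
#' @param raw_segment numeric matrix (N x n): the raw signal slice, used only
#'   for the tolerance.
#' @param scales a [cumulative_scales()] object, or list of N x n matrices
#'   covering the same sample span (and channel subset) as `raw_segment`.
#' @param M,tau embedding parameters, see [msampen()].
#' @param r_factor tolerance factor (default 0.2).
#' @return A tibble of class `mmse_curve` with columns `scale`, `value`,
#'   `defined`, `B_m`, `B_m1`; attribute `r` records the tolerance used.
#' @export
mmse_curve <- function(raw_segment, scales, M = 2L, tau = 1L, r_factor = 0.2) {
  if (is.vector(raw_segment)) raw_segment <- matrix(raw_segment, ncol = 1)
  raw_segment <- unclass(as.matrix(raw_segment))
  for (s in scales) {
    if (nrow(s) != nrow(raw_segment) || ncol(s) != ncol(raw_segment))
      stop("every scale must cover the same samples x channels span as the raw segment")
  }
  r <- tolerance_from_raw(raw_segment, r_factor)
  ests <- lapply(scales, msampen, M = M, tau = tau, r = r)
  out <- tibble::tibble(
    scale = seq_along(scales),
    value = vapply(ests, `[[`, numeric(1), "value"),
    defined = vapply(ests, `[[`, logical(1), "defined"),
    B_m = vapply(ests, `[[`, numeric(1), "B_m"),
    B_m1 = vapply(ests, `[[`, numeric(1), "B_m1")
  )
  attr(out, "r") <- r
  class(out) <- c("mmse_curve", class(out))
  out
}
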