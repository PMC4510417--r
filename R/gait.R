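#' Detect heel-strike peaks in a gravity-axis accelerometer trace
#'
#' Heel strikes show up as sharp peaks in the accelerometer axis along
#' gravity. Peaks are local maxima exceeding `prominence_factor * SD(acc)`,
#' thinned so that retained peaks are at least `min_interval_s` apart
#' (larger peaks win).
#'
#' @param acc numeric vector, the accelerometer trace.
#' @param acc_rate sampling rate of `acc` in Hz.
#' @param min_interval_s minimum spacing between retained peaks in seconds
#'   (default 0.4, below any plausible step interval).
#' @param prominence_factor amplitude threshold in units of the trace SD
#'   (default 2).
#' @param side optional label ("left"/"right") carried in the result.
#' @return An object of class `heel_strikes`: list with `side`, `indices`
#'   (strictly increasing 0-based sample indices at `acc_rate`), `rate`.
#'   A flat or empty trace yields zero peaks, not an error.
#' @export
detect_acc_peaks <- function(acc, acc_rate, min_interval_s = 0.4,
                             prominence_factor = 2, side = NA_character_) {
  if (!all(is.finite(acc))) stop("accelerometer trace contains non-finite values")
  idx <- integer(0)
  if (length(acc) >= 3L) {
    cand <- extrema_indices(acc)
    thr <- prominence_factor * sd(acc)
    cand <- cand[acc[cand] > thr]
    if (length(cand) > 0L) {
      min_gap <- min_interval_s * acc_rate
      keep <- logical(length(cand))
      taken <- numeric(0)
      for (o in order(acc[cand], decreasing = TRUE)) {
        if (all(abs(cand[o] - taken) >= min_gap)) {
          keep[o] <- TRUE
          taken <- c(taken, cand[o])
        }
      }
      idx <- sort(cand[keep])
    }
  }
  structure(list(side = side, indices = as.integer(idx - 1L), rate = acc_rate),
            class = "heel_strikes")
}

#' @rdname detect_acc_peaks
#' @param indices strictly increasing 0-based sample indices.
#' @export
heel_strikes <- function(indices, acc_rate, side = NA_character_) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop("heel-strike indices must be strictly increasing")
  structure(list(side = side, indices = indices, rate = acc_rate),
            class = "heel_strikes")
}

#' @export
print.heel_strikes <- function(x, ...) {
  cat(sprintf("<heel_strikes> side=%s, %d strikes @ %g Hz\n",
              x$side, length(x$indices), x$rate))
  invisible(x)
}

#' Build gait cycles from bilateral heel strikes
#'
#' One gait cycle of a leg spans two consecutive ipsilateral heel strikes;
#' the stance phase runs from the ipsilateral strike to the next
#' contralateral strike, the swing phase covers the remainder. Consecutive
#' ipsilateral strike pairs containing anything other than exactly one
#' contralateral strike are discarded, as are cycles outside the
#' physiological duration bounds. All spans are half-open `[start, end)`
#' 0-based sample indices at the EMG rate, mapped from the accelerometer
#' rate by nearest-integer rate-ratio scaling.
#'
#' @param ipsi,contra [detect_acc_peaks()] results for the two legs; `ipsi`
#'   defines the cycles being built.
#' @param emg_rate EMG sampling rate in Hz.
#' @param min_duration_s,max_duration_s cycle duration sanity bounds in
#'   seconds (defaults 0.5 and 4).
#' @return A tibble of class `gait_cycles` with columns `side`, `start`,
#'   `stance_end`, `end` (EMG-rate sample indices); attribute `n_dropped`
#'   counts discarded strike pairs.
#' @export
build_gait_cycles <- function(ipsi, contra, emg_rate,
                              min_duration_s = 0.5, max_duration_s = 4) {
  stopifnot(inherits(ipsi, "heel_strikes"), inherits(contra, "heel_strikes"))
  if (length(ipsi$indices) == 0L || length(contra$indices) == 0L)
    stop("both heel-strike series must be non-empty")
  ratio <- emg_rate / ipsi$rate
  if (!is.finite(ratio) || ratio <= 0) stop("EMG/ACC rate ratio must be positive")
  rows <- list()
  n_dropped <- 0L
  ip <- ipsi$indices
  for (k in seq_len(length(ip) - 1L)) {
    p0 <- ip[k]; p1 <- ip[k + 1L]
    q <- contra$indices[contra$indices > p0 & contra$indices < p1]
    dur <- (p1 - p0) / ipsi$rate
    if (length(q) != 1L || dur < min_duration_s || dur > max_duration_s) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      side = ipsi$side,
      start = as.integer(round(p0 * ratio)),
      stance_end = as.integer(round(q * ratio)),
      end = as.integer(round(p1 * ratio))
    )
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(side = character(), start = integer(),
                   stance_end = integer(), end = integer())
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("gait_cycles", class(out))
  out
}

#' Extract one per-cycle EMG segment
#'
#' @param emg an [multichannel_signal()].
#' @param cycle a single row of a [build_gait_cycles()] table (or any list
#'   with `start`, `stance_end`, `end`).
#' @param segment which span to extract: the full cycle, the stance phase or
#'   the swing phase.
#' @param channels channel labels to keep (default: all).
#' @return Numeric matrix (samples x selected channels), half-open span.
#' @export
extract_segment <- function(emg, cycle, segment = c("full", "stance", "swing"),
                            channels = channel_labels(emg)) {
  stopifnot(inherits(emg, "mc_signal"))
  segment <- match.arg(segment)
  span <- switch(segment,
    full = c(cycle$start, cycle$end),
    stance = c(cycle$start, cycle$stance_end),
    swing = c(cycle$stance_end, cycle$end))
  if (span[1] < 0 || span[2] > nrow(emg))
    stop("cycle span [", span[1], ", ", span[2], ") outside signal bounds")
  x <- select_channels(emg, channels)
  unclass(x)[(span[1] + 1L):span[2], , drop = FALSE]
}

#' Drop amplitude-artifact gait cycles
#'
#' Automated stand-in for visual artifact screening: a cycle is rejected when
#' its peak absolute amplitude on any channel exceeds `z_threshold` times
#' that channel's global standard deviation.
#'
#' @param emg an [multichannel_signal()].
#' @param cycles a [build_gait_cycles()] table.
#' @param z_threshold rejection threshold in channel-SD units (default 8).
#' @return The filtered cycles table; attribute `n_rejected` counts drops.
#' @export
reject_artifact_cycles <- function(emg, cycles, z_threshold = 8) {
  stopifnot(inherits(emg, "mc_signal"))
  if (nrow(cycles) == 0L) return(cycles)
  global_sd <- apply(unclass(emg), 2L, sd)
  ok <- vapply(seq_len(nrow(cycles)), function(i) {
    seg <- extract_segment(emg, cycles[i, ], "full")
    all(apply(abs(seg), 2L, max) <= z_threshold * global_sd)
  }, logical(1))
  out <- cycles[ok, ]
  attr(out, "n_rejected") <- sum(!ok)
  attr(out, "n_dropped") <- attr(cycles, "n_dropped")
  class(out) <- unique(c("gait_cycles", class(out)))
  out
}
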