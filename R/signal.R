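#' Multichannel signal container
#'
#' A light matrix-backed container for uniformly sampled multichannel
#' recordings (surface EMG, accelerometry): a T x n matrix of amplitudes with
#' a sampling rate in Hz and one label per channel.
#'
#' @param values numeric matrix, samples in rows, channels in columns. A bare
#'   numeric vector is treated as a single channel.
#' @param rate sampling frequency in Hz (> 0).
#' @param labels character vector of channel identifiers, one per column.
#' @return An object of class `mc_signal`: the value matrix with `rate` and
#'   column-name labels attached.
#' @examples
#' x <- multichannel_signal(cbind(sin(1:100), cos(1:100)), 100, c("a", "b"))
#' n_channels(x)
#' @export
multichannel_signal <- function(values, rate, labels = colnames(values)) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("a signal needs at least 2 samples")
  if (ncol(values) < 1L) stop("a signal needs at least 1 channel")
  if (!all(is.finite(values))) stop("signal values must all be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("need exactly one label per channel (got ", length(labels),
         " labels for ", ncol(values), " channels)")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  dimnames(values) <- list(NULL, labels)
  structure(values, rate = as.numeric(rate), class = c("mc_signal", "matrix", "array"))
}

#' @export
print.mc_signal <- function(x, ...) {
  cat(sprintf("<mc_signal> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x), ncol(x), signal_rate(x), nrow(x) / signal_rate(x)))
  cat("channels:", paste(channel_labels(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname multichannel_signal
#' @param x an `mc_signal`.
#' @export
signal_rate <- function(x) attr(x, "rate")

#' @rdname multichannel_signal
#' @export
channel_labels <- function(x) colnames(x)

#' @rdname multichannel_signal
#' @export
n_channels <- function(x) ncol(x)

#' Tidy view of a multichannel signal
#'
#' @param x an `mc_signal`.
#' @param ... unused.
#' @return A tibble with columns `time_s`, `channel`, `value`.
#' @export
as_tibble.mc_signal <- function(x, ...) {
  tibble::tibble(
    time_s = rep((seq_len(nrow(x)) - 1) / signal_rate(x), times = ncol(x)),
    channel = rep(channel_labels(x), each = nrow(x)),
    value = as.vector(unclass(x)[, , drop = TRUE])
  )
}

#' Read / write multichannel signals as delimited text
#'
#' The canonical interchange format is tab-separated text with a single
#' header line `rate=<Hz>\t<label1>\t<label2>...` followed by one row of
#' amplitudes per sample. Values round-trip at `%.12g` precision.
#'
#' @param path file path.
#' @return `read_signal()` returns an [multichannel_signal()] object;
#'   `write_signal()` returns `path` invisibly.
#' @export
read_signal <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty signal file: ", path)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (!grepl("^rate=", fields[1]))
    stop("malformed header (line 1): expected leading `rate=<Hz>` field in ", path)
  rate <- suppressWarnings(as.numeric(sub("^rate=", "", fields[1])))
  if (!is.finite(rate) || rate <= 0)
    stop("malformed header (line 1): rate is not a positive number in ", path)
  labels <- fields[-1]
  if (length(labels) == 0L)
    stop("malformed header (line 1): no channel labels after rate in ", path)
  values <- utils::read.table(path, sep = "\t", skip = 1L,
                              colClasses = "numeric", header = FALSE)
  if (ncol(values) != length(labels))
    stop("ragged file: ", ncol(values), " data columns vs ",
         length(labels), " header labels in ", path)
  values <- as.matrix(values)
  bad <- which(!is.finite(values))
  if (length(bad) > 0) {
    stop("non-finite value at data line ", ((bad[1] - 1) %% nrow(values)) + 2L,
         " of ", path)
  }
  multichannel_signal(values, rate, labels)
}

#' @rdname read_signal
#' @param x an `mc_signal` to serialize.
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "mc_signal"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(sprintf("rate=%.10g", signal_rate(x)), channel_labels(x)),
                   collapse = "\t"), con)
  body <- apply(unclass(x), 1L, function(row)
    paste(sprintf("%.12g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

# internal: subset channels by label, preserving class/rate
select_channels <- function(x, labels) {
  have <- channel_labels(x)
  missing <- setdiff(labels, have)
  if (length(missing) > 0)
    stop("unknown channel label(s): ", paste(missing, collapse = ", "),
         "; valid labels are: ", paste(have, collapse = ", "))
  multichannel_signal(unclass(x)[, labels, drop = FALSE], signal_rate(x), labels)
}
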