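#' Continuous multi-channel signal
#'
#' Lightweight container for a continuous signal: a channels-by-time numeric
#' matrix, its sampling frequency, and the time of the first sample (`t0`,
#' seconds). Event onsets are expressed on the same clock, so a signal
#' zero-padded before the first event simply has a negative `t0`.
#'
#' @param data Numeric matrix (channels x samples) or vector (one channel).
#' @param sfreq Sampling frequency in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return Object of class `durerp_signal`.
#' @export
signal <- function(data, sfreq, t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data), sfreq > 0)
  structure(list(data = data, sfreq = sfreq, t0 = t0), class = "durerp_signal")
}

#' @export
print.durerp_signal <- function(x, ...) {
  cat(sprintf("<durerp_signal> %d channel(s) x %d samples @ %g Hz, t0=%gs (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, x$t0, ncol(x$data) / x$sfreq))
  invisible(x)
}

#' @export
dim.durerp_signal <- function(x) dim(x$data)

n_samples <- function(x) ncol(x$data)

# sample index (1-based) of a time point on the signal clock; the time point
# and the origin are rounded separately so that event placement is identical
# whichever origin a consumer uses
time_to_sample <- function(sig, t) {
  as.integer(round(t * sig$sfreq)) - as.integer(round(sig$t0 * sig$sfreq)) + 1L
}

#' Write / read a continuous signal
#'
#' The signal matrix is stored as little-endian 64-bit floats (row-major:
#' channel-by-channel) next to a JSON sidecar `<path>.json` holding
#' `sfreq`, `t0`, `n_channels`, `n_samples`, and any extra metadata.
#'
#' @param sig A [signal()].
#' @param path Destination file for the raw float payload.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path, meta = list()) {
  stopifnot(inherits(sig, "durerp_signal"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(sig$data)), con, size = 8, endian = "little")
  sidecar <- c(list(sfreq = sig$sfreq, t0 = sig$t0,
                    n_channels = nrow(sig$data), n_samples = ncol(sig$data)),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- sidecar$n_channels * sidecar$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  signal(matrix(x, nrow = sidecar$n_channels, byrow = TRUE),
         sfreq = sidecar$sfreq, t0 = sidecar$t0)
}
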