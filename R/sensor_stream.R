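#' Multichannel uniformly sampled sensor stream
#'
#' The basic container for EEG, EMG, acceleration and synchronization-pulse
#' recordings: a channels-by-samples matrix with a sampling rate, unique
#' channel labels, a stream kind and a start time in the recorder's clock.
#'
#' @param data numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz, positive.
#' @param labels character vector of unique channel identifiers, one per row.
#' @param kind one of `"eeg"`, `"emg"`, `"accel"`, `"pulse"`.
#' @param start_time start of the recording in seconds (recorder clock).
#' @param units physical units of the samples (e.g. `"uV"`, `"g"`).
#' @param pos optional channels x 3 electrode/sensor positions in mm.
#' @return an object of class `SensorStream`.
#' @export
sensor_stream <- function(data, fs, labels = NULL,
                          kind = c("eeg", "emg", "accel", "pulse"),
                          start_time = 0, units = "", pos = NULL) {
  kind <- match.arg(kind)
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix (channels x samples)")
  if (!all(is.finite(data))) stop("all samples must be finite")
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive finite number")
  if (is.null(labels)) labels <- paste0(substr(kind, 1, 3), seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("channel count does not match data rows")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.null(pos)) {
    pos <- as.matrix(pos)
    stopifnot(nrow(pos) == nrow(data), ncol(pos) == 3)
  }
  structure(list(data = data, fs = fs, labels = labels, kind = kind,
                 start_time = start_time, units = units, pos = pos),
            class = "SensorStream")
}

#' @export
print.SensorStream <- function(x, ...) {
  cat(sprintf("<SensorStream: %s> %d ch x %d samples @ %g Hz (%.2f s)\n",
              x$kind, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  cat("  labels:", paste(head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Sample times of a stream (seconds, recorder clock)
#' @param x a `SensorStream`.
#' @return numeric vector of per-sample times.
#' @export
stream_times <- function(x) {
  x$start_time + (seq_len(ncol(x$data)) - 1) / x$fs
}

#' Duration of a stream in seconds
#' @param x a `SensorStream`.
#' @export
stream_duration <- function(x) ncol(x$data) / x$fs

#' Select channels of a stream by label or index
#' @param x a `SensorStream`; @param sel labels or integer indices.
#' @return a `SensorStream` with the selected channels.
#' @export
stream_channels <- function(x, sel) {
  if (is.character(sel)) sel <- match(sel, x$labels)
  if (anyNA(sel)) stop("unknown channel label")
  sensor_stream(x$data[sel, , drop = FALSE], x$fs, x$labels[sel], x$kind,
                x$start_time, x$units,
                if (!is.null(x$pos)) x$pos[sel, , drop = FALSE])
}

#' Shift a stream's clock by tau seconds
#' @param x a `SensorStream`; @param tau shift in seconds.
#' @return the stream with `start_time` advanced by `tau`.
#' @export
shift_stream <- function(x, tau) {
  x$start_time <- x$start_time + tau
  x
}
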