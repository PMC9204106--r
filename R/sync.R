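# Offline synchronization of the EEG and body-sensor clock domains using the
# shared square-pulse channel recorded by both systems.

find_pulse_channel <- function(x) {
  if (x$kind == "pulse") return(1L)
  hit <- grep("pulse|sync|trig", x$labels, ignore.case = TRUE)
  if (length(hit) == 0) stop("no pulse channel found in stream (label containing 'pulse'/'sync'/'trig' or kind='pulse')")
  hit[1]
}

#' Rising-edge times of a pulse channel
#'
#' Edges are threshold crossings at half the pulse amplitude, refined by
#' linear interpolation between the bracketing samples.
#'
#' @param x a `SensorStream` containing a pulse channel.
#' @return numeric vector of edge times in seconds (recorder clock).
#' @export
pulse_edges <- function(x) {
  ch <- find_pulse_channel(x)
  v <- x$data[ch, ]
  lo <- quantile(v, 0.1); hi <- quantile(v, 0.9)
  if (hi - lo <= 10 * .Machine$double.eps * max(abs(v), 1))
    return(numeric(0))
  thr <- (lo + hi) / 2
  above <- v >= thr
  idx <- which(!above[-length(above)] & above[-1])
  if (length(idx) == 0) return(numeric(0))
  frac <- (thr - v[idx]) / (v[idx + 1] - v[idx])
  x$start_time + (idx - 1 + frac) / x$fs
}

#' Synchronize two sensor streams via their shared pulse channel
#'
#' Both pulse channels are resampled to a common rate (default 1 kHz) and the
#' lag maximizing their normalized cross-correlation within `max_lag_s` is
#' found. The lag is then refined and its residual spread quantified on the
#' matched rising edges: jitter is the standard deviation of per-edge offsets
#' after applying the lag.
#'
#' @param a,b `SensorStream`s that each contain a pulse channel; `lag` is the
#'   time of `b`'s clock minus `a`'s clock.
#' @param common_fs rate used for cross-correlation (Hz).
#' @param max_lag_s lag search window in seconds.
#' @return a `SyncReport`: list with `lag` (s), `jitter` (s),
#'   `n_edges`, and `method = "cross-correlation"`.
#' @export
align_streams <- function(a, b, common_fs = 1000, max_lag_s = 30) {
  ea <- pulse_edges(a)
  eb <- pulse_edges(b)
  if (length(ea) == 0 && length(eb) == 0)
    stop("alignment error: no pulse edges detected in either stream")
  if (length(ea) == 0 || length(eb) == 0)
    stop("alignment error: no pulse edges detected in one stream")

  pa <- a$data[find_pulse_channel(a), ]
  pb <- b$data[find_pulse_channel(b), ]
  ta <- stream_times(a); tb <- stream_times(b)
  t0 <- min(ta[1], tb[1]); t1 <- max(ta[length(ta)], tb[length(tb)])
  tg <- seq(t0, t1, by = 1 / common_fs)
  ra <- approx(ta, pa, xout = tg, rule = 2)$y
  rb <- approx(tb, pb, xout = tg, rule = 2)$y
  ra <- ra - mean(ra); rb <- rb - mean(rb)

  n <- length(tg)
  nf <- next_pow2(2 * n)
  FA <- fft(c(ra, numeric(nf - n)))
  FB <- fft(c(rb, numeric(nf - n)))
  cc <- Re(fft(FA * Conj(FB), inverse = TRUE)) / nf
  # circular correlation: index k+1 corresponds to shifting b forward by k
  lags <- c(0:(nf / 2 - 1), -(nf / 2):-1)
  keep <- abs(lags) <= max_lag_s * common_fs
  cc_k <- cc[keep]; lag_k <- lags[keep]
  best <- lag_k[which.max(cc_k)]
  # b delayed relative to a by `best` samples means b's clock = a's clock + lag
  lag0 <- -best / common_fs

  # refine on matched edges: shift b's edges back by lag0, pair to nearest a edge
  eb_in_a <- eb - lag0
  resid <- vapply(eb_in_a, function(t) {
    d <- ea - t
    d[which.min(abs(d))]
  }, 0)
  period <- if (length(ea) > 1) median(diff(ea)) else Inf
  ok <- abs(resid) < period / 2
  if (!any(ok)) stop("alignment error: pulse trains do not overlap after lag search")
  lag <- lag0 - mean(resid[ok])
  jitter <- if (sum(ok) > 1) sd(resid[ok]) else 0
  structure(list(lag = lag, jitter = jitter, n_edges = sum(ok),
                 method = "cross-correlation"),
            class = "SyncReport")
}

#' @export
print.SyncReport <- function(x, ...) {
  cat(sprintf("<SyncReport> lag = %.4f s, jitter = %.2f ms (%d edges, %s)\n",
              x$lag, 1000 * x$jitter, x$n_edges, x$method))
  invisible(x)
}

#' Shift a body-sensor stream into the EEG clock
#'
#' @param body a `SensorStream` in the body-recorder clock.
#' @param sync a `SyncReport` from [align_streams()] where `a` was the EEG
#'   stream and `b` the body stream.
#' @return `body` with its timestamps expressed in the EEG clock. No
#'   resampling of data channels occurs.
#' @export
apply_sync <- function(body, sync) {
  stopifnot(inherits(sync, "SyncReport"))
  shift_stream(body, -sync$lag)
}
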