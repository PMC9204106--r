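# Trial-averaged velocity and EMG envelopes on the gait-percentage grid, and
# their cross-sensor correlation statistics (Fisher z, group t-tests, FDR).

#' Band-pass filter and rectify raw EMG
#'
#' Zero-phase band-pass in 1-500 Hz followed by full-wave rectification.
#'
#' @param raw a one-channel EMG `SensorStream` with `fs > 1000` Hz.
#' @return the rectified `SensorStream` (nonnegative samples).
#' @export
preprocess_emg <- function(raw) {
  stopifnot(inherits(raw, "SensorStream"))
  if (raw$fs <= 1000) stop("EMG sampling rate must exceed 1000 Hz (500 Hz band edge above Nyquist)")
  x <- filter_band(raw$data[1, ], raw$fs, 1, 500, trans_lo = 1, trans_hi = 50)
  out <- raw
  out$data <- matrix(abs(x), 1)
  out
}

#' Hilbert amplitude envelope, resampled to a common rate
#'
#' Magnitude of the analytic signal, then anti-alias resampled (default
#' 200 Hz).
#'
#' @param x a one-channel `SensorStream` with finite samples.
#' @param target_fs output rate (Hz), at most `x$fs`.
#' @return a one-channel `SensorStream` at `target_fs`.
#' @export
envelope <- function(x, target_fs = 200) {
  stopifnot(inherits(x, "SensorStream"))
  if (target_fs > x$fs) stop("target_fs exceeds the signal sampling rate")
  env <- hilbert_env(x$data[1, ])
  y <- if (target_fs < x$fs) resample_sig(env, x$fs, target_fs) else env
  sensor_stream(matrix(y, 1), target_fs, paste0(x$labels[1], "_env"),
                kind = x$kind, start_time = x$start_time, units = x$units)
}

#' Standardize an envelope to gait-cycle percentage
#'
#' Each cycle is piecewise-linearly time-warped so that its RTO, RHS and LTO
#' events land on the participant-median event percentages (anchors LHS = 0%,
#' next LHS = 100%), then sampled on a uniform percentage grid and averaged
#' over cycles.
#'
#' @param env a one-channel `SensorStream` (envelope).
#' @param events a [gait_event_table()] covering the envelope time span.
#' @param grid_n grid points (>= 50; default 200).
#' @param signal_type `"emg"` or `"velocity"`, carried as metadata.
#' @return a `CycleEnvelope`: list with `grid` (0-100), `per_cycle`
#'   (cycles x grid), `mean`, `anchors` (median event percentages),
#'   `sensor_id`, `signal_type`, `n_dropped`.
#' @export
standardize_to_cycle <- function(env, events, grid_n = 200,
                                 signal_type = c("emg", "velocity")) {
  stopifnot(inherits(env, "SensorStream"), inherits(events, "GaitEventTable"))
  signal_type <- match.arg(signal_type)
  if (grid_n < 50) stop("grid_n must be >= 50")
  tt <- stream_times(env)
  x <- env$data[1, ]
  med <- c(RTO = median((events$t_RTO - events$t_LHS) / events$duration),
           RHS = median((events$t_RHS - events$t_LHS) / events$duration),
           LTO = median((events$t_LTO - events$t_LHS) / events$duration))
  grid <- seq(0, 100, length.out = grid_n)
  anchors_pct <- c(0, med, 1)
  per <- matrix(NA_real_, nrow(events), grid_n)
  dropped <- 0L
  for (i in seq_len(nrow(events))) {
    tc <- c(events$t_LHS[i], events$t_RTO[i], events$t_RHS[i],
            events$t_LTO[i], events$t_LHS_next[i])
    if (anyNA(tc) || tc[1] < tt[1] || tc[5] > tt[length(tt)]) {
      dropped <- dropped + 1L
      next
    }
    tq <- approx(anchors_pct * 100, tc, xout = grid)$y
    per[i, ] <- approx(tt, x, xout = tq)$y
  }
  per <- per[stats::complete.cases(per), , drop = FALSE]
  if (nrow(per) == 0) stop("no usable cycles within the envelope time span")
  structure(list(grid = grid, per_cycle = per, mean = colMeans(per),
                 anchors = med, sensor_id = env$labels[1],
                 signal_type = signal_type, n_dropped = dropped),
            class = "CycleEnvelope")
}

#' Fisher z-transform of a correlation, with capping of |r| = 1
#' @param r correlation values; |r| is capped at `1 - eps` before `atanh` so
#'   degenerate perfect correlations stay finite.
#' @param eps cap distance (default 1e-7).
#' @return z values.
#' @export
fisher_z <- function(r, eps = 1e-7) atanh(pmin(pmax(r, -1 + eps), 1 - eps))

#' Inverse Fisher transform
#' @param z z values.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Cross-sensor correlation statistics of cycle envelopes
#'
#' Pearson correlations between trial-averaged envelope curves for every
#' sensor pair, per participant; Fisher z; one-sample group t-tests per pair;
#' Benjamini-Hochberg FDR over the off-diagonal family; group correlations as
#' the back-transformed mean z; per-participant mean and maximum |z|.
#'
#' @param envs list over participants; each element a named list of
#'   `CycleEnvelope`s (same sensors, same grid).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return an `EnvelopeCorrStats`: `r` (participant x pair array as matrix
#'   list), `z_matrix` (sensor x sensor x participant), `group_r`, `t`, `p`,
#'   `q` (sensor x sensor), `mean_abs_z`, `max_abs_z` (per participant).
#' @export
correlate_sensors <- function(envs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(envs) >= 1)
  sensors <- names(envs[[1]])
  if (length(sensors) < 2) stop("need at least 2 sensors")
  ns <- length(sensors)
  np <- length(envs)
  z <- array(NA_real_, c(ns, ns, np), dimnames = list(sensors, sensors, NULL))
  for (p in seq_len(np)) {
    curves <- vapply(envs[[p]][sensors], function(e) e$mean,
                     numeric(length(envs[[p]][[1]]$mean)))
    const <- apply(curves, 2, function(v) sd(v) == 0)
    r <- suppressWarnings(cor(curves, method = method))
    r[const, ] <- NA; r[, const] <- NA
    z[, , p] <- fisher_z(r)
  }
  off <- upper.tri(matrix(0, ns, ns))
  tmat <- pmat <- matrix(NA_real_, ns, ns, dimnames = list(sensors, sensors))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    zi <- z[i, j, ]
    zi <- zi[is.finite(zi)]
    if (length(zi) >= 2 && sd(zi) > 0) {
      tt <- t.test(zi)
      tmat[i, j] <- tmat[j, i] <- unname(tt$statistic)
      pmat[i, j] <- pmat[j, i] <- tt$p.value
    }
  }
  q <- matrix(NA_real_, ns, ns, dimnames = dimnames(pmat))
  q[off] <- p.adjust(pmat[off], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  zbar <- apply(z, c(1, 2), function(v) mean(v[is.finite(v)]))
  group_r <- fisher_z_inv(zbar)
  diag(group_r) <- 1
  mean_abs_z <- apply(z, 3, function(m) mean(abs(m[off]), na.rm = TRUE))
  max_abs_z <- apply(z, 3, function(m) max(abs(m[off]), na.rm = TRUE))
  structure(list(sensors = sensors, z_matrix = z, t = tmat, p = pmat, q = q,
                 group_r = group_r, mean_abs_z = mean_abs_z,
                 max_abs_z = max_abs_z, method = method),
            class = "EnvelopeCorrStats")
}

#' @export
print.EnvelopeCorrStats <- function(x, ...) {
  cat(sprintf("<EnvelopeCorrStats> %d sensors, %d participants (%s)\n",
              length(x$sensors), dim(x$z_matrix)[3], x$method))
  cat("  group r:\n")
  print(round(x$group_r, 2))
  invisible(x)
}
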