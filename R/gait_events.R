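# Gait segmentation from ankle accelerometry: heel strikes from impact peaks
# of the total acceleration, toe offs from the onset of the subsequent
# swing/push-off burst, merged into left-heel-strike-referenced cycles.

#' Per-cycle gait event table
#'
#' @param df data.frame with columns `t_LHS`, `t_RTO`, `t_RHS`, `t_LTO`,
#'   `t_LHS_next` (seconds). A `duration` column is added.
#' @param validate_durations reject cycles outside the physiological
#'   0.5-2.5 s range (default TRUE).
#' @return a `GaitEventTable` (data.frame subclass); within each cycle the
#'   ordering t_LHS < t_RTO < t_RHS < t_LTO < t_LHS_next is enforced.
#' @export
gait_event_table <- function(df, validate_durations = TRUE) {
  need <- c("t_LHS", "t_RTO", "t_RHS", "t_LTO", "t_LHS_next")
  stopifnot(all(need %in% names(df)))
  df <- df[, need, drop = FALSE]
  ord <- df$t_LHS < df$t_RTO & df$t_RTO < df$t_RHS &
    df$t_RHS < df$t_LTO & df$t_LTO < df$t_LHS_next
  if (!all(ord)) stop(sprintf("%d cycles violate event ordering", sum(!ord)))
  df$duration <- df$t_LHS_next - df$t_LHS
  if (validate_durations && any(df$duration < 0.5 | df$duration > 2.5))
    stop("cycle durations outside [0.5, 2.5] s; pass validate_durations = FALSE to keep them")
  if (nrow(df) > 1 && any(diff(df$t_LHS) <= 0)) stop("cycles overlap")
  class(df) <- c("GaitEventTable", "data.frame")
  df
}

#' Total (norm) acceleration with gravity/bias removed
#'
#' Euclidean norm across the three axes per sample, then mean-removed.
#'
#' @param accel a 3-channel acceleration `SensorStream`.
#' @return a one-channel `SensorStream`.
#' @export
total_acceleration <- function(accel) {
  stopifnot(inherits(accel, "SensorStream"))
  if (nrow(accel$data) != 3) stop("total_acceleration requires exactly 3 channels")
  nrm <- sqrt(colSums(accel$data^2))
  sensor_stream(matrix(nrm - mean(nrm), 1), accel$fs, "total_accel",
                kind = "accel", start_time = accel$start_time,
                units = accel$units)
}

#' Velocity from the integral of total acceleration
#'
#' High-pass filters the total acceleration (zero-phase, default 0.3 Hz),
#' integrates with the cumulative trapezoid rule, and applies the same
#' high-pass to the integrated velocity: integration amplifies any residual
#' near-DC content, so both passes are needed to keep the velocity baseline
#' from wandering.
#'
#' @param total_accel one-channel `SensorStream` from [total_acceleration()].
#' @param highpass_hz drift-suppression high-pass edge (Hz); 0 disables it.
#' @return a one-channel velocity `SensorStream`.
#' @export
velocity_from_accel <- function(total_accel, highpass_hz = 0.3) {
  stopifnot(inherits(total_accel, "SensorStream"), nrow(total_accel$data) == 1)
  fs <- total_accel$fs
  if (fs < 50) stop("sampling rate must be >= 50 Hz")
  if (highpass_hz >= fs / 2) stop("highpass_hz must be below Nyquist")
  x <- total_accel$data[1, ]
  if (highpass_hz > 0) {
    bf <- signal::butter(2, highpass_hz / (fs / 2), type = "high")
    x <- signal::filtfilt(bf, x)
  }
  v <- pracma::cumtrapz(x)[, 1] / fs
  if (highpass_hz > 0) v <- signal::filtfilt(bf, v)
  sensor_stream(matrix(v, 1), fs, "velocity", kind = "accel",
                start_time = total_accel$start_time, units = "m/s")
}

#' Isolate segments with stable walking velocity
#'
#' The envelope RMS of the signal is tracked in sliding windows; samples whose
#' window RMS stays within `tol` of the running median RMS form stable
#' segments. Segments shorter than `min_len_s` are dropped.
#'
#' @param velocity one-channel `SensorStream` (velocity or total
#'   acceleration).
#' @param win_s window length (s); should span at least two gait cycles.
#' @param tol allowed fractional deviation from the running median (default
#'   0.2).
#' @param min_len_s minimum segment length to keep (s).
#' @param min_rms absolute rest threshold: samples whose window RMS falls
#'   below this are treated as standstill (default 0.05, i.e. 5 cm/s for
#'   velocity in m/s).
#' @return data.frame with columns `start`, `end` (s); possibly 0 rows.
#' @export
select_stable_segments <- function(velocity, win_s = 4, tol = 0.2,
                                   min_len_s = 5, min_rms = 0.05) {
  stopifnot(inherits(velocity, "SensorStream"))
  fs <- velocity$fs
  x <- velocity$data[1, ]
  env <- moving_rms(x - mean(x), win_s * fs)
  ref <- stats::runmed(env, 1 + 2 * floor(30 * fs / 2))
  overall <- median(env[env > 0])
  active <- env > pmax(0.25 * overall, min_rms)  # exclude rest/standstill
  stable <- active & abs(env - ref) <= tol * pmax(ref, .Machine$double.eps)
  r <- rle(stable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len_s * fs
  if (!any(keep)) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = velocity$start_time + (starts[keep] - 1) / fs,
             end = velocity$start_time + (ends[keep] - 1) / fs)
}

# heel strikes: dominant impact peaks with a cadence-scaled refractory period
detect_heel_strikes <- function(tot, fs, period_s) {
  x <- abs(tot)
  sm <- moving_rms(x, max(1, round(0.01 * fs)))
  thr <- 0.5 * quantile(sm, 0.995)
  pk <- pracma::findpeaks(sm, minpeakheight = thr,
                          minpeakdistance = max(1, round(0.4 * period_s * fs)))
  if (is.null(pk)) return(numeric(0))
  sort((pk[, 2] - 1) / fs)
}

estimate_period <- function(env, fs) {
  e <- env - mean(env)
  n <- length(e)
  ac <- stats::acf(e, lag.max = min(n - 1, round(3 * fs)), plot = FALSE)$acf[, 1, 1]
  lo <- round(0.5 * fs)
  if (length(ac) <= lo + 2) return(NA_real_)
  seg <- ac[(lo + 1):length(ac)]
  pk <- pracma::findpeaks(seg, npeaks = 1, sortstr = TRUE)
  if (is.null(pk)) return(NA_real_)
  (lo + pk[1, 2] - 1) / fs
}

# toe off: onset of the push-off/swing burst between two ipsilateral heel
# strikes, detected as the first sustained crossing of the smoothed envelope
# at onset_frac of the burst peak, measured above the quiet-stance baseline
detect_toe_offs <- function(tot, fs, hs, onset_frac = 0.3) {
  env <- moving_rms(abs(tot), max(1, round(0.05 * fs)))
  out <- rep(NA_real_, length(hs) - 1)
  hold <- max(2L, round(0.03 * fs))
  for (i in seq_len(length(hs) - 1)) {
    Tcyc <- hs[i + 1] - hs[i]
    w0 <- round((hs[i] + 0.25 * Tcyc) * fs) + 1
    w1 <- round((hs[i + 1] - 0.12 * Tcyc) * fs) + 1
    if (w1 <= w0 + 2 || w1 > length(env)) next
    seg <- env[w0:w1]
    base <- median(seg[seq_len(max(3, floor(0.3 * length(seg))))])
    thr <- base + onset_frac * (max(seg) - base)
    above <- seg >= thr
    # first index from which the envelope stays above threshold for `hold`
    run <- rle(above)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1
    cand <- starts[run$values & run$lengths >= hold]
    if (length(cand) == 0) next
    out[i] <- (w0 + cand[1] - 2) / fs
  }
  out
}

#' Detect gait events from bilateral ankle acceleration
#'
#' Heel strikes are the dominant impact peaks of each ankle's total
#' acceleration within stable-velocity segments; toe offs are onset crossings
#' (default 30% of the swing-burst peak) of the smoothed envelope between
#' successive ipsilateral heel strikes. Events are merged into LHS-referenced
#' cycles; cycles violating the ordering or duration bounds are discarded and
#' counted.
#'
#' @param left_accel,right_accel 3-axis ankle `SensorStream`s, time-aligned,
#'   each at least 10 s long.
#' @param onset_frac toe-off onset threshold as a fraction of the swing-burst
#'   peak.
#' @param use_stable_segments restrict detection to stable-velocity segments.
#' @return a [gait_event_table()]; attribute `n_discarded` counts rejected
#'   cycles.
#' @export
detect_events <- function(left_accel, right_accel, onset_frac = 0.3,
                          use_stable_segments = TRUE) {
  if (stream_duration(left_accel) < 10 || stream_duration(right_accel) < 10)
    stop("need at least 10 s of acceleration data")
  totL <- total_acceleration(left_accel)
  totR <- total_acceleration(right_accel)
  fs <- totL$fs
  xl <- totL$data[1, ]; xr <- totR$data[1, ]
  if (sd(xl) == 0 || sd(xr) == 0)
    stop("segmentation error: flat acceleration signal")

  env <- moving_rms(abs(xl), round(0.1 * fs))
  period <- estimate_period(env, fs)
  if (!is.finite(period)) stop("segmentation error: no rhythmic structure found")

  t_off <- totL$start_time
  hsL <- detect_heel_strikes(xl, fs, period) + t_off
  hsR <- detect_heel_strikes(xr, fs, period) + totR$start_time
  if (length(hsL) < 4 || length(hsR) < 3)
    stop("segmentation error: fewer than 3 valid cycles")

  if (use_stable_segments) {
    vel <- velocity_from_accel(totL)
    seg <- select_stable_segments(vel, win_s = 2 * period)
    if (nrow(seg) > 0) {
      inseg <- function(t) {
        ok <- rep(FALSE, length(t))
        for (i in seq_len(nrow(seg)))
          ok <- ok | (t >= seg$start[i] - period & t <= seg$end[i] + period)
        ok
      }
      hsL <- hsL[inseg(hsL)]; hsR <- hsR[inseg(hsR)]
    }
  }

  toL <- detect_toe_offs(xl, fs, hsL - t_off, onset_frac) + t_off
  toR <- detect_toe_offs(xr, fs, hsR - totR$start_time, onset_frac) +
    totR$start_time

  pick_in <- function(v, lo, hi) {
    x <- v[!is.na(v) & v > lo & v < hi]
    if (length(x) == 0) NA_real_ else x[1]
  }
  n <- length(hsL) - 1
  cyc <- data.frame(t_LHS = hsL[-length(hsL)], t_RTO = NA_real_,
                    t_RHS = NA_real_, t_LTO = NA_real_,
                    t_LHS_next = hsL[-1])
  for (i in seq_len(n)) {
    cyc$t_RTO[i] <- pick_in(toR, cyc$t_LHS[i], cyc$t_LHS_next[i])
    cyc$t_RHS[i] <- pick_in(hsR, cyc$t_LHS[i], cyc$t_LHS_next[i])
    cyc$t_LTO[i] <- pick_in(toL, cyc$t_RHS[i], cyc$t_LHS_next[i])
  }
  ok <- stats::complete.cases(cyc) &
    cyc$t_LHS < cyc$t_RTO & cyc$t_RTO < cyc$t_RHS &
    cyc$t_RHS < cyc$t_LTO & cyc$t_LTO < cyc$t_LHS_next &
    (cyc$t_LHS_next - cyc$t_LHS) >= 0.5 & (cyc$t_LHS_next - cyc$t_LHS) <= 2.5
  if (sum(ok) < 3) stop("segmentation error: fewer than 3 valid cycles")
  out <- gait_event_table(cyc[ok, , drop = FALSE], validate_durations = FALSE)
  attr(out, "n_discarded") <- sum(!ok)
  out
}
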