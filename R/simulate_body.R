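# Synthetic wireless body-sensor streams. Each sensor site provides 3-axis
# acceleration; the eight muscle sites additionally provide EMG. Muscle
# activation follows the classical phasing of level walking, expressed as
# raised-cosine windows on the left-heel-strike-referenced cycle fraction:
#   vastus medialis   - short window around the ipsilateral heel strike
#   biceps femoris    - terminal swing through the first double support
#   tibialis anterior - swing phase plus the subsequent double support
#   gastrocnemius     - stance (single-support) phase, antiphase to the above
# Right-side muscles use the same windows shifted by half a cycle.

wrap_half <- function(x) ((x + 0.5) %% 1) - 0.5

raised_bump <- function(phi, center, width) {
  d <- wrap_half(phi - center)
  out <- numeric(length(phi))
  inside <- abs(d) < width / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * d[inside] / width))
  out
}

# activation template of one muscle at cycle fraction phi (left side)
muscle_templates <- list(
  vastus        = function(phi) raised_bump(phi, 0.00, 0.20),
  biceps        = function(phi) raised_bump(phi, 0.97, 0.22),
  tibialis      = function(phi) raised_bump(phi, 0.87, 0.50),
  gastrocnemius = function(phi) raised_bump(phi, 0.33, 0.42)
)

#' Muscle activation template on the gait-percentage grid
#' @param muscle one of `"vastus"`, `"biceps"`, `"tibialis"`,
#'   `"gastrocnemius"`.
#' @param side `"l"` or `"r"` (right templates are shifted by half a cycle).
#' @param phi cycle fractions in `[0, 1)`.
#' @return activation in `[0, 1]`.
#' @export
muscle_activation <- function(muscle, side, phi) {
  f <- muscle_templates[[muscle]]
  if (is.null(f)) stop("unknown muscle: ", muscle)
  f(if (side == "r") phi - 0.5 else phi)
}

# smooth swing-velocity template; swing spans [swing_start, 1] for the left
# leg (LTO to next LHS) and [RTO, RHS] for the right leg
swing_velocity <- function(phi, side, ef) {
  if (side == "l") { s0 <- ef["LTO"]; s1 <- 1 } else { s0 <- ef["RTO"]; s1 <- ef["RHS"] }
  len <- s1 - s0
  u <- (phi - s0) / len
  v <- numeric(length(phi))
  inside <- u >= 0 & u <= 1
  v[inside] <- sin(pi * u[inside])^2
  v
}

swing_accel <- function(phi, side, ef) {  # d(template)/d(phi)
  if (side == "l") { s0 <- ef["LTO"]; s1 <- 1 } else { s0 <- ef["RTO"]; s1 <- ef["RHS"] }
  len <- s1 - s0
  u <- (phi - s0) / len
  a <- numeric(length(phi))
  inside <- u >= 0 & u <= 1
  a[inside] <- pi / len * sin(2 * pi * u[inside])
  a
}

gauss_spikes <- function(t, centers, sigma) {
  out <- numeric(length(t))
  for (c0 in centers) {
    w <- which(abs(t - c0) < 5 * sigma)
    out[w] <- out[w] + exp(-0.5 * ((t[w] - c0) / sigma)^2)
  }
  out
}

# sharp-onset burst (biexponential): zero before `onsets`, fast rise, slower
# decay; unit peak. Models the push-off transient whose onset marks toe off.
onset_bursts <- function(t, onsets, tau_r = 0.008, tau_d = 0.03) {
  out <- numeric(length(t))
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  pk <- exp(-tp / tau_d) - exp(-tp / tau_r)
  for (c0 in onsets) {
    w <- which(t >= c0 & t < c0 + 8 * tau_d)
    u <- t[w] - c0
    out[w] <- out[w] + (exp(-u / tau_d) - exp(-u / tau_r)) / pk
  }
  out
}

body_sensor_names <- function() {
  c(paste0(rep(c("vastus", "biceps", "tibialis", "gastrocnemius"), 2),
           rep(c("_l", "_r"), each = 4)),
    "ankle_l", "ankle_r")
}

#' Simulate body-sensor streams for a gait timeline
#'
#' Ankle (and muscle-site) acceleration is the analytic derivative of a smooth
#' swing-velocity template plus sharp heel-strike impact and toe-off push-off
#' transients on the vertical axis; EMG is amplitude-modulated broadband noise
#' whose modulation follows each muscle's activation window. Ground-truth
#' envelopes are returned on the 0-100% gait-percentage grid.
#'
#' @param timeline a [make_timeline()] result.
#' @param fs_accel accelerometer rate (Hz, >= 100; default 148).
#' @param fs_emg EMG rate (Hz, >= 1024 so that the 1-500 Hz band is valid;
#'   default 2000).
#' @param noise_sd additive sensor noise as a fraction of the signal scale.
#' @param seed integer seed (local to the call).
#' @param emg generate EMG streams (disable for kinematics-only studies).
#' @param muscle_accel generate 3-axis acceleration at the eight muscle sites
#'   in addition to the ankles (the wireless sensors record both).
#' @param grid_n points of the ground-truth gait-percentage grid.
#' @return list with `accel` (named list of 3-channel `SensorStream`s),
#'   `emg` (named list of 1-channel streams), and `truth` containing
#'   `velocity_env` and `emg_env` matrices (sensor x grid) plus the grid.
#' @export
simulate_body <- function(timeline, fs_accel = 148, fs_emg = 2000,
                          noise_sd = 0.05, seed = 1, emg = TRUE,
                          muscle_accel = TRUE, grid_n = 200) {
  stopifnot(inherits(timeline, "GaitTimeline"))
  if (fs_emg < 1024) stop("fs_emg must be >= 1024 Hz so the 1-500 Hz EMG band is valid")
  if (fs_accel < 100) stop("fs_accel must be >= 100 Hz")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old))

  ef <- timeline$event_fractions
  dur <- timeline_duration(timeline)
  ev <- timeline_events(timeline)
  grid <- seq(0, 100, length.out = grid_n)
  phig <- grid / 100

  sites <- body_sensor_names()
  side_of <- ifelse(grepl("_r$", sites), "r", "l")
  # amplitude of the swing kinematics at each site (thigh attenuated)
  site_scale <- ifelse(grepl("ankle", sites), 1,
                ifelse(grepl("vastus|biceps", sites), 0.55, 0.85))

  ta <- seq(0, dur, by = 1 / fs_accel)
  pha <- timeline_phase(timeline, ta)
  idx <- pmin(pmax(findInterval(ta, timeline$cycle_starts), 1),
              length(timeline$durations))
  inv_T <- 1 / timeline$durations[idx]
  a_sw_peak <- pi / 0.38   # peak of the swing-acceleration template at T = 1 s

  hs_l <- ev$t_LHS; hs_r <- ev$t_RHS
  to_l <- ev$t_LTO; to_r <- ev$t_RTO

  accel <- list()
  vel_env <- matrix(0, length(sites), grid_n,
                    dimnames = list(sites, NULL))
  for (k in seq_along(sites)) {
    sd_ <- side_of[k]
    ap <- site_scale[k] * swing_accel(pha, sd_, ef) * inv_T
    hs <- if (sd_ == "l") hs_l else hs_r
    to <- if (sd_ == "l") to_l else to_r
    vert <- 3.0 * a_sw_peak * ifelse(grepl("ankle", sites[k]), 1, 0.5) *
      gauss_spikes(ta, hs, 0.015) +
      1.3 * a_sw_peak * site_scale[k] * onset_bursts(ta, to)
    ml <- 0.1 * a_sw_peak * sin(2 * pi * timeline$cadence * ta)
    noise <- matrix(rnorm(3 * length(ta), sd = noise_sd * a_sw_peak), 3)
    dat <- rbind(ap, ml, vert) + noise
    accel[[sites[k]]] <- sensor_stream(
      dat, fs_accel, paste0(sites[k], c("_x", "_y", "_z")),
      kind = "accel", units = "m/s^2")
    vel_env[k, ] <- site_scale[k] * swing_velocity(phig, sd_, ef)
  }

  emg_list <- list()
  muscles <- sites[1:8]
  emg_env <- matrix(0, length(muscles), grid_n,
                    dimnames = list(muscles, NULL))
  base <- 0.15
  if (emg) {
    te <- seq(0, dur, by = 1 / fs_emg)
    phe <- timeline_phase(timeline, te)
    for (k in seq_along(muscles)) {
      mus <- sub("_[lr]$", "", muscles[k])
      act <- base + muscle_activation(mus, side_of[k], phe)
      carrier <- bandlimited_noise(length(te), fs_emg, 20, min(450, 0.45 * fs_emg))
      x <- carrier * act + rnorm(length(te), sd = noise_sd)
      emg_list[[muscles[k]]] <- sensor_stream(
        matrix(x, 1), fs_emg, muscles[k], kind = "emg", units = "mV")
    }
  }
  for (k in seq_along(muscles)) {
    mus <- sub("_[lr]$", "", muscles[k])
    emg_env[k, ] <- base + muscle_activation(mus, side_of[k], phig)
  }

  list(accel = accel, emg = emg_list,
       truth = list(grid = grid, velocity_env = vel_env, emg_env = emg_env,
                    events = ev))
}

#' Square synchronization pulse train
#'
#' @param duration seconds of signal.
#' @param fs sampling rate (Hz).
#' @param period pulse period (s).
#' @param width pulse width (s).
#' @param t0 time of the first rising edge (s).
#' @param start_time stream clock offset (s).
#' @return a one-channel `SensorStream` of kind `"pulse"` (0/1 square wave).
#' @export
make_pulse_stream <- function(duration, fs, period = 1, width = 0.2,
                              t0 = 0.5, start_time = 0) {
  t <- start_time + (seq_len(round(duration * fs)) - 1) / fs
  ph <- (t - t0) %% period
  v <- as.numeric(t >= t0 & ph < width)
  sensor_stream(matrix(v, 1), fs, "sync_pulse", kind = "pulse",
                start_time = start_time, units = "V")
}
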