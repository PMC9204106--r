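# Synthetic hdEEG: gait-modulated band-limited source rhythms projected
# through the lead field, plus broadband background dipoles, stereotyped
# ocular/motion/myogenic artifact components and white sensor noise. Every
# planted quantity is returned as ground truth.

band_edges <- function() list(alpha = c(8, 13), beta = c(13, 30),
                              gamma = c(30, 50))

#' Define a gait-modulated oscillatory source
#'
#' @param voxel index into the lead-field source grid.
#' @param mod named list over bands (`alpha`, `beta`, `gamma`) of functions
#'   `f(phi)` returning the relative amplitude modulation (zero-mean over the
#'   cycle) at cycle fraction `phi`.
#' @param amp named numeric vector of baseline amplitudes (dipole moment
#'   units) per band; bands absent from `mod` are silent.
#' @param orientation unit 3-vector dipole orientation; default superficial
#'   radial-ish `c(0, 0, 1)`.
#' @return a `SourceSpec`.
#' @export
source_spec <- function(voxel, mod, amp, orientation = c(0, 0, 1)) {
  stopifnot(is.list(mod), all(names(mod) %in% names(band_edges())))
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(voxel = voxel, mod = mod, amp = amp,
                 orientation = orientation),
            class = "SourceSpec")
}

#' Define artifact amplitudes and rates
#'
#' Amplitudes are in the same (microvolt-like) units as the projected EEG;
#' defaults are chosen so that each planted artifact exceeds its screening
#' threshold by a comfortable margin, as documented in the configuration.
#'
#' @param blink_rate ocular blink rate (Hz).
#' @param blink_amp blink peak amplitude at the most frontal channel.
#' @param motion_amp step-locked motion artifact amplitude.
#' @param myo_amp broadband (30-80 Hz) myogenic amplitude.
#' @return an `ArtifactSpec`.
#' @export
artifact_spec <- function(blink_rate = 0.25, blink_amp = 150,
                          motion_amp = 80, myo_amp = 15) {
  stopifnot(blink_rate >= 0, blink_amp >= 0, motion_amp >= 0, myo_amp >= 0)
  structure(list(blink_rate = blink_rate, blink_amp = blink_amp,
                 motion_amp = motion_amp, myo_amp = myo_amp),
            class = "ArtifactSpec")
}

# artifact scalp topographies from electrode positions (unit peak)
artifact_topographies <- function(elec) {
  front <- c(0, max(elec[, 2]), 0.3 * max(elec[, 3]))
  d_front <- sqrt(rowSums((elec - matrix(front, nrow(elec), 3, byrow = TRUE))^2))
  blink <- exp(-d_front / 40)
  motion <- 0.4 + 0.6 * (elec[, 3] - min(elec[, 3])) /
    max(elec[, 3] - min(elec[, 3]))
  rim <- exp(-(elec[, 3] - min(elec[, 3])) / 25)
  topo <- cbind(blink = blink / max(blink), motion = motion / max(motion),
                myogenic = rim / max(rim))
  topo
}

biexp_kernel <- function(fs, tau_r = 0.02, tau_d = 0.08) {
  t <- seq(0, 6 * tau_d, by = 1 / fs)
  k <- exp(-t / tau_d) - exp(-t / tau_r)
  k / max(k)
}

#' Simulate mobile EEG for a gait timeline
#'
#' Each planted source emits band-filtered Gaussian noise whose instantaneous
#' amplitude follows its gait-phase modulation curve; dipole moments are
#' projected through the lead field. Broadband (1-80 Hz, 1/f) background
#' dipoles at random grid voxels emulate ongoing neural activity. Artifact
#' components are added as topography x waveform, plus white sensor noise.
#'
#' @param timeline a [make_timeline()] result.
#' @param leadfield a [make_lead_field()] result.
#' @param sources list of [source_spec()].
#' @param artifacts an [artifact_spec()], or `NULL` for artifact-free data.
#' @param fs sampling rate (Hz, default 200; use 1000 for raw-rate studies).
#' @param sensor_noise_sd per-channel electrode/skin-interface noise SD
#'   (1/f-shaped within 1-80 Hz, default 2).
#' @param white_noise_sd amplifier (flat-spectrum) noise SD (default 0.5;
#'   small relative to the physiological background, as in modern
#'   amplifiers).
#' @param seed integer seed (local to the call).
#' @param n_background number of broadband background dipoles (default 64).
#' @param bg_amp background dipole amplitude (default 1.2e4, giving a
#'   realistic ~10 microvolt channel-level background).
#' @param rhythm_amp default per-band baseline amplitude when a `SourceSpec`
#'   has no `amp` entry (default 6e3).
#' @return list with `eeg` (a `SensorStream` with electrode positions
#'   attached) and `truth` (clean projected EEG, per-source band power curves
#'   on the percentage grid, artifact topographies and waveforms, background
#'   and noise fields).
#' @export
simulate_eeg <- function(timeline, leadfield, sources, artifacts = artifact_spec(),
                         fs = 200, sensor_noise_sd = 2, white_noise_sd = 0.5,
                         seed = 1, n_background = 64, bg_amp = 1.2e4,
                         rhythm_amp = 6e3) {
  stopifnot(inherits(timeline, "GaitTimeline"), inherits(leadfield, "LeadField"))
  nch <- dim(leadfield$gain)[1]
  nsrc <- dim(leadfield$gain)[2]
  for (sp in sources) {
    if (sp$voxel < 1 || sp$voxel > nsrc)
      stop("dimension error: source voxel index outside the grid")
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old))

  dur <- timeline_duration(timeline)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  n <- length(t)
  phi <- timeline_phase(timeline, t)
  grid_pct <- seq(0, 100, length.out = 200)
  be <- band_edges()

  X <- matrix(0, nch, n)
  power_curves <- list()
  source_signals <- matrix(0, length(sources), n)
  for (si in seq_along(sources)) {
    sp <- sources[[si]]
    g <- leadfield$gain[, sp$voxel, ] %*% sp$orientation   # nch x 1
    sig <- numeric(n)
    pc <- list()
    for (b in names(sp$mod)) {
      lohi <- be[[b]]
      hi <- min(lohi[2], 0.45 * fs)
      carrier <- bandlimited_noise(n, fs, lohi[1], hi)
      a0 <- if (!is.null(sp$amp) && b %in% names(sp$amp)) sp$amp[[b]] else rhythm_amp
      amp <- a0 * pmax(1 + sp$mod[[b]](phi), 0)
      sig <- sig + carrier * amp
      pc[[b]] <- (a0 * pmax(1 + sp$mod[[b]](grid_pct / 100), 0))^2
    }
    source_signals[si, ] <- sig
    X <- X + g %*% matrix(sig, 1)
    power_curves[[si]] <- pc
  }

  # broadband background dipoles
  if (n_background > 0) {
    bg_vox <- sample.int(nsrc, min(n_background, nsrc), replace = n_background > nsrc)
    for (v in bg_vox) {
      orient <- rnorm(3); orient <- orient / sqrt(sum(orient^2))
      g <- leadfield$gain[, v, ] %*% orient
      X <- X + g %*% matrix(bg_amp * bandlimited_noise(n, fs, 1, min(80, 0.45 * fs),
                                                       slope = -0.5), 1)
    }
  }
  clean <- X

  topo_all <- artifact_topographies(leadfield$electrodes_mm)
  art_wave <- matrix(0, 3, n, dimnames = list(colnames(topo_all), NULL))
  used <- logical(3)
  if (!is.null(artifacts)) {
    stopifnot(inherits(artifacts, "ArtifactSpec"))
    if (artifacts$blink_rate > 0 && artifacts$blink_amp > 0) {
      n_blink <- stats::rpois(1, artifacts$blink_rate * dur)
      if (n_blink > 0) {
        times <- sort(runif(n_blink, 1, dur - 1))
        w <- numeric(n)
        kern <- biexp_kernel(fs)
        for (tc in times) {
          i0 <- round(tc * fs) + 1
          idx <- i0:min(i0 + length(kern) - 1, n)
          w[idx] <- w[idx] + kern[seq_along(idx)]
        }
        art_wave["blink", ] <- artifacts$blink_amp * w
        used[1] <- TRUE
      }
    }
    if (artifacts$motion_amp > 0) {
      f_step <- 2 * timeline$cadence
      art_wave["motion", ] <- artifacts$motion_amp *
        sin(2 * pi * f_step * t) * (1 + 0.25 * sin(2 * pi * 0.2 * t))
      used[2] <- TRUE
    }
    if (artifacts$myo_amp > 0) {
      myo <- bandlimited_noise(n, fs, 30, min(80, 0.45 * fs))
      art_wave["myogenic", ] <- artifacts$myo_amp * myo *
        (1 + 0.3 * sin(2 * pi * timeline$cadence * t))
      used[3] <- TRUE
    }
    X <- X + topo_all %*% art_wave
  }

  noise <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    noise[ch, ] <- sensor_noise_sd *
      bandlimited_noise(n, fs, 1, min(80, 0.45 * fs), slope = -0.5) +
      rnorm(n, sd = white_noise_sd)
  }
  X <- X + noise

  eeg <- sensor_stream(X, fs, sprintf("E%03d", seq_len(nch)), kind = "eeg",
                       units = "uV", pos = leadfield$electrodes_mm)
  truth <- list(
    clean_eeg = clean, t = t, phi = phi, grid = grid_pct,
    source_signals = source_signals,
    power_curves = power_curves,
    sources = sources,
    artifact_topos = topo_all[, used, drop = FALSE],
    artifact_waveforms = art_wave[used, , drop = FALSE],
    sensor_noise_sd = sensor_noise_sd
  )
  list(eeg = eeg, truth = truth)
}

#' Default bilateral sensorimotor source specification
#'
#' Two sources at the most superior lateral grid voxels (left/right "M1").
#' Alpha and beta amplitudes decrease while the contralateral leg's flexor
#' muscles (vastus, biceps femoris, tibialis) are active, i.e. during the
#' contralateral swing and surrounding double support; gamma shows a smaller
#' modulation of opposite sign. This yields contralateral-negative /
#' ipsilateral-positive alpha-beta NMC with the gastrocnemius reversed.
#'
#' @param leadfield a `LeadField`.
#' @param mod_depth alpha/beta amplitude modulation depth (default 0.4).
#' @param gamma_depth gamma modulation depth, reversed sign (default 0.15).
#' @return list of two [source_spec()] (left, right).
#' @export
default_source_specs <- function(leadfield, mod_depth = 0.4,
                                 gamma_depth = 0.15) {
  grid <- leadfield$grid_mm
  target_l <- c(min(grid[, 1]), stats::median(grid[, 2]), max(grid[, 3]))
  target_r <- c(max(grid[, 1]), stats::median(grid[, 2]), max(grid[, 3]))
  vox_of <- function(target) {
    which.min(rowSums((grid - matrix(target, nrow(grid), 3, byrow = TRUE))^2))
  }
  flexor_comp <- function(side) {
    phi0 <- seq(0, 1, length.out = 1024)
    v <- muscle_activation("vastus", side, phi0) +
      muscle_activation("biceps", side, phi0) +
      muscle_activation("tibialis", side, phi0)
    v <- v - mean(v)
    v <- v / max(abs(v))
    function(phi) approx(phi0, v, xout = phi %% 1, rule = 2)$y
  }
  make_mod <- function(contra_side) {
    comp <- flexor_comp(contra_side)
    list(alpha = function(phi) -mod_depth * comp(phi),
         beta  = function(phi) -mod_depth * comp(phi),
         gamma = function(phi)  gamma_depth * comp(phi))
  }
  # per-band baseline amplitudes: alpha/beta spectral density well above the
  # 1/f background (a clear sensorimotor rhythm bump, as in real EEG); gamma
  # deliberately weak, as gait-related gamma is in recordings
  amps <- c(alpha = 2e4, beta = 2.6e4, gamma = 5e3)
  list(
    left  = source_spec(vox_of(target_l), make_mod("r"), amp = amps),
    right = source_spec(vox_of(target_r), make_mod("l"), amp = amps)
  )
}
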