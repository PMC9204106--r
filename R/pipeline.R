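# End-to-end orchestration: simulate a participant's MoBI session, run the
# body and brain pipelines, and assemble group-level NKC/NMC results.

#' Simulate a complete MoBI dataset on disk
#'
#' Writes EEG as EDF, body sensors as TSV, the lead field as JSON and the
#' ground truth (events, envelopes) as JSON, emulating a walking session.
#'
#' @param out_dir output directory (created if needed).
#' @param n_cycles gait cycles to simulate (default 120, about 2 min at
#'   cadence 1).
#' @param cadence cycles/s (default 1).
#' @param n_channels EEG montage size (default 32; set 128 for full-scale
#'   emulation).
#' @param fs_eeg EEG rate (default 1000 Hz).
#' @param seed integer seed.
#' @return invisible list of written paths.
#' @export
simulate_mobi <- function(out_dir, n_cycles = 120, cadence = 1,
                          n_channels = 32, fs_eeg = 1000, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tl <- make_timeline(cadence, n_cycles, duration_cv = 0.03, seed = seed)
  body <- simulate_body(tl, seed = seed + 1)
  lf <- make_lead_field(n_channels)
  ee <- simulate_eeg(tl, lf, default_source_specs(lf), artifact_spec(),
                     fs = fs_eeg, seed = seed + 2)
  dur <- timeline_duration(tl)
  pulse_eeg <- make_pulse_stream(dur, fs_eeg)
  pulse_body <- make_pulse_stream(dur, 148)

  eeg <- ee$eeg
  eeg$data <- rbind(eeg$data, pulse_eeg$data[1, seq_len(ncol(eeg$data))])
  eeg <- sensor_stream(eeg$data, fs_eeg, c(ee$eeg$labels, "sync_pulse"),
                       kind = "eeg", units = "uV")
  paths <- list(eeg = file.path(out_dir, "eeg.edf"))
  write_eeg(eeg, paths$eeg)
  for (nm in names(body$accel)) {
    paths[[paste0("accel_", nm)]] <- file.path(out_dir, paste0("accel_", nm, ".tsv"))
    write_body_tsv(body$accel[[nm]], paths[[paste0("accel_", nm)]])
  }
  for (nm in names(body$emg)) {
    paths[[paste0("emg_", nm)]] <- file.path(out_dir, paste0("emg_", nm, ".tsv"))
    write_body_tsv(body$emg[[nm]], paths[[paste0("emg_", nm)]])
  }
  paths$pulse_body <- file.path(out_dir, "pulse_body.tsv")
  write_body_tsv(pulse_body, paths$pulse_body)
  paths$leadfield <- file.path(out_dir, "leadfield.json")
  write_lead_field(lf, paths$leadfield)
  paths$events <- file.path(out_dir, "ground_truth_events.tsv")
  write_events_tsv(body$truth$events, paths$events)
  invisible(paths)
}

#' Inverse operator with noise-appropriate regularization
#'
#' [eloreta_fit()]'s default regularization (1e-3 of the mean gain-Gram
#' eigenvalue) is the noiseless-analysis setting; for data with realistic
#' sensor and background noise the pipeline uses a stronger value, by default
#' 0.1 of the mean Gram eigenvalue, which keeps point-source localization
#' intact while limiting noise amplification at the voxel level.
#'
#' @param leadfield a `LeadField`.
#' @param alpha_frac regularization as a fraction of the mean gain-Gram
#'   eigenvalue (default 0.1).
#' @return an `InverseOperator`.
#' @export
pipeline_inverse <- function(leadfield, alpha_frac = 0.1) {
  gram_mean <- sum(leadfield$gain^2) / dim(leadfield$gain)[1]
  eloreta_fit(leadfield, alpha = alpha_frac * gram_mean)
}

#' Per-participant body-envelope statistics
#'
#' Simulates one participant's body signals, detects gait events, computes
#' velocity and EMG cycle envelopes for every sensor and their cross-sensor
#' correlation inputs.
#'
#' @param seed participant seed.
#' @param n_cycles,cadence,noise_sd simulation parameters.
#' @param use_truth_events use planted instead of detected events (faster,
#'   used when event detection is not under study).
#' @param grid_n percentage-grid points.
#' @return list with `velocity` and `emg`: named lists of `CycleEnvelope`s,
#'   plus `events`.
#' @export
participant_envelopes <- function(seed, n_cycles = 60, cadence = 1,
                                  noise_sd = 0.05, use_truth_events = TRUE,
                                  grid_n = 200) {
  tl <- make_timeline(cadence, n_cycles, duration_cv = 0.03, seed = seed)
  body <- simulate_body(tl, noise_sd = noise_sd, seed = seed + 1000)
  events <- if (use_truth_events) body$truth$events else
    detect_events(body$accel$ankle_l, body$accel$ankle_r)
  vel <- list()
  for (nm in names(body$accel)) {
    tot <- total_acceleration(body$accel[[nm]])
    v <- velocity_from_accel(tot)
    env <- envelope(v, 148)    # velocity is already slow; keep native rate
    env$labels <- nm
    vel[[nm]] <- standardize_to_cycle(env, events, grid_n,
                                      signal_type = "velocity")
  }
  emg <- list()
  for (nm in names(body$emg)) {
    pe <- preprocess_emg(body$emg[[nm]])
    env <- envelope(pe, 200)
    env$labels <- nm
    emg[[nm]] <- standardize_to_cycle(env, events, grid_n,
                                      signal_type = "emg")
  }
  list(velocity = vel, emg = emg, events = events, truth = body$truth)
}

#' Per-participant brain-body connectivity (NKC and NMC)
#'
#' Runs the full brain pipeline for one simulated participant: EEG
#' simulation, three-stage artifact attenuation with the ground-truth
#' backend, average reference, eLORETA, bilateral M1 ROI extraction,
#' gait-locked spectrograms and frequency-wise correlation with the body
#' envelopes, aggregated to alpha/beta/gamma bands.
#'
#' @param seed participant seed.
#' @param leadfield shared `LeadField`.
#' @param inv_op shared `InverseOperator` from [eloreta_fit()].
#' @param n_cycles,cadence simulation parameters.
#' @param fs EEG analysis rate (default 200 Hz; the EEG is simulated at this
#'   rate directly).
#' @param envelopes optional precomputed [participant_envelopes()] result for
#'   this seed (recomputed when `NULL`).
#' @return list with `nmc` and `nkc`: band x sensor x hemisphere arrays of r
#'   values, plus `events` and the screening `report`.
#' @export
participant_connectivity <- function(seed, leadfield, inv_op, n_cycles = 60,
                                     cadence = 1, fs = 200,
                                     envelopes = NULL) {
  tl <- make_timeline(cadence, n_cycles, duration_cv = 0.03, seed = seed)
  if (is.null(envelopes))
    envelopes <- participant_envelopes(seed, n_cycles, cadence)
  events <- envelopes$events
  specs <- default_source_specs(leadfield)
  ee <- simulate_eeg(tl, leadfield, specs, artifact_spec(), fs = fs,
                     seed = seed + 2000)
  clean <- attenuate_artifacts(ee$eeg, backend_oracle(ee$truth$artifact_topos))
  clean <- average_reference(clean)
  src <- apply_inverse(inv_op, clean)
  grid <- leadfield$grid_mm
  roi_sig <- list()
  for (h in c("left", "right")) {
    vox <- specs[[h]]$voxel
    vox_sel <- which(sqrt(rowSums((grid - matrix(grid[vox, ], nrow(grid), 3,
                                                 byrow = TRUE))^2)) <= 6 + 1e-9)
    vs <- t(vapply(vox_sel, function(v) collapse_dipole(src[v, , ]),
                   numeric(dim(src)[3])))
    roi_sig[[h]] <- extract_roi(vs, roi_spec("M1", h, grid[vox, ]),
                                grid[vox_sel, , drop = FALSE])
  }
  freqs <- cwt_freqs(fs)
  bands <- names(band_edges())
  muscles <- names(envelopes$emg)
  vel_sensors <- names(envelopes$velocity)
  nmc <- array(NA_real_, c(length(bands), length(muscles), 2),
               dimnames = list(bands, muscles, c("left", "right")))
  nkc <- array(NA_real_, c(length(bands), length(vel_sensors), 2),
               dimnames = list(bands, vel_sensors, c("left", "right")))
  for (h in c("left", "right")) {
    spg <- gait_spectrogram(roi_sig[[h]], fs, events, grid_n = 200,
                            freqs = freqs)
    for (m in muscles) {
      prof <- connectivity_profile(spg, envelopes$emg[[m]])
      nmc[, m, h] <- band_aggregate(prof, freqs)
    }
    for (s in vel_sensors) {
      prof <- connectivity_profile(spg, envelopes$velocity[[s]])
      nkc[, s, h] <- band_aggregate(prof, freqs)
    }
  }
  list(nmc = nmc, nkc = nkc, events = events,
       report = attr(clean, "report"))
}

#' Expected NMC sign pattern of the default simulation
#'
#' Contralateral-negative / ipsilateral-positive alpha-beta couplings for the
#' flexor muscles (vastus, biceps femoris, tibialis anterior), reversed for
#' the gastrocnemius.
#'
#' @param muscles muscle sensor names as produced by the simulator.
#' @return sign matrix (muscle x hemisphere) with values -1/+1.
#' @export
expected_nmc_signs <- function(muscles = body_sensor_names()[1:8]) {
  out <- matrix(0, length(muscles), 2,
                dimnames = list(muscles, c("left", "right")))
  for (m in muscles) {
    side <- if (grepl("_r$", m)) "r" else "l"
    gast <- grepl("gastrocnemius", m)
    # left hemisphere is contralateral to right-side sensors
    contra <- c(left = if (side == "r") TRUE else FALSE,
                right = if (side == "l") TRUE else FALSE)
    for (h in c("left", "right")) {
      s <- if (contra[[h]]) -1 else 1
      if (gast) s <- -s
      out[m, h] <- s
    }
  }
  out
}
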