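# EMG preprocessing, Hilbert envelopes, gait-percentage standardization and
# cross-sensor correlation statistics.

test_that("preprocess_emg band-passes 1-500 Hz and rectifies", {
  fs <- 2000
  t <- (seq_len(20 * fs) - 1) / fs
  tone <- sensor_stream(matrix(sin(2 * pi * 100 * t), 1), fs, "emg1",
                        kind = "emg")
  out <- preprocess_emg(tone)
  expect_true(all(out$data >= 0))
  interior <- out$data[1, (2 * fs):(18 * fs)]
  expect_equal(mean(interior), 2 / pi, tolerance = 0.01)

  dc <- sensor_stream(matrix(1, 1, 10 * fs), fs, "emg1", kind = "emg")
  outdc <- preprocess_emg(dc)
  expect_lt(mean(outdc$data[1, (2 * fs):(8 * fs)]), 0.02)

  slow <- sensor_stream(matrix(rnorm(1000), 1), 500, "emg1", kind = "emg")
  expect_error(preprocess_emg(slow), "1000")
})

test_that("envelope returns the analytic-signal magnitude at the target rate", {
  fs <- 2000; A <- 1.7
  t <- (seq_len(20 * fs) - 1) / fs
  tone <- sensor_stream(matrix(A * sin(2 * pi * 40 * t), 1), fs, "s")
  env <- envelope(tone, 200)
  expect_equal(env$fs, 200)
  interior <- env$data[1, 100:(20 * 200 - 100)]
  expect_true(all(abs(interior - A) / A < 0.02))

  zero <- sensor_stream(matrix(0, 1, fs), fs, "s")
  expect_equal(envelope(zero, 200)$data[1, ], rep(0, 200))

  # AM tone: envelope recovers the modulator
  mod <- 1 + 0.5 * cos(2 * pi * 1 * t)
  am <- sensor_stream(matrix(mod * sin(2 * pi * 40 * t), 1), fs, "s")
  env <- envelope(am, 200)
  tm <- (seq_len(ncol(env$data)) - 1) / 200
  target <- 1 + 0.5 * cos(2 * pi * 1 * tm)
  sel <- 100:(length(tm) - 100)
  rmse <- sqrt(mean((env$data[1, sel] - target[sel])^2))
  expect_lt(rmse / diff(range(target)), 0.03)

  expect_error(envelope(tone, 5000), "target_fs")
})

test_that("identity warp reproduces a single cycle and grid bookkeeping holds", {
  tl <- make_timeline(1, 15, 0, seed = 1)
  ev <- timeline_events(tl)
  fs <- 200
  dur <- timeline_duration(tl)
  t <- seq(0, dur, by = 1 / fs)
  phi <- mobigait:::timeline_phase(tl, t)
  x <- sensor_stream(matrix(1 + sin(2 * pi * phi), 1), fs, "env")
  ce <- standardize_to_cycle(x, ev, 200)
  expect_length(ce$grid, 200)
  expect_equal(range(ce$grid), c(0, 100))
  # identical cycles: the mean equals any single cycle
  expect_lt(max(abs(ce$mean - ce$per_cycle[1, ])), 1e-6)
  expect_equal(ce$mean, 1 + sin(2 * pi * ce$grid / 100), tolerance = 0.01,
               ignore_attr = TRUE)
  expect_error(standardize_to_cycle(x, ev, 10), "grid_n")
})

test_that("warp-and-average reconstructs a template under duration jitter", {
  # one template envelope replayed with +/-10% random cycle-duration jitter
  set.seed(42)
  n_cyc <- 40
  dur <- runif(n_cyc, 0.9, 1.1)
  starts <- 1 + c(0, cumsum(dur[-n_cyc]))
  tl <- structure(list(cycle_starts = starts, durations = dur,
                       event_fractions = c(RTO = 0.12, RHS = 0.5, LTO = 0.62),
                       cadence = 1, duration_cv = 0.06),
                  class = "GaitTimeline")
  ev <- timeline_events(tl)
  fs <- 200
  t <- seq(0, starts[n_cyc] + dur[n_cyc] + 1, by = 1 / fs)
  phi <- mobigait:::timeline_phase(tl, t)
  template <- function(p) 1 + 0.8 * sin(2 * pi * p) + 0.3 * cos(6 * pi * p)
  x <- sensor_stream(matrix(template(phi), 1), fs, "env")
  ce <- standardize_to_cycle(x, ev, 200)
  target <- template(ce$grid / 100)
  rmse <- sqrt(mean((ce$mean - target)^2))
  expect_lt(rmse / diff(range(target)), 0.01)
})

test_that("Fisher transform pair inverts exactly and caps degenerate r", {
  r <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_true(is.finite(fisher_z(1)))
})

test_that("correlate_sensors computes pairwise stats with FDR", {
  grid <- seq(0, 100, length.out = 200)
  mk <- function(curve, id) {
    structure(list(grid = grid, per_cycle = matrix(curve, 1), mean = curve,
                   sensor_id = id, signal_type = "emg", n_dropped = 0L),
              class = "CycleEnvelope")
  }
  set.seed(3)
  base <- sin(2 * pi * grid / 100)
  envs <- lapply(1:6, function(p) {
    list(a = mk(base + rnorm(200, sd = 0.1), "a"),
         b = mk(base + rnorm(200, sd = 0.1), "b"),
         c = mk(rnorm(200), "c"))
  })
  st <- correlate_sensors(envs)
  expect_gt(st$group_r["a", "b"], 0.8)
  expect_lt(st$p["a", "b"], 0.01)
  expect_true(all(st$q[upper.tri(st$q)] >= st$p[upper.tri(st$p)] - 1e-12,
                  na.rm = TRUE))
  expect_length(st$max_abs_z, 6)

  # identical envelopes: r capped, z finite
  envs_id <- lapply(1:4, function(p) list(a = mk(base, "a"), b = mk(base, "b")))
  st_id <- correlate_sensors(envs_id)
  expect_equal(st_id$group_r["a", "b"], 1, tolerance = 1e-6)
  expect_true(all(is.finite(st_id$z_matrix)))
})

test_that("independent white-noise envelopes are not declared dependent", {
  grid <- seq(0, 100, length.out = 200)
  set.seed(11)
  envs <- lapply(1:24, function(p) {
    lapply(stats::setNames(nm = c("u", "v")), function(nm) {
      curve <- rnorm(200)
      structure(list(grid = grid, per_cycle = matrix(curve, 1), mean = curve,
                     sensor_id = nm, signal_type = "emg", n_dropped = 0L),
                class = "CycleEnvelope")
    })
  })
  st <- correlate_sensors(envs)
  expect_gt(st$q["u", "v"], 0.05)
})

test_that("BH adjustment equals the brute-force definition", {
  set.seed(99)
  for (i in 1:25) {
    p <- runif(40)^sample(c(1, 2, 3), 1)
    expect_equal(p.adjust(p, method = "BH"), bh_bruteforce(p),
                 tolerance = 1e-12)
  }
})

test_that("velocity envelopes are more inter-dependent than EMG envelopes", {
  pe <- participant_envelopes(5, n_cycles = 40)
  ipsi_vel <- pe$velocity[c("vastus_l", "biceps_l", "tibialis_l",
                            "gastrocnemius_l", "ankle_l")]
  ipsi_emg <- pe$emg[c("vastus_l", "biceps_l", "tibialis_l",
                       "gastrocnemius_l")]
  vel_curves <- vapply(ipsi_vel, function(e) e$mean, numeric(200))
  emg_curves <- vapply(ipsi_emg, function(e) e$mean, numeric(200))
  zv <- fisher_z(cor(vel_curves)); ze <- fisher_z(cor(emg_curves))
  expect_gt(max(abs(zv[upper.tri(zv)])), max(abs(ze[upper.tri(ze)])))
})
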