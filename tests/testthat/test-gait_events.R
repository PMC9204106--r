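# Velocity estimation and gait-cycle segmentation from ankle accelerometry.

test_that("total_acceleration is the mean-removed Euclidean norm", {
  z <- sensor_stream(rbind(rep(3, 100), rep(4, 100), rep(0, 100)), 100,
                     c("x", "y", "z"), kind = "accel")
  out <- total_acceleration(z)
  expect_equal(out$data[1, ], rep(0, 100), tolerance = 1e-12)

  # single-axis sinusoid amplitude a: |a sin| minus its mean 2a/pi
  fs <- 1000; a <- 2.5
  t <- (0:(20 * fs - 1)) / fs
  s <- sensor_stream(rbind(a * sin(2 * pi * 1 * t), 0 * t, 0 * t), fs,
                     c("x", "y", "z"), kind = "accel")
  out <- total_acceleration(s)
  expect_equal(mean(abs(a * sin(2 * pi * t))), 2 * a / pi, tolerance = 1e-3)
  expect_equal(out$data[1, ], abs(a * sin(2 * pi * t)) -
                 mean(abs(a * sin(2 * pi * t))), tolerance = 1e-9)

  zero <- sensor_stream(matrix(0, 3, 50), 100, c("x", "y", "z"), kind = "accel")
  expect_equal(total_acceleration(zero)$data[1, ], rep(0, 50))

  two <- sensor_stream(matrix(0, 2, 50), 100, c("x", "y"), kind = "accel")
  expect_error(total_acceleration(two), "3 channels")
})

test_that("velocity_from_accel integrates correctly", {
  fs <- 200
  # constant acceleration with the high-pass disabled: v = a t
  const <- sensor_stream(matrix(2, 1, 5 * fs), fs, "ta", kind = "accel")
  v <- velocity_from_accel(const, highpass_hz = 0)
  t <- (seq_len(5 * fs) - 1) / fs
  expect_equal(v$data[1, ], 2 * t, tolerance = 0.02)

  # sinusoid A sin(2 pi f t): velocity amplitude A / (2 pi f)
  A <- 3; f <- 2
  t <- (seq_len(30 * fs) - 1) / fs
  s <- sensor_stream(matrix(A * sin(2 * pi * f * t), 1), fs, "ta", kind = "accel")
  v <- velocity_from_accel(s)
  interior <- v$data[1, (5 * fs):(25 * fs)]
  expect_equal((max(interior) - min(interior)) / 2, A / (2 * pi * f),
               tolerance = 0.02)

  zero <- sensor_stream(matrix(0, 1, fs * 5), fs, "ta", kind = "accel")
  expect_equal(velocity_from_accel(zero)$data[1, ], rep(0, fs * 5))

  expect_error(velocity_from_accel(s, highpass_hz = 200), "Nyquist")
})

test_that("integrated velocity keeps a stable baseline over 10-s windows", {
  fs <- 148
  tl <- make_timeline(1, 60, 0.03, seed = 6)
  body <- simulate_body(tl, noise_sd = 0.1, seed = 6, emg = FALSE)
  v <- velocity_from_accel(total_acceleration(body$accel$ankle_l))
  x <- v$data[1, ]
  sdv <- sd(x)
  win <- 10 * fs
  starts <- seq(1, length(x) - win, by = win)
  baseline <- vapply(starts, function(i) abs(mean(x[i:(i + win - 1)])), 0)
  expect_lt(median(baseline), 0.02 * sdv)
})

test_that("stable-segment selection isolates steady walking", {
  tl <- make_timeline(1, 60, 0.02, seed = 2)
  body <- simulate_body(tl, noise_sd = 0.05, seed = 2, emg = FALSE)
  v <- velocity_from_accel(total_acceleration(body$accel$ankle_l))
  seg <- select_stable_segments(v)
  expect_equal(nrow(seg), 1)
  expect_gt(seg$end[1] - seg$start[1], 0.85 * stream_duration(v))

  # 10-s standstill in the middle: two intervals excluding the gap
  x <- v$data[1, ]
  n <- length(x)
  mid <- floor(n / 2)
  gap <- mid:(mid + 10 * v$fs)
  x2 <- x
  x2[gap] <- rnorm(length(gap), sd = 1e-4)
  v2 <- sensor_stream(matrix(x2, 1), v$fs, "vel", kind = "accel")
  seg2 <- select_stable_segments(v2)
  expect_gte(nrow(seg2), 2)
  gapmid <- (mid + 5 * v$fs) / v$fs
  inside <- any(seg2$start < gapmid & seg2$end > gapmid &
                  seg2$start > gapmid - 4 & seg2$end < gapmid + 4)
  expect_false(inside)

  rest <- sensor_stream(matrix(rnorm(n, sd = 1e-4), 1), v$fs, "vel",
                        kind = "accel")
  expect_equal(nrow(select_stable_segments(rest)), 0)
})

test_that("detect_events recovers planted events and rejects degenerate input", {
  tl <- make_timeline(1, 120, 0.03, seed = 1)
  body <- simulate_body(tl, noise_sd = 0.1, seed = 1, emg = FALSE)
  ev <- detect_events(body$accel$ankle_l, body$accel$ankle_r)
  tr <- body$truth$events
  expect_lt(abs(nrow(ev) - 119), 3)
  errs <- c(event_errors(ev$t_LHS, tr$t_LHS), event_errors(ev$t_RTO, tr$t_RTO),
            event_errors(ev$t_RHS, tr$t_RHS), event_errors(ev$t_LTO, tr$t_LTO))
  expect_gte(mean(abs(errs) < 0.03), 0.95)
  expect_lte(median(abs(errs)), 0.02)

  flat <- sensor_stream(matrix(0, 3, 148 * 20), 148, c("x", "y", "z"),
                        kind = "accel")
  expect_error(detect_events(flat, flat), "segmentation error")
  short <- sensor_stream(matrix(rnorm(3 * 148 * 5), 3), 148,
                         c("x", "y", "z"), kind = "accel")
  expect_error(detect_events(short, short), "10 s")
})

test_that("noiseless constant-cadence cycles are recovered to one sample", {
  tl <- make_timeline(1, 30, 0, seed = 1)
  body <- simulate_body(tl, noise_sd = 0, seed = 1, emg = FALSE)
  ev <- detect_events(body$accel$ankle_l, body$accel$ankle_r)
  expect_true(all(abs(ev$duration - 1) <= 1 / 148 + 1e-9))
})

test_that("cycle durations fall in the 1000-2000 ms walking range for slow cadences", {
  for (cad in c(0.6, 0.9)) {
    tl <- make_timeline(cad, 40, 0.03, seed = 8)
    body <- simulate_body(tl, noise_sd = 0.05, seed = 8, emg = FALSE)
    ev <- detect_events(body$accel$ankle_l, body$accel$ankle_r)
    expect_true(mean(ev$duration >= 1.0 & ev$duration <= 2.0) > 0.9)
  }
})

test_that("gait_event_table enforces ordering and duration invariants", {
  bad <- data.frame(t_LHS = 0, t_RTO = 0.6, t_RHS = 0.5, t_LTO = 0.7,
                    t_LHS_next = 1)
  expect_error(gait_event_table(bad), "ordering")
  long <- data.frame(t_LHS = 0, t_RTO = 1, t_RHS = 2, t_LTO = 2.5,
                     t_LHS_next = 3)
  expect_error(gait_event_table(long), "durations")
  expect_s3_class(gait_event_table(long, validate_durations = FALSE),
                  "GaitEventTable")
})
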