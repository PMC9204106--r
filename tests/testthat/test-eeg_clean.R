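# EEG preprocessing and three-stage artifact screening.

test_that("sample entropy equals the brute-force oracle to 1e-10", {
  set.seed(21)
  for (m in c(1, 2)) {
    for (rf in c(0.1, 0.2)) {
      x <- rnorm(500)
      r <- rf * sd(x)
      expect_equal(sample_entropy(x, m, r), sampen_bruteforce(x, m, r),
                   tolerance = 1e-10)
    }
  }
  # regular signal too (low-entropy branch)
  x <- sin(2 * pi * 5 * (0:499) / 100) + rnorm(500, sd = 0.05)
  expect_equal(sample_entropy(x, 2, 0.2 * sd(x)),
               sampen_bruteforce(x, 2, 0.2 * sd(x)), tolerance = 1e-10)
  expect_true(is.na(sample_entropy(rep(1, 100))))
})

test_that("component scores discriminate the artifact classes", {
  fs <- 200
  n <- 40 * fs
  t <- (seq_len(n) - 1) / fs
  set.seed(5)
  sine <- sin(2 * pi * 2 * t)
  wn <- bandlimited_noise(n, fs, 1, 80)
  blink <- numeric(n)
  ons <- seq(2, 38, by = 5)
  kern <- mobigait:::biexp_kernel(fs)
  for (o in ons) {
    i0 <- round(o * fs)
    blink[i0:(i0 + length(kern) - 1)] <- kern
  }
  blink <- 20 * blink + rnorm(n, sd = 0.5)
  S <- rbind(sine, wn, blink)
  sc <- score_components(S, fs)

  # pure sinusoid: excess kurtosis -1.5, regular (low sample entropy)
  expect_equal(sc$max_win_kurtosis[1], -1.5, tolerance = 0.01)
  expect_lt(sc$mean_win_sampen[1], 0.8)
  expect_true(sc$motion[1])
  expect_false(sc$ocular[1])

  # flat-spectrum 1-80 Hz noise: band ratio near 50/29 > 1
  expect_gt(sc$band_power_ratio[2], 1)
  expect_equal(sc$band_power_ratio[2], 50 / 29, tolerance = 0.25)
  expect_true(sc$myogenic[2])
  expect_false(sc$motion[2])

  # sparse biexponential blink train: window kurtosis above 12
  expect_gt(sc$max_win_kurtosis[3], 12)
  expect_true(sc$ocular[3])
})

test_that("constant components are flagged degenerate, short ones skip entropy", {
  fs <- 200
  S <- rbind(rep(1, 10 * fs), rnorm(10 * fs))
  sc <- score_components(S, fs)
  expect_true(is.na(sc$max_win_kurtosis[1]))
  # 10 s < 20-s entropy window: score omitted
  expect_true(all(is.na(sc$mean_win_sampen)))
})

test_that("bad channels are detected and repaired from neighbours", {
  lf <- test_leadfield()
  tl <- make_timeline(1, 20, 0.02, seed = 4)
  ee <- simulate_eeg(tl, lf, default_source_specs(lf), NULL, fs = 200, seed = 4)
  eeg <- ee$eeg
  set.seed(8)
  eeg$data[7, ] <- rnorm(ncol(eeg$data), sd = sd(eeg$data[7, ]))
  rep7 <- repair_bad_channels(eeg)
  expect_true(eeg$labels[7] %in% attr(rep7, "repaired"))
  # repaired channel now correlates with the montage
  expect_gt(median(abs(cor(rep7$data[7, ], t(rep7$data[-7, ])))), 0.4)

  clean <- repair_bad_channels(ee$eeg)
  expect_length(attr(clean, "repaired"), 0)

  broken <- ee$eeg
  broken$data[1:10, ] <- 0
  expect_error(repair_bad_channels(broken), "quality error")
})

test_that("filter_resample attenuates out-of-band tones and keeps passband", {
  fs <- 1000
  t <- (seq_len(20 * fs) - 1) / fs
  mk <- function(f) sensor_stream(matrix(sin(2 * pi * f * t), 2, 20 * fs,
                                         byrow = TRUE), fs, c("a", "b"))
  hi <- filter_resample(mk(100))
  expect_equal(hi$fs, 200)
  # measure away from the filter's edge transients (half-kernel margins)
  interior <- hi$data[1, (4 * 200):(16 * 200)]
  pow_ratio <- var(interior) / var(sin(2 * pi * 100 * t))
  expect_lt(10 * log10(pow_ratio), -40)

  lo <- filter_resample(mk(10))
  interior <- lo$data[1, 200:(20 * 200 - 200)]
  expect_equal((max(interior) - min(interior)) / 2, 1, tolerance = 0.02)

  slow <- sensor_stream(matrix(rnorm(400), 2), 100, c("a", "b"))
  expect_error(filter_resample(slow), "200")
})

test_that("average reference zeroes the per-sample channel mean and is idempotent", {
  set.seed(2)
  x <- sensor_stream(matrix(rnorm(5 * 100), 5), 100, paste0("c", 1:5))
  ar <- average_reference(x)
  expect_lt(max(abs(colSums(ar$data))), 1e-10)
  ar2 <- average_reference(ar)
  expect_equal(ar2$data, ar$data, tolerance = 1e-12)
  sym <- sensor_stream(rbind(x$data[1, ], -x$data[1, ]), 100, c("p", "n"))
  expect_equal(average_reference(sym)$data, sym$data, tolerance = 1e-12)
})

test_that("oracle-backend attenuation removes exactly the planted artifacts", {
  lf <- test_leadfield()
  tl <- make_timeline(1, 45, 0.03, seed = 13)
  ee <- simulate_eeg(tl, lf, default_source_specs(lf), artifact_spec(),
                     fs = 200, seed = 13)
  cl <- attenuate_artifacts(ee$eeg, backend_oracle(ee$truth$artifact_topos))
  rep <- attr(cl, "report")
  expect_equal(rep$ocular$removed, 1)
  expect_equal(rep$motion$removed, 2)
  expect_equal(rep$myogenic$removed, 3)

  # planted-artifact subspace variance reduced by >= 90%
  Ta <- ee$truth$artifact_topos
  P <- Ta %*% solve(crossprod(Ta), t(Ta))
  v0 <- sum((P %*% ee$eeg$data)^2)
  v1 <- sum((P %*% cl$data)^2)
  expect_gt(1 - v1 / v0, 0.9)
})

test_that("artifact-free data pass through the screening unchanged", {
  lf <- test_leadfield()
  tl <- make_timeline(1, 45, 0.03, seed = 14)
  ee <- simulate_eeg(tl, lf, default_source_specs(lf), NULL, fs = 200,
                     seed = 14)
  cl <- attenuate_artifacts(ee$eeg, backend_oracle(NULL))
  rep <- attr(cl, "report")
  expect_equal(length(rep$ocular$removed), 0)
  expect_equal(length(rep$motion$removed), 0)
  expect_equal(length(rep$myogenic$removed), 0)
  # nothing removed: reconstruction identity
  expect_equal(cl$data, ee$eeg$data, tolerance = 1e-8)
})

test_that("a failing backend skips its stage with a warning", {
  lf <- test_leadfield()
  tl <- make_timeline(1, 25, 0.02, seed = 15)
  ee <- simulate_eeg(tl, lf, default_source_specs(lf), NULL, fs = 200,
                     seed = 15)
  bad <- function(X, fs) stop("no convergence")
  backends <- list(ocular = bad, motion = backend_oracle(NULL),
                   myogenic = backend_oracle(NULL))
  expect_warning(cl <- attenuate_artifacts(ee$eeg, backends), "skipped")
  expect_true(attr(cl, "report")$ocular$skipped)
})

test_that("FastICA backend separates a simple mixture", {
  set.seed(31)
  n <- 4000
  S <- rbind(sin(2 * pi * 3 * (1:n) / 200),
             sign(sin(2 * pi * 0.7 * (1:n) / 200)),
             rnorm(n))
  A <- matrix(rnorm(9), 3)
  X <- A %*% S
  for (ap in c("deflation", "symmetric")) {
    dec <- backend_fastica(ap, seed = 1)(X, 200)
    # each true source matches some component almost perfectly
    cors <- abs(cor(t(dec$S), t(S)))
    expect_true(all(apply(cors, 2, max) > 0.95))
    # reconstruction: mixing x components returns the (centered) data
    Xc <- X - rowMeans(X)
    expect_lt(max(abs(dec$A %*% dec$S - Xc)), 1e-6 * max(abs(Xc)))
  }
})
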