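# CWT spectrograms, NKC/NMC profiles, band aggregation, group statistics,
# ANOVAs and voxel-wise images.

test_that("CWT frequency grid spans 6 octaves x 8 voices within 1-50 Hz", {
  f <- cwt_freqs(200)
  expect_true(all(f >= 1 & f <= 50))
  expect_true(all(diff(f) > 0))
  ratios <- f[-1] / f[-length(f)]
  expect_equal(ratios, rep(2^(1 / 8), length(ratios)), tolerance = 1e-9)
  for (b in list(c(8, 13), c(13, 30), c(30, 50))) {
    expect_gte(sum(f >= b[1] & f < b[2]), 2)
  }
})

test_that("gait spectrogram localizes tones and planted amplitude dips", {
  fs <- 200
  tl <- make_timeline(1, 20, 0, seed = 1)
  ev <- timeline_events(tl)
  dur <- timeline_duration(tl)
  t <- seq(0, dur, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t)
  spg <- gait_spectrogram(tone, fs, ev)
  peak_f <- spg$freqs[which.max(rowMeans(spg$raw_power))]
  expect_equal(peak_f, spg$freqs[which.min(abs(spg$freqs - 10))])
  # constant amplitude: standardized modulation stays small at 10 Hz
  k10 <- which.min(abs(spg$freqs - 10))
  expect_lt(diff(range(spg$raw_power[k10, 10:190])) /
              mean(spg$raw_power[k10, ]), 0.2)

  # 40% amplitude dip inside a fixed cycle window
  phi <- mobigait:::timeline_phase(tl, t)
  dip <- 1 - 0.4 * (phi > 0.3 & phi < 0.5)
  spg2 <- gait_spectrogram(dip * tone, fs, ev)
  min_pos <- spg2$grid[which.min(spg2$power[k10, ])]
  expect_gt(min_pos, 28)
  expect_lt(min_pos, 52)
})

test_that("trial averaging shrinks spurious modulation of stationary noise", {
  fs <- 200
  set.seed(12)
  amp <- function(n_cyc) {
    tl <- make_timeline(1, n_cyc, 0, seed = 2)
    ev <- timeline_events(tl)
    x <- bandlimited_noise(round(timeline_duration(tl) * fs), fs, 1, 80)
    spg <- gait_spectrogram(x, fs, ev)
    k <- which.min(abs(spg$freqs - 10))
    diff(range(spg$raw_power[k, ])) / mean(spg$raw_power[k, ])
  }
  expect_lt(amp(200), amp(20))
})

test_that("connectivity profile and band aggregation behave as defined", {
  fs <- 200
  tl <- make_timeline(1, 12, 0, seed = 1)
  ev <- timeline_events(tl)
  freqs <- cwt_freqs(fs)
  grid <- seq(0, 100, length.out = 200)
  curve <- sin(2 * pi * grid / 100)
  spg <- structure(list(freqs = freqs, grid = grid,
                        power = matrix(curve, length(freqs), 200,
                                       byrow = TRUE),
                        raw_power = NULL, n_cycles = 12),
                   class = "GaitSpectrogram")
  body <- structure(list(grid = grid, mean = curve), class = "CycleEnvelope")
  prof <- connectivity_profile(spg, body)
  expect_equal(unname(prof), rep(1, length(freqs)), tolerance = 1e-12)
  body_neg <- structure(list(grid = grid, mean = -curve),
                        class = "CycleEnvelope")
  expect_equal(unname(connectivity_profile(spg, body_neg)),
               rep(-1, length(freqs)), tolerance = 1e-12)
  body_bad <- structure(list(grid = grid[1:100], mean = curve[1:100]),
                        class = "CycleEnvelope")
  expect_error(connectivity_profile(spg, body_bad), "grid mismatch")

  # independent random curves stay near zero
  set.seed(6)
  worst <- max(abs(replicate(50, cor(rnorm(200), rnorm(200)))))
  expect_lt(worst, 0.3)

  ba <- band_aggregate(rep(0.4, length(freqs)), freqs)
  expect_equal(unname(ba), c(0.4, 0.4, 0.4), tolerance = 1e-12)

  prof2 <- numeric(length(freqs))
  prof2[freqs >= 9 & freqs <= 11] <- 0.5
  ba2 <- band_aggregate(prof2, freqs)
  expect_gt(ba2["alpha"], 0.1)
  expect_equal(unname(ba2["beta"]), 0, tolerance = 1e-12)

  low <- freqs[freqs <= 12]
  expect_error(band_aggregate(rep(0.1, length(low)), low),
               "fewer than 2 CWT frequencies")
})

test_that("group_stats produces calibrated z/t/p/q", {
  # all-zero cells: t = 0, p = 1
  r0 <- array(0, c(5, 2))
  g0 <- group_stats(r0)
  expect_equal(as.numeric(g0$t), c(0, 0))
  expect_equal(as.numeric(g0$p), c(1, 1))

  # planted mean z = 0.6, sd = 0.2, n = 24: q below 0.001
  set.seed(20)
  z <- matrix(rnorm(24 * 4, mean = c(0.6, 0, 0, 0), sd = 0.2), 24, 4,
              byrow = TRUE)
  g <- group_stats(tanh(z))
  expect_lt(g$q[1], 0.001)
  expect_gt(min(g$q[2:4]), 0.05)
  expect_equal(g$n, 24)
  expect_error(group_stats(array(0.1, c(2, 3))), "3 participants")
})

test_that("one-factor ANOVA F equals t^2 and flat data give F = 0", {
  set.seed(30)
  df <- data.frame(value = c(rnorm(12, 0), rnorm(12, 0.8)),
                   g = rep(c("a", "b"), each = 12))
  tab <- anova_nway(df, "g")
  tt <- t.test(value ~ g, data = df, var.equal = TRUE)
  expect_equal(tab$F[tab$term == "g"], unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(tab$p[tab$term == "g"], tt$p.value, tolerance = 1e-9)

  flat <- data.frame(value = rep(1, 24), g = rep(c("a", "b"), each = 12))
  tf <- anova_nway(flat, "g")
  expect_equal(tf$F[1], 0)
  expect_equal(tf$p[1], 1)

  unb <- data.frame(value = rnorm(5), g = c("a", "a", "a", "b", "b"))
  expect_error(anova_nway(unb, "g"), "unbalanced")
})

test_that("planted factor effects are recovered by the n-way ANOVA", {
  set.seed(31)
  lay <- expand.grid(participant = 1:24, sensor = paste0("s", 1:4),
                     band = c("alpha", "beta", "gamma"))
  shift <- c(s1 = 0, s2 = 0.3, s3 = -0.3, s4 = 0.6)
  lay$value <- rnorm(nrow(lay), sd = 0.2) + shift[lay$sensor]
  tab <- anova_nway(lay, c("sensor", "band"))
  expect_lt(tab$p[tab$term == "sensor"], 0.001)
  expect_gt(tab$p[tab$term == "band"], 0.05)
})

test_that("voxel-wise images recover a planted single-voxel sensor effect", {
  set.seed(32)
  np <- 24; nv <- 60
  bands <- c("alpha", "beta"); sensors <- paste0("s", 1:3)
  r <- array(rnorm(np * 2 * 3 * nv, sd = 0.08),
             dim = c(np, 2, 3, nv),
             dimnames = list(NULL, bands, sensors, NULL))
  target <- 17
  for (s in seq_along(sensors)) r[, , s, target] <- r[, , s, target] +
    c(-0.35, 0, 0.35)[s]
  img <- connectivity_images(r)
  expect_identical(which(img$anova[["sensor"]]$mask), as.integer(target))
  expect_equal(sum(img$anova[["band"]]$mask), 0)
  expect_equal(sum(img$anova[["band:sensor"]]$mask), 0)

  # group average of identical participant images equals any one image
  r1 <- array(rep(rnorm(2 * 3 * nv), each = np), dim = c(np, 2, 3, nv),
              dimnames = dimnames(r))
  img1 <- connectivity_images(r1)
  expect_equal(img1$group_mean, array(r1[1, , , ], dim = c(2, 3, nv)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # display threshold zeroes sub-threshold voxels only in the rendered copy
  expect_true(all(img$display[abs(img$group_mean) <= 0.2] == 0))

  r_bad <- r; r_bad[1, 1, 1, 3] <- NA
  expect_error(connectivity_images(r_bad), "voxel 3")
})

test_that("voxel-wise ANOVA equals anova_nway at a single voxel", {
  set.seed(33)
  np <- 8; nv <- 3
  r <- array(rnorm(np * 2 * 2 * nv, sd = 0.1), dim = c(np, 2, 2, nv),
             dimnames = list(NULL, c("alpha", "beta"), c("s1", "s2"), NULL))
  img <- connectivity_images(r)
  v <- 2
  df <- expand.grid(participant = seq_len(np), band = c("alpha", "beta"),
                    sensor = c("s1", "s2"))
  df$value <- as.vector(r[, , , v])
  tab <- anova_nway(df, c("band", "sensor"), interactions = TRUE)
  expect_equal(img$anova[["sensor"]]$F[v], tab$F[tab$term == "sensor"],
               tolerance = 1e-12)
  expect_equal(img$anova[["band:sensor"]]$F[v],
               tab$F[tab$term == "band:sensor"], tolerance = 1e-12)
})

test_that("voxel images serialize to NIfTI on the source grid", {
  lf <- test_leadfield()
  vals <- seq_len(nrow(lf$grid_mm)) / 10
  p <- tempfile(fileext = ".nii")
  write_voxel_nifti(vals, lf, p)
  img <- RNifti::readNifti(p)
  expect_identical(dim(img), c(5L, 5L, 4L))
  expect_equal(sort(as.numeric(img)), sort(vals), tolerance = 1e-6)
})
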