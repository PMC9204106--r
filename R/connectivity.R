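# Frequency-resolved gait-locked neural power modulations (analytic Morlet
# CWT, 6 octaves x 8 voices, 1-50 Hz), their correlation with body envelopes
# (neurokinematic / neuromuscular connectivity), group statistics, fixed-
# effects ANOVAs and voxel-wise connectivity images.

#' CWT frequency grid
#'
#' Geometric grid descending from `f_max` over `n_octaves` octaves with
#' `voices` voices per octave, masked to `[f_min, f_max]` and the Nyquist
#' range.
#'
#' @param fs sampling rate (Hz).
#' @param f_min,f_max analysis band (Hz), default 1-50.
#' @param n_octaves,voices wavelet discretization (default 6 x 8).
#' @return increasing numeric vector of frequencies (Hz).
#' @export
cwt_freqs <- function(fs, f_min = 1, f_max = 50, n_octaves = 6, voices = 8) {
  f <- f_max * 2^(-(0:(n_octaves * voices)) / voices)
  f <- f[f >= f_min & f <= min(f_max, 0.5 * fs)]
  sort(f)
}

#' Analytic Morlet continuous wavelet transform
#'
#' Frequency-domain implementation; the wavelet at scale `s` has Fourier
#' transform `exp(-(s*w - w0)^2 / 2)` for positive frequencies (analytic),
#' with `s = w0 / (2 pi f)`.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param freqs analysis frequencies (Hz), e.g. [cwt_freqs()].
#' @param omega0 Morlet centre frequency parameter (default 6).
#' @return complex matrix, `length(freqs)` x `length(x)`.
#' @export
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  nf <- next_pow2(2 * n)
  X <- fft(c(x - mean(x), numeric(nf - n)))
  w <- 2 * pi * fs * c(seq(0, floor(nf / 2)), seq(-ceiling(nf / 2) + 1, -1)) / nf
  out <- matrix(0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])
    psi <- numeric(nf)
    pos <- w > 0
    psi[pos] <- exp(-0.5 * (s * w[pos] - omega0)^2)
    y <- fft(X * psi, inverse = TRUE) / nf
    out[k, ] <- y[seq_len(n)]
  }
  out
}

#' Gait-cycle-locked spectrogram of a source or ROI signal
#'
#' CWT magnitude-squared power per frequency, warped to the gait-percentage
#' grid with the same anchor warping as the body envelopes, averaged over
#' cycles and per-frequency z-scored across the grid.
#'
#' @param x numeric vector or one-channel `SensorStream` (200 Hz typical).
#' @param fs sampling rate (ignored when `x` is a stream).
#' @param events a [gait_event_table()].
#' @param grid_n percentage-grid points (default 200).
#' @param freqs analysis frequencies; default [cwt_freqs()] for `fs`.
#' @return a `GaitSpectrogram`: `freqs`, `grid`, `power` (freqs x grid,
#'   standardized), `raw_power` (freqs x grid, pre-standardization),
#'   `n_cycles`.
#' @export
gait_spectrogram <- function(x, fs = NULL, events, grid_n = 200,
                             freqs = NULL) {
  if (inherits(x, "SensorStream")) {
    fs <- x$fs
    start <- x$start_time
    x <- x$data[1, ]
  } else start <- 0
  stopifnot(!is.null(fs), inherits(events, "GaitEventTable"))
  if (is.null(freqs)) freqs <- cwt_freqs(fs)
  W <- morlet_cwt(x, fs, freqs)
  P <- Mod(W)^2
  raw <- matrix(NA_real_, length(freqs), grid_n)
  std <- matrix(NA_real_, length(freqs), grid_n)
  n_cyc <- NA_integer_
  for (k in seq_along(freqs)) {
    ps <- sensor_stream(matrix(P[k, ], 1), fs, "power", kind = "eeg",
                        start_time = start)
    ce <- standardize_to_cycle(ps, events, grid_n)
    if (is.na(n_cyc)) n_cyc <- nrow(ce$per_cycle)
    raw[k, ] <- ce$mean
    s <- sd(ce$mean)
    std[k, ] <- if (s > 0) (ce$mean - mean(ce$mean)) / s else 0
  }
  if (n_cyc < 3) stop("fewer than 3 usable cycles for the spectrogram")
  structure(list(freqs = freqs, grid = ce$grid, power = std, raw_power = raw,
                 n_cycles = n_cyc),
            class = "GaitSpectrogram")
}

#' Frequency-wise brain-body connectivity profile
#'
#' Pearson correlation over the gait-percentage grid between the standardized
#' neural power modulation at each frequency and one body envelope.
#'
#' @param spec a `GaitSpectrogram`.
#' @param body a `CycleEnvelope` on the identical grid.
#' @return numeric vector of r values, named by frequency.
#' @export
connectivity_profile <- function(spec, body) {
  stopifnot(inherits(spec, "GaitSpectrogram"), inherits(body, "CycleEnvelope"))
  if (length(spec$grid) != length(body$grid) ||
      max(abs(spec$grid - body$grid)) > 1e-9)
    stop("grid mismatch between spectrogram and body envelope")
  r <- apply(spec$power, 1, function(p) {
    if (sd(p) == 0 || sd(body$mean) == 0) return(NA_real_)
    cor(p, body$mean)
  })
  names(r) <- sprintf("%.3f", spec$freqs)
  r
}

#' Aggregate a frequency profile into alpha/beta/gamma bands
#'
#' Mean r over in-band frequencies; band edges half-open `[lo, hi)`:
#' alpha 8-13, beta 13-30, gamma 30-50 Hz.
#'
#' @param profile named r vector from [connectivity_profile()].
#' @param freqs frequencies (Hz) matching `profile`.
#' @return named numeric vector `c(alpha=, beta=, gamma=)`.
#' @export
band_aggregate <- function(profile, freqs) {
  stopifnot(length(profile) == length(freqs))
  be <- band_edges()
  out <- vapply(names(be), function(b) {
    sel <- freqs >= be[[b]][1] & freqs < be[[b]][2]
    if (sum(sel) < 2)
      stop(sprintf("band '%s' covered by fewer than 2 CWT frequencies", b))
    mean(profile[sel], na.rm = TRUE)
  }, 0)
  names(out) <- names(be)
  out
}

#' Group statistics over per-participant connectivity values
#'
#' Fisher z per cell, one-sample t-test across participants, and
#' Benjamini-Hochberg FDR over all cells of the array (one declared family).
#'
#' @param r_arr numeric array whose first dimension is participants; the
#'   remaining dimensions index cells (sensor, band, ROI, ...).
#' @return a `ConnectivityStats` list: `group_r`, `z_mean`, `t`, `p`, `q`
#'   (arrays over the cell dimensions), `n`.
#' @export
group_stats <- function(r_arr) {
  d <- dim(r_arr)
  if (is.null(d)) d <- c(length(r_arr), 1)
  np <- d[1]
  if (np < 3) stop("need at least 3 participants")
  cell_dim <- d[-1]
  ncell <- prod(cell_dim)
  rm_ <- matrix(r_arr, np, ncell)
  z <- fisher_z(rm_)
  zbar <- colMeans(z)
  tv <- pv <- rep(NA_real_, ncell)
  for (j in seq_len(ncell)) {
    zj <- z[, j]
    zj <- zj[is.finite(zj)]
    if (length(zj) >= 3 && sd(zj) > 0) {
      tt <- t.test(zj)
      tv[j] <- unname(tt$statistic)
      pv[j] <- tt$p.value
    } else if (length(zj) >= 3 && all(zj == 0)) {
      tv[j] <- 0; pv[j] <- 1      # exactly-null cell
    }                              # constant nonzero cell stays NA (flagged)
  }
  qv <- rep(NA_real_, ncell)
  ok <- !is.na(pv)
  qv[ok] <- p.adjust(pv[ok], method = "BH")
  shape <- function(v) array(v, dim = cell_dim,
                             dimnames = dimnames(r_arr)[-1])
  structure(list(group_r = shape(fisher_z_inv(zbar)), z_mean = shape(zbar),
                 t = shape(tv), p = shape(pv), q = shape(qv), n = np),
            class = "ConnectivityStats")
}

#' Fixed-effects n-way ANOVA on connectivity cells
#'
#' Balanced fixed-effects linear model with sum-to-zero coding, participants
#' as replicates. The four-way variant fits main effects only; the two-way
#' variant includes the interaction.
#'
#' @param df data.frame with a numeric `value` column and factor columns.
#' @param factors character vector of factor column names.
#' @param interactions include all interactions (default FALSE: main effects
#'   only).
#' @return data.frame with `term`, `df`, `sumsq`, `F`, `p`.
#' @export
anova_nway <- function(df, factors, interactions = FALSE) {
  stopifnot("value" %in% names(df), all(factors %in% names(df)))
  for (f in factors) df[[f]] <- factor(df[[f]])
  counts <- table(df[, factors, drop = FALSE])
  if (length(unique(as.vector(counts))) != 1)
    stop("unbalanced layout: every factor-level combination needs the same replicate count")
  rhs <- paste(factors, collapse = if (interactions) " * " else " + ")
  ctr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- aov(stats::as.formula(paste("value ~", rhs)), data = df,
             contrasts = ctr)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  out <- data.frame(term = terms, df = sm[["Df"]], sumsq = sm[["Sum Sq"]],
                    F = sm[["F value"]], p = sm[["Pr(>F)"]],
                    row.names = NULL)
  # a perfectly flat response is 0/0 up to rounding noise: F = 0, p = 1
  if (var(df$value) <= 1e-20 * (mean(df$value)^2 + 1)) {
    keep <- out$term != "Residuals"
    out$F[keep] <- 0
    out$p[keep] <- 1
  }
  out
}

#' Voxel-wise connectivity images and ANOVA maps
#'
#' Group-average r image per (band, sensor); per-voxel two-way ANOVA
#' (band x sensor, with interaction) across participants; F-maps converted to
#' p, FDR-corrected across voxels within each effect, and binarized at
#' `q_thr`. The display threshold `r_thr` is applied only to the rendered
#' group maps.
#'
#' @param r_vox numeric array participants x bands x sensors x voxels (with
#'   dimnames for bands and sensors).
#' @param q_thr significance threshold on FDR-adjusted p (default 0.001).
#' @param r_thr display threshold for rendered maps (default 0.2).
#' @return a `ConnectivityImages` list: `group_mean` (band x sensor x voxel),
#'   `display` (thresholded copy), `anova` (list per effect with `F`, `p`,
#'   `q`, `mask` vectors over voxels), `q_thr`, `r_thr`.
#' @export
connectivity_images <- function(r_vox, q_thr = 0.001, r_thr = 0.2) {
  d <- dim(r_vox)
  stopifnot(length(d) == 4)
  if (any(!is.finite(r_vox))) {
    bad <- which(apply(r_vox, 4, function(m) any(!is.finite(m))))[1]
    stop(sprintf("missing connectivity cell at voxel %d", bad))
  }
  np <- d[1]; nb <- d[2]; ns <- d[3]; nv <- d[4]
  bands <- dimnames(r_vox)[[2]] %||% paste0("band", seq_len(nb))
  sensors <- dimnames(r_vox)[[3]] %||% paste0("sensor", seq_len(ns))
  group_mean <- apply(r_vox, c(2, 3, 4), mean)
  display <- group_mean
  display[abs(display) <= r_thr] <- 0
  lay <- expand.grid(participant = seq_len(np), band = bands,
                     sensor = sensors)
  effects <- c("band", "sensor", "band:sensor")
  maps <- lapply(effects, function(e) list(F = rep(NA_real_, nv),
                                           p = rep(NA_real_, nv)))
  names(maps) <- effects
  for (v in seq_len(nv)) {
    dfv <- lay
    dfv$value <- as.vector(r_vox[, , , v])
    tab <- anova_nway(dfv, c("band", "sensor"), interactions = TRUE)
    for (e in effects) {
      row <- which(tab$term == e)
      maps[[e]]$F[v] <- tab$F[row]
      maps[[e]]$p[v] <- tab$p[row]
    }
  }
  for (e in effects) {
    maps[[e]]$q <- p.adjust(maps[[e]]$p, method = "BH")
    maps[[e]]$mask <- maps[[e]]$q < q_thr
  }
  structure(list(group_mean = group_mean, display = display, anova = maps,
                 bands = bands, sensors = sensors, q_thr = q_thr,
                 r_thr = r_thr),
            class = "ConnectivityImages")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a voxel image to NIfTI on the lead-field grid
#'
#' Values are placed into the regular source-grid volume; the voxel size is
#' the grid spacing.
#'
#' @param values numeric vector, one value per grid voxel.
#' @param leadfield the `LeadField` whose grid defines the volume.
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_voxel_nifti <- function(values, leadfield, path) {
  grid <- leadfield$grid_mm
  ax <- lapply(1:3, function(k) sort(unique(grid[, k])))
  dims <- vapply(ax, length, 1L)
  vol <- array(NA_real_, dims)
  idx <- cbind(match(grid[, 1], ax[[1]]), match(grid[, 2], ax[[2]]),
               match(grid[, 3], ax[[3]]))
  vol[idx] <- values
  img <- RNifti::asNifti(vol, pixdim = rep(leadfield$spacing_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
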