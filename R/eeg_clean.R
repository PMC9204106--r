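# EEG preprocessing: bad-channel repair, 1-80 Hz filtering with downsampling
# to 200 Hz, three-stage blind-source-separation artifact attenuation
# (ocular / movement / myogenic screening via kurtosis, sample entropy and
# band-power ratio), and average re-referencing.

#' Sample entropy
#'
#' Negative log conditional probability that template sequences matching for
#' `m` points (Chebyshev distance <= `r`) also match for `m + 1` points;
#' self-matches excluded.
#'
#' @param x numeric vector.
#' @param m template length (default 2).
#' @param r tolerance; by default `0.2 * sd(x)` when `r = NULL`.
#' @return nonnegative scalar; `NA` if undefined (e.g. constant input),
#'   `Inf` when no `m + 1` matches exist.
#' @export
sample_entropy <- function(x, m = 2, r = NULL) {
  if (is.null(r)) r <- 0.2 * sd(x)
  if (!is.finite(r) || r <= 0) return(NA_real_)
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Detect and repair bad EEG channels
#'
#' A channel is bad when its correlation with the mean of its neighbours (its
#' neighbour-interpolated estimate) falls below `cor_thr`, or when its
#' log-variance deviates from the montage median by more than `var_mads`
#' MADs. Bad channels are replaced by the mean of their `k` nearest good
#' neighbours (spatial neighbours when electrode positions are attached,
#' otherwise the most-correlated channels).
#'
#' @param eeg an EEG `SensorStream` with at least 8 channels.
#' @param cor_thr neighbour-correlation threshold (default 0.4).
#' @param var_mads variance deviation threshold in MADs (default 5).
#' @param k neighbours used for interpolation (default 4).
#' @param max_bad_frac abort threshold: more than this fraction bad raises a
#'   quality error (default 0.25).
#' @return the repaired stream, with attribute `repaired` listing channel
#'   labels.
#' @export
repair_bad_channels <- function(eeg, cor_thr = 0.4, var_mads = 5, k = 4,
                                max_bad_frac = 0.25) {
  stopifnot(inherits(eeg, "SensorStream"))
  X <- eeg$data
  nch <- nrow(X)
  if (nch < 8) stop("need at least 8 channels")
  v <- apply(X, 1, var)
  C <- suppressWarnings(abs(cor(t(X))))
  diag(C) <- NA
  neigh_idx <- function(i) {
    if (!is.null(eeg$pos)) {
      d <- sqrt(rowSums((eeg$pos - matrix(eeg$pos[i, ], nch, 3, byrow = TRUE))^2))
      d[i] <- Inf
      order(d)[seq_len(min(k, nch - 1))]
    } else {
      order(-C[i, ])[seq_len(min(k, nch - 1))]
    }
  }
  pred_cor <- vapply(seq_len(nch), function(i) {
    pred <- colMeans(X[neigh_idx(i), , drop = FALSE])
    if (sd(pred) == 0 || sd(X[i, ]) == 0) return(0)
    abs(cor(X[i, ], pred))
  }, 0)
  lv <- log(pmax(v, .Machine$double.xmin))
  var_dev <- abs(lv - median(lv)) / max(mad(lv), .Machine$double.eps)
  bad <- which(pred_cor < cor_thr | var_dev > var_mads | v == 0)
  if (length(bad) > max_bad_frac * nch)
    stop(sprintf("quality error: %d of %d channels bad (> %.0f%%)",
                 length(bad), nch, 100 * max_bad_frac))
  good <- setdiff(seq_len(nch), bad)
  for (b in bad) {
    if (!is.null(eeg$pos)) {
      d <- sqrt(rowSums((eeg$pos[good, , drop = FALSE] -
                           matrix(eeg$pos[b, ], length(good), 3, byrow = TRUE))^2))
      nb <- good[order(d)[seq_len(min(k, length(good)))]]
    } else {
      nb <- good[order(-C[b, good])[seq_len(min(k, length(good)))]]
    }
    X[b, ] <- colMeans(X[nb, , drop = FALSE])
  }
  out <- eeg
  out$data <- X
  attr(out, "repaired") <- eeg$labels[bad]
  out
}

#' Band-pass filter EEG to 1-80 Hz and downsample to 200 Hz
#'
#' Zero-phase FIR band-pass, then anti-aliased resampling.
#'
#' @param eeg an EEG `SensorStream` with `fs >= 200` Hz.
#' @param lo,hi band edges (Hz).
#' @param target_fs output rate (Hz, default 200).
#' @return the filtered, downsampled stream.
#' @export
filter_resample <- function(eeg, lo = 1, hi = 80, target_fs = 200) {
  stopifnot(inherits(eeg, "SensorStream"))
  if (eeg$fs < 200) stop("EEG sampling rate must be >= 200 Hz")
  hi <- min(hi, 0.45 * eeg$fs)
  n_out <- floor(ncol(eeg$data) * target_fs / eeg$fs)
  Y <- matrix(0, nrow(eeg$data), n_out)
  for (ch in seq_len(nrow(eeg$data))) {
    xf <- filter_band(eeg$data[ch, ], eeg$fs, lo, hi,
                      trans_lo = min(1, lo), trans_hi = min(10, eeg$fs / 2 - hi))
    Y[ch, ] <- if (target_fs < eeg$fs) resample_sig(xf, eeg$fs, target_fs) else xf
  }
  sensor_stream(Y, target_fs, eeg$labels, kind = eeg$kind,
                start_time = eeg$start_time, units = eeg$units, pos = eeg$pos)
}

#' Average re-reference
#'
#' Subtracts the per-sample mean across channels; column sums become 0.
#'
#' @param eeg an EEG `SensorStream` with >= 2 channels.
#' @return the re-referenced stream.
#' @export
average_reference <- function(eeg) {
  stopifnot(inherits(eeg, "SensorStream"), nrow(eeg$data) >= 2)
  out <- eeg
  out$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  out
}

#' Score decomposition components for artifact screening
#'
#' For each component: maximum excess kurtosis over non-overlapping 5-s
#' windows, mean sample entropy over non-overlapping 20-s windows (m = 2,
#' r = 0.2 x window SD), and the Welch band-power ratio P[30-80]/P[1-30].
#' Stage flags use the thresholds kurtosis > 12 (ocular), sample entropy
#' < 0.8 (motion) and ratio > 1 (myogenic).
#'
#' @param S components x time matrix of component time courses.
#' @param fs sampling rate (Hz).
#' @param kurt_thr,sampen_thr,ratio_thr screening thresholds.
#' @param measures which scores to compute (sample entropy is the expensive
#'   one; stages that do not screen on it may omit it).
#' @return data.frame of class `ComponentScore` with one row per component:
#'   `component_id`, `max_win_kurtosis`, `mean_win_sampen`,
#'   `band_power_ratio`, and logicals `ocular`, `motion`, `myogenic`.
#' @export
score_components <- function(S, fs, kurt_thr = 12, sampen_thr = 0.8,
                             ratio_thr = 1,
                             measures = c("kurtosis", "sampen", "ratio")) {
  stopifnot(is.matrix(S))
  ncomp <- nrow(S)
  w5 <- floor(5 * fs); w20 <- floor(20 * fs)
  n <- ncol(S)
  res <- data.frame(component_id = seq_len(ncomp),
                    max_win_kurtosis = NA_real_,
                    mean_win_sampen = NA_real_,
                    band_power_ratio = NA_real_)
  for (i in seq_len(ncomp)) {
    x <- S[i, ]
    if (sd(x) == 0) next
    if ("kurtosis" %in% measures) {
      k_starts <- seq(1, max(n - w5 + 1, 1), by = w5)
      kv <- vapply(k_starts, function(s) {
        excess_kurtosis(x[s:min(s + w5 - 1, n)])
      }, 0)
      res$max_win_kurtosis[i] <- max(kv, na.rm = TRUE)
    }
    if ("sampen" %in% measures && n >= w20) {
      e_starts <- seq(1, n - w20 + 1, by = w20)
      ev <- vapply(e_starts, function(s) {
        w <- x[s:(s + w20 - 1)]
        sample_entropy(w, m = 2, r = 0.2 * sd(w))
      }, 0)
      ev <- ev[is.finite(ev)]
      if (length(ev)) res$mean_win_sampen[i] <- mean(ev)
    }
    if ("ratio" %in% measures) {
      res$band_power_ratio[i] <- band_power(x, fs, 30, 80) /
        max(band_power(x, fs, 1, 30), .Machine$double.eps)
    }
  }
  res$ocular <- !is.na(res$max_win_kurtosis) & res$max_win_kurtosis > kurt_thr
  res$motion <- !is.na(res$mean_win_sampen) & res$mean_win_sampen < sampen_thr
  res$myogenic <- !is.na(res$band_power_ratio) & res$band_power_ratio > ratio_thr
  class(res) <- c("ComponentScore", "data.frame")
  res
}

#' Ground-truth decomposition backend
#'
#' Builds a decomposition whose first components are the known artifact
#' topographies (time courses by least squares) and whose remaining
#' components are principal components of the residual. Reconstruction is
#' exact, so screening can be validated against planted artifacts.
#'
#' @param artifact_topos channels x n_artifact matrix of planted artifact
#'   scalp topographies.
#' @return a backend `function(X, fs)` returning a `Decomposition` (list with
#'   `S`, `A`, `method`).
#' @export
backend_oracle <- function(artifact_topos) {
  force(artifact_topos)
  function(X, fs) {
    nch <- nrow(X)
    if (is.null(artifact_topos) || ncol(artifact_topos) == 0) {
      e <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)
      return(list(S = t(e$vectors) %*% X, A = e$vectors, method = "oracle-pca"))
    }
    A1 <- artifact_topos
    S1 <- solve(crossprod(A1), t(A1) %*% X)
    Xr <- X - A1 %*% S1
    e <- eigen(tcrossprod(Xr) / ncol(Xr), symmetric = TRUE)
    keep <- which(e$values > 1e-12 * e$values[1])
    U <- e$vectors[, keep, drop = FALSE]
    list(S = rbind(S1, t(U) %*% Xr), A = cbind(A1, U), method = "oracle")
  }
}

# compact FastICA (whitening + tanh contrast); deflation or symmetric
fastica_core <- function(X, approach = c("deflation", "symmetric"),
                         max_iter = 200, tol = 1e-5) {
  approach <- match.arg(approach)
  nch <- nrow(X)
  Xc <- X - rowMeans(X)
  e <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
  keep <- which(e$values > 1e-10 * e$values[1])
  K <- diag(1 / sqrt(e$values[keep]), length(keep)) %*% t(e$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc
  nc <- nrow(Z)
  W <- matrix(rnorm(nc * nc), nc)
  if (approach == "deflation") {
    for (i in seq_len(nc)) {
      w <- W[i, ]
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wx <- drop(w %*% Z)
        g <- tanh(wx)
        w_new <- Z %*% g / ncol(Z) - mean(1 - g^2) * w
        if (i > 1) {
          Wp <- W[seq_len(i - 1), , drop = FALSE]
          w_new <- w_new - t(Wp) %*% (Wp %*% w_new)
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        conv <- abs(abs(sum(w_new * w)) - 1) < tol
        w <- drop(w_new)
        if (conv) break
      }
      W[i, ] <- w
    }
  } else {
    sym_decor <- function(W) {
      s <- eigen(tcrossprod(W), symmetric = TRUE)
      s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
    }
    W <- sym_decor(W)
    for (it in seq_len(max_iter)) {
      WX <- W %*% Z
      G <- tanh(WX)
      W_new <- G %*% t(Z) / ncol(Z) - diag(rowMeans(1 - G^2)) %*% W
      W_new <- sym_decor(W_new)
      conv <- max(abs(abs(rowSums(W_new * W)) - 1)) < tol
      W <- W_new
      if (conv) break
    }
  }
  U <- W %*% K                      # unmixing (comps x channels)
  A <- pseudo_inverse(U)
  list(S = U %*% Xc, A = A, method = paste0("fastica-", approach))
}

# Moore-Penrose pseudoinverse via SVD
pseudo_inverse <- function(M, tol = 1e-12) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' FastICA decomposition backend
#'
#' @param approach `"deflation"` or `"symmetric"`.
#' @param seed seed for the random initial unmixing matrix.
#' @return a backend `function(X, fs)` usable by [attenuate_artifacts()].
#' @export
backend_fastica <- function(approach = c("deflation", "symmetric"), seed = 1) {
  approach <- match.arg(approach)
  function(X, fs) {
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(.restore_seed(old))
    fastica_core(X, approach)
  }
}

#' Three-stage artifact attenuation
#'
#' Runs the screening stages strictly in order ocular, motion, myogenic. At
#' each stage the data are decomposed by the backend for that stage,
#' components failing the stage criterion are zeroed and the data
#' reconstructed. A backend that errors makes the stage skip with a warning.
#'
#' @param eeg an EEG `SensorStream` (typically after [filter_resample()]).
#' @param backends either a single backend function used for all stages or a
#'   named list with entries `ocular`, `motion`, `myogenic`. Use
#'   [backend_oracle()] in validation, [backend_fastica()] in production.
#' @param kurt_thr,sampen_thr,ratio_thr screening thresholds.
#' @return the cleaned stream; attribute `report` is a list per stage with
#'   the `ComponentScore` table and the removed component ids.
#' @export
attenuate_artifacts <- function(eeg, backends, kurt_thr = 12,
                                sampen_thr = 0.8, ratio_thr = 1) {
  stopifnot(inherits(eeg, "SensorStream"))
  stages <- c("ocular", "motion", "myogenic")
  if (is.function(backends))
    backends <- stats::setNames(rep(list(backends), 3), stages)
  X <- eeg$data
  report <- list()
  for (st in stages) {
    dec <- tryCatch(backends[[st]](X, eeg$fs), error = function(e) e)
    if (inherits(dec, "error")) {
      warning(sprintf("stage '%s' skipped: backend failed (%s)", st,
                      conditionMessage(dec)))
      report[[st]] <- list(skipped = TRUE, reason = conditionMessage(dec))
      next
    }
    meas <- switch(st, ocular = c("kurtosis", "ratio"),
                   motion = c("kurtosis", "sampen", "ratio"),
                   myogenic = c("kurtosis", "ratio"))
    sc <- score_components(dec$S, eeg$fs, kurt_thr, sampen_thr, ratio_thr,
                           measures = meas)
    rm_ids <- sc$component_id[sc[[st]]]
    if (length(rm_ids)) {
      X <- X - dec$A[, rm_ids, drop = FALSE] %*% dec$S[rm_ids, , drop = FALSE]
    }
    report[[st]] <- list(skipped = FALSE, scores = sc, removed = rm_ids,
                         method = dec$method)
  }
  out <- eeg
  out$data <- X
  attr(out, "report") <- report
  out
}
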