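# eLORETA source reconstruction: iterative weight computation giving a linear
# inverse with zero localization error for noiseless point sources, dipole
# collapse by PCA, and ROI signal extraction.

sym_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

sym_inv <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  d <- numeric(length(e$values))
  d[keep] <- 1 / e$values[keep]
  e$vectors %*% (d * t(e$vectors))
}

#' Fit an eLORETA inverse operator
#'
#' Source-wise 3x3 weight blocks are iterated on the regularized resolution
#' kernel until the maximum relative weight change falls below `tol`. The
#' gain is average-referenced internally (rows projected off the constant
#' vector), matching average-referenced data.
#'
#' @param leadfield a `LeadField`.
#' @param alpha Tikhonov regularization; `NULL` (default) uses
#'   `1e-3 x` the mean eigenvalue of the gain Gram matrix.
#' @param tol convergence tolerance on the relative weight change.
#' @param max_iter iteration cap (error on non-convergence, carrying the last
#'   residual).
#' @return an `InverseOperator`: `weights` (sources x 3 x channels), `alpha`,
#'   `n_iter`, `residual`, `method = "eLORETA"`.
#' @export
eloreta_fit <- function(leadfield, alpha = NULL, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(leadfield, "LeadField"))
  g <- leadfield$gain
  nch <- dim(g)[1]; nsrc <- dim(g)[2]
  K <- matrix(0, nch, 3 * nsrc)
  for (i in seq_len(nsrc)) K[, (3 * i - 2):(3 * i)] <- g[, i, ]
  K <- K - matrix(colMeans(K), nch, ncol(K), byrow = TRUE)  # average reference
  for (i in seq_len(nsrc)) {
    s <- svd(K[, (3 * i - 2):(3 * i)], nu = 0, nv = 0)$d
    if (s[3] < 1e-10 * s[1])
      stop(sprintf("rank-deficient source block %d after average referencing", i))
  }
  H <- diag(nch) - matrix(1 / nch, nch, nch)
  if (is.null(alpha)) alpha <- 1e-3 * sum(K * K) / nch
  Wi <- replicate(nsrc, diag(3), simplify = FALSE)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    C <- matrix(0, nch, nch)
    for (i in seq_len(nsrc)) {
      Ki <- K[, (3 * i - 2):(3 * i)]
      C <- C + Ki %*% sym_inv(Wi[[i]]) %*% t(Ki)
    }
    Cp <- sym_inv(C + alpha * H)
    resid <- 0
    Wnew <- vector("list", nsrc)
    for (i in seq_len(nsrc)) {
      Ki <- K[, (3 * i - 2):(3 * i)]
      Wnew[[i]] <- sym_sqrt(t(Ki) %*% Cp %*% Ki)
      resid <- max(resid, norm(Wnew[[i]] - Wi[[i]], "F") /
                     max(norm(Wi[[i]], "F"), 1e-300))
    }
    Wi <- Wnew
    if (resid < tol) break
  }
  if (resid >= tol)
    stop(sprintf("eLORETA did not converge in %d iterations (residual %.3g)",
                 max_iter, resid))
  weights <- array(0, c(nsrc, 3, nch))
  C <- matrix(0, nch, nch)
  for (i in seq_len(nsrc)) {
    Ki <- K[, (3 * i - 2):(3 * i)]
    C <- C + Ki %*% sym_inv(Wi[[i]]) %*% t(Ki)
  }
  Cp <- sym_inv(C + alpha * H)
  for (i in seq_len(nsrc)) {
    Ki <- K[, (3 * i - 2):(3 * i)]
    weights[i, , ] <- sym_inv(Wi[[i]]) %*% t(Ki) %*% Cp
  }
  structure(list(weights = weights, alpha = alpha, n_iter = it,
                 residual = resid, method = "eLORETA",
                 grid_mm = leadfield$grid_mm),
            class = "InverseOperator")
}

#' @export
print.InverseOperator <- function(x, ...) {
  cat(sprintf("<InverseOperator: %s> %d sources x 3 x %d channels (alpha = %.3g, %d iters)\n",
              x$method, dim(x$weights)[1], dim(x$weights)[3], x$alpha,
              x$n_iter))
  invisible(x)
}

#' Apply an inverse operator to EEG data
#'
#' Linear application after average-referencing the data (matching the
#' operator's gain centering).
#'
#' @param op an `InverseOperator`.
#' @param eeg an EEG `SensorStream` whose channel count matches the operator.
#' @return numeric array sources x 3 x time of dipole moment time courses.
#' @export
apply_inverse <- function(op, eeg) {
  stopifnot(inherits(op, "InverseOperator"))
  X <- if (inherits(eeg, "SensorStream")) eeg$data else eeg
  if (nrow(X) != dim(op$weights)[3])
    stop("channel count does not match the inverse operator")
  X <- sweep(X, 2, colMeans(X))
  nsrc <- dim(op$weights)[1]
  Wflat <- matrix(aperm(op$weights, c(2, 1, 3)), nrow = 3 * nsrc,
                  ncol = dim(op$weights)[3])
  S <- Wflat %*% X
  array(S, dim = c(3, nsrc, ncol(X))) |> aperm(c(2, 1, 3))
}

#' Per-voxel reconstructed power
#' @param src sources x 3 x time array from [apply_inverse()].
#' @return numeric vector of summed squared dipole moment per source.
#' @export
voxel_power <- function(src) apply(src, 1, function(m) sum(m^2))

pc1_scores <- function(M) {
  # M: variables x time; returns first principal component score series with
  # a reproducible sign (loading sum positive; tie: first nonzero positive)
  Mc <- M - rowMeans(M)
  C <- tcrossprod(Mc) / ncol(Mc)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  s <- sum(v)
  if (abs(s) > 1e-12) {
    if (s < 0) v <- -v
  } else {
    nz <- which(abs(v) > 1e-12)[1]
    if (length(nz) && v[nz] < 0) v <- -v
  }
  list(score = drop(v %*% Mc), loading = v,
       explained = e$values[1] / max(sum(e$values), .Machine$double.eps))
}

#' Collapse a 3-D dipole time course to one representative signal
#'
#' First principal component of the three orientation channels.
#'
#' @param xyz 3 x time matrix of dipole moments.
#' @return one representative time course (numeric vector); attributes
#'   `loading` and `explained` carry the PCA details. All-zero input returns
#'   zeros with attribute `degenerate = TRUE`.
#' @export
collapse_dipole <- function(xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) == 3, ncol(xyz) >= 2)
  if (all(xyz == 0)) {
    out <- numeric(ncol(xyz))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- pc1_scores(xyz)
  out <- p$score
  attr(out, "loading") <- p$loading
  attr(out, "explained") <- p$explained
  out
}

#' Define a spherical region of interest
#'
#' @param name ROI label, e.g. `"M1"`, `"THAL"`, `"PMC"`, `"PPC"`, `"CER"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param center_mm 3-vector, ROI centre in source-grid coordinates (mm).
#' @param radius_mm sphere radius (default 6 mm).
#' @return a `RoiSpec`.
#' @export
roi_spec <- function(name, hemisphere = c("left", "right"), center_mm,
                     radius_mm = 6) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(radius_mm > 0, length(center_mm) == 3)
  structure(list(name = name, hemisphere = hemisphere,
                 center_mm = as.numeric(center_mm), radius_mm = radius_mm),
            class = "RoiSpec")
}

#' Extract a representative ROI signal
#'
#' First principal component of the per-voxel signals inside the ROI sphere.
#'
#' @param voxel_signals voxels x time matrix (one collapsed signal per grid
#'   voxel).
#' @param spec a [roi_spec()].
#' @param grid_mm voxel coordinates (voxels x 3, mm).
#' @return representative time course; attribute `voxels` lists member
#'   indices.
#' @export
extract_roi <- function(voxel_signals, spec, grid_mm) {
  stopifnot(inherits(spec, "RoiSpec"))
  d <- sqrt(rowSums((grid_mm - matrix(spec$center_mm, nrow(grid_mm), 3,
                                      byrow = TRUE))^2))
  sel <- which(d <= spec$radius_mm + 1e-9)
  if (length(sel) == 0)
    stop(sprintf("empty ROI sphere '%s'; nearest voxel at %.1f mm",
                 spec$name, min(d)))
  if (length(sel) == 1) {
    out <- voxel_signals[sel, ]
    attr(out, "voxels") <- sel
    return(out)
  }
  p <- pc1_scores(voxel_signals[sel, , drop = FALSE])
  out <- p$score
  attr(out, "voxels") <- sel
  attr(out, "loading") <- p$loading
  out
}
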