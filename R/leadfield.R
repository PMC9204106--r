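# Quasi-static forward model: current dipoles inside a homogeneous conducting
# sphere, electrodes on the upper part of the sphere surface. The surface
# potential of a point current source I at position r0 (|r0| < R) observed at
# a surface point R*rhat follows from the Legendre expansion of the interior
# Neumann problem and sums in closed form to
#
#   V = I / (4 pi sigma R) * [ 2 (1/u - 1) + log( 2 / (1 - a + u) ) ]
#
# with a = (rhat . r0)/R, b = |r0|^2/R^2, u = sqrt(1 - 2 a + b). A dipole's
# gain is the analytic gradient of this kernel with respect to r0.

# gradient of the monopole surface kernel wrt the source position (3-vector)
sphere_kernel_grad <- function(rhat, r0, R) {
  a <- sum(rhat * r0) / R
  b <- sum(r0 * r0) / R^2
  u <- sqrt(max(1 - 2 * a + b, .Machine$double.eps))
  da <- rhat / R
  du <- (r0 / R^2 - rhat / R) / u
  -2 * du / u^2 - (-da + du) / (1 - a + u)
}

# scalar kernel (used by tests as the monopole oracle)
sphere_kernel <- function(rhat, r0, R) {
  a <- sum(rhat * r0) / R
  b <- sum(r0 * r0) / R^2
  u <- sqrt(max(1 - 2 * a + b, .Machine$double.eps))
  2 * (1 / u - 1) + log(2 / (1 - a + u))
}

new_lead_field <- function(gain, grid_mm, spacing_mm, electrodes_mm) {
  stopifnot(length(dim(gain)) == 3, dim(gain)[3] == 3,
            nrow(grid_mm) == dim(gain)[2], ncol(grid_mm) == 3,
            all(is.finite(gain)))
  for (i in seq_len(dim(gain)[2])) {
    s <- svd(gain[, i, ], nu = 0, nv = 0)$d
    if (s[3] < 1e-12 * s[1])
      stop(sprintf("rank-deficient orientation space at source %d", i))
  }
  structure(list(gain = gain, grid_mm = grid_mm, spacing_mm = spacing_mm,
                 electrodes_mm = electrodes_mm),
            class = "LeadField")
}

#' @export
print.LeadField <- function(x, ...) {
  cat(sprintf("<LeadField> %d channels x %d sources x 3 orientations, %g mm grid\n",
              dim(x$gain)[1], dim(x$gain)[2], x$spacing_mm))
  invisible(x)
}

# Fibonacci-lattice electrode cap on the upper sphere surface
electrode_cap <- function(n, R, zmin = 0.05) {
  i <- seq_len(n)
  z <- zmin + (i - 0.5) / n * (1 - zmin)
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z) * R
}

#' Generate a synthetic spherical-head lead field
#'
#' Sources sit on a regular 3-D grid inside a homogeneous conducting sphere;
#' electrodes form a Fibonacci lattice over the upper sphere surface. Gains
#' are the analytic dipole solution of the spherical volume conductor. Each
#' source's 3-column orientation block is checked for full rank.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param grid_shape integer 3-vector, sources per axis (product >= 27).
#' @param spacing_mm grid spacing in mm (default 6).
#' @param seed retained for interface uniformity with the other generators
#'   (the construction is deterministic).
#' @param radius_mm sphere radius (default 90 mm).
#' @param center_mm centre of the source grid (default `c(0, 0, 45)` mm,
#'   placing the upper grid layers at cortical depth below the vertex).
#' @param sigma_S_m tissue conductivity (default 0.33 S/m).
#' @return a `LeadField`: `gain` (channels x sources x 3, scalp potential per
#'   unit dipole moment), `grid_mm`, `spacing_mm`, `electrodes_mm`.
#' @export
make_lead_field <- function(n_channels, grid_shape = c(5, 5, 4),
                            spacing_mm = 6, seed = 1, radius_mm = 90,
                            center_mm = c(0, 0, 45), sigma_S_m = 0.33) {
  if (n_channels < 8) stop("need at least 8 channels")
  if (prod(grid_shape) < 27) stop("need at least 27 sources")
  elec <- electrode_cap(n_channels, radius_mm)
  ax <- lapply(1:3, function(k) {
    (seq_len(grid_shape[k]) - (grid_shape[k] + 1) / 2) * spacing_mm + center_mm[k]
  })
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  colnames(grid) <- NULL
  rad <- sqrt(rowSums(grid^2))
  if (any(rad >= 0.95 * radius_mm))
    stop("degenerate geometry: source grid reaches the sphere surface")
  nsrc <- nrow(grid)
  gain <- array(0, dim = c(n_channels, nsrc, 3))
  scale <- 1 / (4 * pi * sigma_S_m * radius_mm)
  for (e in seq_len(n_channels)) {
    rhat <- elec[e, ] / radius_mm
    for (s in seq_len(nsrc)) {
      if (sqrt(sum((elec[e, ] - grid[s, ])^2)) < 1)
        stop("degenerate geometry: electrode coincident with source")
      gain[e, s, ] <- scale * sphere_kernel_grad(rhat, grid[s, ], radius_mm)
    }
  }
  new_lead_field(gain, grid, spacing_mm, elec)
}
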