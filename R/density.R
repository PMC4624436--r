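# Real-space electron density. Atomic densities are sums of Gaussians from
# tabulated element form factors (4-Gaussian + constant, the constant folded
# in as a fifth Gaussian), broadened by the isotropic Debye-Waller factor:
# each Gaussian's width term b_k becomes b_k + B. Maps are scalar grids on an
# orthogonal P1 box with an origin and per-axis spacing.

# 4-Gaussian coefficients + constant c per element (International Tables
# style a1..a4, b1..b4, c). Rows: a1..a4, c and b1..b4, 0.
FORM_FACTORS <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879, 0.001305),
           b = c(20.6593, 7.74039, 49.5519, 2.20159, 0)),
  C = list(a = c(2.31, 1.02, 1.5886, 0.865, 0.2156),
           b = c(20.8439, 10.2075, 0.5687, 51.6512, 0)),
  N = list(a = c(12.2126, 3.1322, 2.0125, 1.1663, -11.529),
           b = c(0.0057, 9.8933, 28.9975, 0.5826, 0)),
  O = list(a = c(3.0485, 2.2868, 1.5463, 0.867, 0.2508),
           b = c(13.2771, 5.7011, 0.3239, 32.9089, 0)),
  S = list(a = c(6.9053, 5.2034, 1.4379, 1.5863, 0.8669),
           b = c(1.4679, 22.2151, 0.2536, 56.172, 0)),
  P = list(a = c(6.4345, 4.1791, 1.78, 1.4908, 1.1149),
           b = c(1.9067, 27.157, 0.526, 68.1645, 0))
)

#' Construct a density map object
#'
#' @param values 3D numeric array (fast index = x).
#' @param origin Cartesian position (Angstrom) of voxel (1,1,1).
#' @param spacing per-axis voxel size (Angstrom), length 1 or 3.
#' @param resolution nominal resolution d (Angstrom).
#' @return object of class `density_map`.
#' @export
density_map <- function(values, origin, spacing, resolution) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(dim(values)) == 3, all(spacing > 0), resolution > 0)
  if (!all(is.finite(values))) stop("map values must be finite")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %dx%dx%d voxels, spacing %.3f/%.3f/%.3f A, d = %.2f A\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$resolution))
  invisible(x)
}

# Cartesian centers of voxels given their array indices
mask_points <- function(ai, map) {
  cbind(map$origin[1] + (ai[, 1] - 1) * map$spacing[1],
        map$origin[2] + (ai[, 2] - 1) * map$spacing[2],
        map$origin[3] + (ai[, 3] - 1) * map$spacing[3])
}

map_axis_coords <- function(map, axis) {
  map$origin[axis] + (seq_len(dim(map$values)[axis]) - 1) * map$spacing[axis]
}

#' Empty map grid enclosing a set of atoms
#'
#' @param atoms atom table (columns x, y, z).
#' @param spacing voxel size; defaults to d/4.
#' @param resolution nominal resolution d.
#' @param margin box padding around the atoms (Angstrom).
#' @return a zero-filled [density_map()].
#' @export
grid_for_atoms <- function(atoms, resolution, spacing = resolution / 4, margin = 5) {
  lo <- c(min(atoms$x), min(atoms$y), min(atoms$z)) - margin
  hi <- c(max(atoms$x), max(atoms$y), max(atoms$z)) + margin
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  n <- pmax(2, ceiling((hi - lo) / spacing) + 1)
  density_map(array(0, n), lo, spacing, resolution)
}

#' Resolution-dependent fitting mask radius
#'
#' r = 0.7 + (d - 0.6)/3 Angstrom below 3 Angstrom resolution, and d/2 at or
#' beyond; continuous at the branch point.
#'
#' @param d resolution in Angstrom (> 0).
#' @return radius r in Angstrom.
#' @export
mask_radius <- function(d) {
  if (any(d <= 0)) stop("resolution must be positive")
  ifelse(d < 3.0, 0.7 + (d - 0.6) / 3.0, 0.5 * d)
}

#' Compute model density on a map grid
#'
#' Each atom contributes an occupancy-scaled, B-broadened Gaussian-sum
#' density truncated beyond `cutoff` (default 3 + r(d) Angstrom). The
#' computation is separable per Gaussian term, so cost is linear in atoms.
#'
#' @param atoms atom table with element, occ, b, x, y, z.
#' @param grid a [density_map()] supplying the grid (values ignored), or NULL
#'   to build one with [grid_for_atoms()].
#' @param resolution nominal resolution d (defaults to `grid$resolution`).
#' @param cutoff per-atom truncation radius; default `3 + mask_radius(d)`.
#' @return a [density_map()] with the calculated density.
#' @export
calc_density <- function(atoms, grid = NULL, resolution = NULL, cutoff = NULL) {
  if (is.null(grid)) grid <- grid_for_atoms(atoms, resolution)
  d <- if (is.null(resolution)) grid$resolution else resolution
  if (is.null(cutoff)) cutoff <- 3 + mask_radius(d)
  vals <- array(0, dim(grid$values))
  dims <- dim(vals)
  ax <- lapply(1:3, function(k) map_axis_coords(grid, k))
  for (i in seq_len(nrow(atoms))) {
    occ <- atoms$occ[i]
    if (occ == 0) next
    el <- toupper(atoms$element[i])
    ff <- FORM_FACTORS[[el]]
    if (is.null(ff)) stop("no form factor for element: ", el)
    B <- max(atoms$b[i], 0)
    ctr <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    rng <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - ctr[k]) <= cutoff)
    })
    if (any(vapply(rng, length, 0L) == 0)) next
    dx <- ax[[1]][rng[[1]]] - ctr[1]
    dy <- ax[[2]][rng[[2]]] - ctr[2]
    dz <- ax[[3]][rng[[3]]] - ctr[3]
    block <- array(0, c(length(dx), length(dy), length(dz)))
    for (k in seq_along(ff$a)) {
      w <- max(ff$b[k] + B, 0.1)  # width floor guards the constant term at B ~ 0
      alpha <- 4 * pi^2 / w
      amp <- occ * ff$a[k] * (4 * pi / w)^1.5
      ex <- exp(-alpha * dx^2); ey <- exp(-alpha * dy^2); ez <- exp(-alpha * dz^2)
      block <- block + amp * (ex %o% ey %o% ez)
    }
    # spherical truncation
    r2 <- (dx^2 %o% rep(1, length(dy)) %o% rep(1, length(dz))) +
      (rep(1, length(dx)) %o% dy^2 %o% rep(1, length(dz))) +
      (rep(1, length(dx)) %o% rep(1, length(dy)) %o% dz^2)
    block[r2 > cutoff^2] <- 0
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]]] + block
  }
  density_map(vals, grid$origin, grid$spacing, d)
}

#' Voxel mask around a set of atom positions
#'
#' @param map a [density_map()] supplying the grid.
#' @param centers n x 3 matrix of Cartesian centers.
#' @param radius mask radius (Angstrom).
#' @return sorted vector of linear voxel indices within `radius` of any center.
#' @export
voxel_mask <- function(map, centers, radius) {
  centers <- matrix(centers, ncol = 3)
  dims <- dim(map$values)
  ax <- lapply(1:3, function(k) map_axis_coords(map, k))
  idx <- integer(0)
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    rng <- lapply(1:3, function(k) which(abs(ax[[k]] - ctr[k]) <= radius))
    if (any(vapply(rng, length, 0L) == 0)) next
    dx <- ax[[1]][rng[[1]]] - ctr[1]
    dy <- ax[[2]][rng[[2]]] - ctr[2]
    dz <- ax[[3]][rng[[3]]] - ctr[3]
    r2 <- (dx^2 %o% rep(1, length(dy)) %o% rep(1, length(dz))) +
      (rep(1, length(dx)) %o% dy^2 %o% rep(1, length(dz))) +
      (rep(1, length(dx)) %o% rep(1, length(dy)) %o% dz^2)
    keep <- which(r2 <= radius^2, arr.ind = TRUE)
    if (nrow(keep) == 0) next
    lin <- (rng[[1]][keep[, 1]]) +
      (rng[[2]][keep[, 2]] - 1L) * dims[1] +
      (rng[[3]][keep[, 3]] - 1L) * dims[1] * dims[2]
    idx <- c(idx, lin)
  }
  sort(unique(idx))
}

#' Scale an observed map onto a calculated map
#'
#' Fits obs ~ gain * calc + offset by least squares over the masked voxels
#' and returns (obs - offset)/gain on the full grid.
#'
#' @param obs,calc [density_map()]s on the same grid.
#' @param mask linear voxel indices over which to fit (>= 10 required).
#' @return the scaled observed map, with `gain` and `offset` attributes.
#' @export
scale_obs_to_calc <- function(obs, calc, mask) {
  stopifnot(identical(dim(obs$values), dim(calc$values)))
  if (length(mask) < 10) stop("degenerate scaling mask (< 10 voxels)")
  x <- calc$values[mask]; y <- obs$values[mask]
  fit <- stats::lm.fit(cbind(1, x), y)
  offset <- fit$coefficients[1]; gain <- fit$coefficients[2]
  if (!is.finite(gain) || abs(gain) < 1e-12) stop("degenerate scaling fit")
  out <- density_map((obs$values - offset) / gain, obs$origin, obs$spacing,
                     obs$resolution)
  attr(out, "gain") <- unname(gain)
  attr(out, "offset") <- unname(offset)
  out
}

#' Background-subtracted fitting target
#'
#' Subtracts the calculated density of every atom NOT in the rebuild
#' selection from the observed map, leaving the residual density that the
#' candidate conformers must explain. This emulates an omit map without a
#' refinement engine.
#'
#' @param obs observed [density_map()].
#' @param model a [protein_model()].
#' @param selection logical or integer row index into `model$atoms` naming
#'   the atoms to be rebuilt.
#' @param d resolution (defaults to the map's).
#' @return residual [density_map()] on the observed grid.
#' @export
background_subtract <- function(obs, model, selection, d = obs$resolution) {
  if (is.logical(selection)) selection <- which(selection)
  if (length(selection) == 0) stop("empty rebuild selection")
  bg <- model$atoms[-selection, ]
  if (nrow(bg) == 0) return(obs)
  calc <- calc_density(bg, grid = obs, resolution = d)
  density_map(obs$values - calc$values, obs$origin, obs$spacing, obs$resolution)
}
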