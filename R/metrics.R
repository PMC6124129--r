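# Multi-trial aggregation and shape summary metrics.

#' Trial-averaged cell density
#'
#' Per-voxel mean of `max(u, 0)` (living cells) over a collection of
#' snapshots taken on one grid at one time.  Values lie in `[0, 2]`.
#'
#' @param states list of [CellState-class] objects (or a list of occupancy
#'   vectors) sharing one grid.
#' @return a [ScalarField-class] of mean occupancy.
#' @export
averageDensity <- function(states) {
  if (!length(states)) stop("no snapshots to average")
  uList <- lapply(states, function(s) {
    if (is(s, "CellState")) pmax(occupancy(s), 0L) else pmax(as.integer(s), 0L)
  })
  n <- unique(lengths(uList))
  if (length(n) != 1) stop("grid mismatch: snapshots differ in voxel count")
  scalarField(Reduce(`+`, uList) / length(uList), name = "density")
}

#' Shape metrics of a density field
#'
#' Summaries of a nonnegative per-voxel density used to quantify grid
#' artefacts: effective area, equal-area reference circle radius,
#' mass-weighted centroid, central second-moment tensor, and the anisotropy
#' ratio `max(eig)/min(eig) - 1` (zero for a rotationally symmetric field).
#' The effective area `sum(density_i * voxelMeasure_i)` is the area the cell
#' population would cover at one cell per voxel, so after a relaxation run
#' (all voxels singly occupied) it equals the populated area and the
#' reference circle has the same area as the total cell population.
#'
#' @param density a [ScalarField-class] (or numeric vector), nonnegative.
#' @param grid a [VoxelGrid-class]
#' @return list with `effectiveArea`, `radius`, `centroid`, `secondMoments`,
#'   `eigenvalues`, `anisotropy`.
#' @export
shapeMetrics <- function(density, grid) {
  dens <- as.numeric(density)
  if (any(dens < 0)) stop("density must be nonnegative")
  mass <- dens * voxelMeasure(grid)
  tot <- sum(mass)
  if (tot <= 0) stop("undefined metrics: all-zero density field")
  co <- voxelCenters(grid)
  centroid <- colSums(mass * co) / tot
  cc <- sweep(co, 2, centroid)
  mom <- crossprod(cc, cc * mass) / tot
  ev <- eigen(mom, symmetric = TRUE, only.values = TRUE)$values
  list(effectiveArea = tot,
       radius = if (grid@dim == 2L) sqrt(tot / pi) else (3 * tot / (4 * pi))^(1 / 3),
       centroid = centroid,
       secondMoments = mom,
       eigenvalues = ev,
       anisotropy = max(ev) / min(ev) - 1)
}
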