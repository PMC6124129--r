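# Structured grid construction.
#
# Voxel indexing is row-major over the structured lattice (x fastest, then y,
# then z) so that snapshots are reproducible across runs and platforms.

.newGrid <- function(kind, dim, h, centers, edges, externalBoundary,
                     voxelMeasure, meta = list()) {
  n <- nrow(centers)
  nbr <- vector("list", n)
  if (nrow(edges) > 0) {
    ord <- order(edges$from, edges$to)
    edges <- edges[ord, , drop = FALSE]
    half <- data.frame(a = c(edges$from, edges$to), b = c(edges$to, edges$from))
    nbr <- unname(split(half$b, factor(half$a, levels = seq_len(n))))
    nbr <- lapply(nbr, function(v) as.integer(sort(v)))
  } else {
    nbr <- rep(list(integer(0)), n)
  }
  new("VoxelGrid", kind = kind, dim = as.integer(dim), h = h,
      centers = centers, nbr = nbr,
      edgeFrom = as.integer(edges$from), edgeTo = as.integer(edges$to),
      edgeMeasure = as.numeric(edges$e), centerDist = as.numeric(edges$d),
      externalBoundary = externalBoundary, voxelMeasure = voxelMeasure,
      meta = meta)
}

#' Build a structured voxel grid
#'
#' Constructs a Cartesian grid in two or three dimensions or a regular
#' pointy-top hexagonal lattice.  Voxels are indexed row-major (x fastest).
#' Interior voxels have exactly 4 edge-sharing neighbours on a 2D Cartesian
#' grid, 6 on the hexagonal lattice and 6 face-sharing neighbours in 3D.
#' On the hexagonal lattice the centre spacing is `h`, the shared edge length
#' is the hexagon side `h/sqrt(3)`, and partial boundary hexagons are not
#' generated (the lattice is trimmed to whole cells).
#'
#' @param kind `"cartesian2d"`, `"cartesian3d"` or `"hexagonal"`.
#' @param extent integer voxel counts per axis (length 2, or 3 for
#'   `"cartesian3d"`).
#' @param h voxel size (centre spacing), `> 0`.
#' @param center logical; if `TRUE`, translate the grid so its centroid is at
#'   the origin (convenient for symmetric initial conditions).
#' @return a [VoxelGrid-class]
#' @examples
#' g <- buildStructuredGrid("cartesian2d", c(3, 3))
#' lengths(voxelNeighbours(g))  # centre voxel has 4 neighbours
#' @export
buildStructuredGrid <- function(kind = c("cartesian2d", "cartesian3d", "hexagonal"),
                                extent, h = 1, center = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop("configuration error: voxel size h must be a positive number")
  extent <- as.integer(extent)
  ndim <- if (kind == "cartesian3d") 3L else 2L
  if (length(extent) == 1) extent <- rep(extent, ndim)
  if (length(extent) != ndim || anyNA(extent) || any(extent < 1L))
    stop("configuration error: extent must give >= 1 voxels per axis")

  grid <- switch(kind,
    cartesian2d = .buildCartesian2d(extent, h),
    cartesian3d = .buildCartesian3d(extent, h),
    hexagonal = .buildHexagonal(extent, h))
  if (center) {
    grid@centers <- sweep(grid@centers, 2, colMeans(grid@centers))
  }
  validObject(grid)
  grid
}

.buildCartesian2d <- function(extent, h) {
  nx <- extent[1]; ny <- extent[2]
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  centers <- cbind(x = (ix - 1) * h, y = (iy - 1) * h)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  # horizontal edges (ix, ix+1) and vertical edges (iy, iy+1)
  eh <- if (nx > 1) {
    hx <- rep(seq_len(nx - 1), times = ny); hy <- rep(seq_len(ny), each = nx - 1)
    cbind(id(hx, hy), id(hx + 1L, hy))
  } else matrix(integer(0), 0, 2)
  ev <- if (ny > 1) {
    vx <- rep(seq_len(nx), times = ny - 1); vy <- rep(seq_len(ny - 1), each = nx)
    cbind(id(vx, vy), id(vx, vy + 1L))
  } else matrix(integer(0), 0, 2)
  ee <- rbind(eh, ev)
  edges <- data.frame(from = ee[, 1], to = ee[, 2],
                      e = rep(h, nrow(ee)), d = rep(h, nrow(ee)))
  ext <- ix == 1L | ix == nx | iy == 1L | iy == ny
  .newGrid("cartesian2d", 2L, h, centers, edges, ext,
           rep(h^2, nx * ny), meta = list(extent = extent))
}

.buildCartesian3d <- function(extent, h) {
  nx <- extent[1]; ny <- extent[2]; nz <- extent[3]
  idx <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))
  centers <- cbind(x = (idx$ix - 1) * h, y = (idx$iy - 1) * h, z = (idx$iz - 1) * h)
  id <- function(ix, iy, iz) ((iz - 1L) * ny + (iy - 1L)) * nx + ix
  e1 <- with(expand.grid(ix = seq_len(max(nx - 1, 0)), iy = seq_len(ny), iz = seq_len(nz)),
             cbind(id(ix, iy, iz), id(ix + 1L, iy, iz)))
  e2 <- with(expand.grid(ix = seq_len(nx), iy = seq_len(max(ny - 1, 0)), iz = seq_len(nz)),
             cbind(id(ix, iy, iz), id(ix, iy + 1L, iz)))
  e3 <- with(expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(max(nz - 1, 0))),
             cbind(id(ix, iy, iz), id(ix, iy, iz + 1L)))
  ee <- rbind(e1, e2, e3)
  edges <- data.frame(from = ee[, 1], to = ee[, 2],
                      e = rep(h^2, nrow(ee)), d = rep(h, nrow(ee)))
  ext <- idx$ix == 1L | idx$ix == nx | idx$iy == 1L | idx$iy == ny |
    idx$iz == 1L | idx$iz == nz
  .newGrid("cartesian3d", 3L, h, centers, edges, ext,
           rep(h^3, nrow(centers)), meta = list(extent = extent))
}

.buildHexagonal <- function(extent, h) {
  # pointy-top hexagons, "odd-r" offset rows: odd rows (0-based) shifted +h/2
  nx <- extent[1]; ny <- extent[2]
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  r0 <- iy - 1L
  centers <- cbind(x = (ix - 1 + 0.5 * (r0 %% 2L)) * h,
                   y = r0 * (sqrt(3) / 2) * h)
  n <- nx * ny
  # neighbour pairs: same-row plus the two adjacent cells in rows above/below;
  # identified by centre distance == h
  id <- function(ix, iy) (iy - 1L) * nx + ix
  cand <- list()
  if (nx > 1) {
    hx <- rep(seq_len(nx - 1), times = ny); hy <- rep(seq_len(ny), each = nx - 1)
    cand[[1]] <- cbind(id(hx, hy), id(hx + 1L, hy))
  }
  if (ny > 1) {
    for (dx in c(-1L, 0L, 1L)) {
      sx <- seq_len(nx); sx <- sx[sx + dx >= 1L & sx + dx <= nx]
      if (!length(sx)) next
      gx <- rep(sx, times = ny - 1); gy <- rep(seq_len(ny - 1), each = length(sx))
      cand[[length(cand) + 1]] <- cbind(id(gx, gy), id(gx + dx, gy + 1L))
    }
  }
  ee <- do.call(rbind, c(cand, list(matrix(integer(0), 0, 2))))
  if (nrow(ee) > 0) {
    dd <- sqrt(rowSums((centers[ee[, 1], , drop = FALSE] -
                          centers[ee[, 2], , drop = FALSE])^2))
    ee <- ee[abs(dd - h) < 1e-9 * h, , drop = FALSE]
  }
  edges <- data.frame(from = pmin(ee[, 1], ee[, 2]), to = pmax(ee[, 1], ee[, 2]),
                      e = rep(h / sqrt(3), nrow(ee)), d = rep(h, nrow(ee)))
  ext <- ix == 1L | ix == nx | iy == 1L | iy == ny
  .newGrid("hexagonal", 2L, h, centers, edges, ext,
           rep(sqrt(3) / 2 * h^2, n), meta = list(extent = extent))
}

#' Thorough structural check of a grid
#'
#' Verifies neighbour symmetry, positivity of the edge measures, and (for
#' structured grids) the interior neighbour counts.  Intended for tests and
#' debugging; construction already validates the cheap invariants.
#'
#' @param grid a [VoxelGrid-class]
#' @return `TRUE`, invisibly; otherwise an error is thrown.
#' @export
checkGrid <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  n <- nVoxels(grid)
  for (e in seq_along(grid@edgeFrom)) {
    i <- grid@edgeFrom[e]; j <- grid@edgeTo[e]
    if (!(j %in% grid@nbr[[i]]) || !(i %in% grid@nbr[[j]]))
      stop("grid invariant violated: neighbour relation not symmetric")
  }
  if (any(grid@edgeMeasure <= 0) || any(grid@centerDist <= 0))
    stop("grid invariant violated: nonpositive edge measure or distance")
  dd <- sqrt(rowSums((grid@centers[grid@edgeFrom, , drop = FALSE] -
                        grid@centers[grid@edgeTo, , drop = FALSE])^2))
  if (any(abs(dd - grid@centerDist) > 1e-9 * max(dd)))
    stop("grid invariant violated: centre distances inconsistent with coordinates")
  invisible(TRUE)
}

#' Serialize a grid to a plain-text table
#'
#' Writes one CSV row per voxel: id, centre coordinates, external-boundary
#' flag, voxel measure and the semicolon-separated neighbour list; a second
#' table (same path with suffix `_edges`) stores the edge list with `e_ij`
#' and `d_ij`.
#'
#' @param grid a [VoxelGrid-class]
#' @param path output CSV path (the edge table goes to
#'   `sub("\\\\.csv$", "_edges.csv", path)`).
#' @return invisibly, the two paths written.
#' @export
writeGrid <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  co <- voxelCenters(grid)
  df <- data.frame(voxel = seq_len(nVoxels(grid)))
  for (k in seq_len(ncol(co))) df[[c("x", "y", "z")[k]]] <- co[, k]
  df$external <- externalBoundary(grid)
  df$measure <- voxelMeasure(grid)
  df$neighbours <- vapply(grid@nbr, paste, character(1), collapse = ";")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  epath <- sub("\\.csv$", "_edges.csv", path)
  if (identical(epath, path)) epath <- paste0(path, "_edges")
  utils::write.csv(edgeTable(grid), epath, row.names = FALSE, quote = FALSE)
  invisible(c(path, epath))
}
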