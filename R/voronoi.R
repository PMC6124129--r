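# Unstructured 2D Voronoi grids.
#
# The bounded Voronoi cell of a seed point is computed by clipping the
# bounding box successively against the perpendicular-bisector half-plane of
# every other seed (Sutherland-Hodgman).  This is O(n^2) but exact for the
# moderate grid sizes a simulation uses, and it needs no external geometry
# library.  Two voxels are neighbours iff their polygons share an edge of
# positive length; corner-touching cells (e.g. the diagonal pairs of a
# square of seeds) are not neighbours.

# clip convex polygon (counterclockwise matrix of vertices) against
# half-plane {x : a . x <= b}
.clipHalfPlane <- function(poly, a, b, tol) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  val <- poly %*% a - b
  inside <- val <= tol
  if (all(inside)) return(poly)
  out <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    p1 <- poly[k, ]; p2 <- poly[k2, ]
    in1 <- inside[k]; in2 <- inside[k2]
    if (in1) out <- rbind(out, p1)
    if (in1 != in2) {
      t <- val[k] / (val[k] - val[k2])
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  out
}

.polygonArea <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Build an unstructured Voronoi voxel grid
#'
#' Constructs the Voronoi tessellation of a set of 2D seed points, clipped to
#' a rectangular bounding box.  Each voxel is the clipped Voronoi polygon of
#' one seed; two voxels are neighbours iff their polygons share an edge of
#' positive length, with `e_ij` the length of that shared edge and `d_ij` the
#' distance between the seed points.  Voxels whose polygon touches the
#' bounding box are flagged as external boundary.
#'
#' @param seedPoints numeric matrix (n x 2) of seed coordinates; at least 3
#'   non-collinear points, no duplicates, all inside the box.
#' @param boundingBox numeric `c(xmin, xmax, ymin, ymax)`; by default the
#'   seed bounding box padded by half its diagonal.
#' @return a [VoxelGrid-class] with the cell polygons in `meta$polygons`.
#' @examples
#' pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' g <- buildVoronoiGrid(pts, c(-5, 6, -5, 6))
#' lengths(voxelNeighbours(g))  # 2 rook neighbours each, diagonals excluded
#' @export
buildVoronoiGrid <- function(seedPoints, boundingBox = NULL) {
  seedPoints <- as.matrix(seedPoints)
  storage.mode(seedPoints) <- "double"
  if (ncol(seedPoints) != 2) stop("configuration error: seed points must be 2D")
  n <- nrow(seedPoints)
  if (n < 3) stop("configuration error: need at least 3 seed points")
  dmat <- as.matrix(stats::dist(seedPoints))
  diag(dmat) <- Inf
  scale <- max(apply(seedPoints, 2, function(v) diff(range(v))), 1e-12)
  if (min(dmat) < 1e-9 * scale)
    stop("configuration error: duplicate seed points")
  # collinearity: rank of centred coordinates
  cc <- sweep(seedPoints, 2, colMeans(seedPoints))
  if (svd(cc)$d[2] < 1e-10 * scale)
    stop("configuration error: seed points are collinear")
  if (is.null(boundingBox)) {
    rx <- range(seedPoints[, 1]); ry <- range(seedPoints[, 2])
    pad <- 0.5 * sqrt(diff(rx)^2 + diff(ry)^2)
    boundingBox <- c(rx[1] - pad, rx[2] + pad, ry[1] - pad, ry[2] + pad)
  }
  bb <- as.numeric(boundingBox)
  if (length(bb) != 4 || bb[1] >= bb[2] || bb[3] >= bb[4])
    stop("configuration error: invalid bounding box")
  if (any(seedPoints[, 1] < bb[1] | seedPoints[, 1] > bb[2] |
          seedPoints[, 2] < bb[3] | seedPoints[, 2] > bb[4]))
    stop("configuration error: seed points must lie inside the bounding box")

  tol <- 1e-9 * max(scale, bb[2] - bb[1], bb[4] - bb[3])
  box <- rbind(c(bb[1], bb[3]), c(bb[2], bb[3]), c(bb[2], bb[4]), c(bb[1], bb[4]))
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- box
    ord <- order(dmat[i, ]) # clip nearest seeds first: shrinks the polygon fast
    for (j in ord) {
      if (nrow(poly) == 0) break
      a <- seedPoints[j, ] - seedPoints[i, ]
      b <- sum(a * (seedPoints[i, ] + seedPoints[j, ]) / 2)
      # quick reject: bisector further than current polygon radius
      poly <- .clipHalfPlane(poly, a, b, tol)
    }
    polys[[i]] <- poly
  }

  # neighbour identification: a polygon edge whose midpoint is equidistant
  # (within tol) from seed i and some other seed j lies on their bisector
  ef <- integer(0); et <- integer(0); ee <- numeric(0)
  ext <- logical(n)
  onBox <- function(p) {
    abs(p[1] - bb[1]) < tol || abs(p[1] - bb[2]) < tol ||
      abs(p[2] - bb[3]) < tol || abs(p[2] - bb[4]) < tol
  }
  edgeLen <- vector("list", n) # collected per ordered pair for symmetrisation
  names(edgeLen) <- seq_len(n)
  pairKey <- character(0); pairLen <- numeric(0); pairI <- integer(0); pairJ <- integer(0)
  for (i in seq_len(n)) {
    poly <- polys[[i]]
    m <- nrow(poly)
    if (m < 3) next
    for (k in seq_len(m)) {
      k2 <- if (k == m) 1L else k + 1L
      p1 <- poly[k, ]; p2 <- poly[k2, ]
      len <- sqrt(sum((p1 - p2)^2))
      if (len <= tol) next
      mid <- (p1 + p2) / 2
      if (onBox(p1) && onBox(p2) && onBox(mid)) { ext[i] <- TRUE; next }
      di <- sqrt(sum((mid - seedPoints[i, ])^2))
      dj <- sqrt(colSums((t(seedPoints) - mid)^2))
      dj[i] <- Inf
      j <- which.min(dj)
      if (abs(dj[j] - di) < 1e-6 * max(di, 1)) {
        pairKey <- c(pairKey, paste(min(i, j), max(i, j)))
        pairLen <- c(pairLen, len)
        pairI <- c(pairI, min(i, j)); pairJ <- c(pairJ, max(i, j))
      } else {
        # box-corner edge fragment
        ext[i] <- ext[i] || onBox(mid)
      }
    }
    # external flag also when any vertex lies on the box
    if (!ext[i]) ext[i] <- any(apply(poly, 1, onBox))
  }
  if (length(pairKey)) {
    agg <- tapply(pairLen, pairKey, mean) # both sides see the same edge
    keys <- names(agg)
    ij <- do.call(rbind, strsplit(keys, " "))
    ef <- as.integer(ij[, 1]); et <- as.integer(ij[, 2]); ee <- as.numeric(agg)
  }
  dd <- sqrt(rowSums((seedPoints[ef, , drop = FALSE] -
                        seedPoints[et, , drop = FALSE])^2))
  edges <- data.frame(from = ef, to = et, e = ee, d = dd)
  measures <- vapply(polys, .polygonArea, numeric(1))
  centers <- seedPoints
  colnames(centers) <- c("x", "y")
  grid <- .newGrid("voronoi", 2L, NA_real_, centers, edges, ext, measures,
                   meta = list(polygons = polys, boundingBox = bb))
  validObject(grid)
  grid
}
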