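# Independent oracles: assembled by different routes than the package code
# they check.

# dense 5-point finite-difference Laplacian on an nx x ny lattice (h = 1),
# row-major indexing, built entry by entry
fdLaplacian2d <- function(nx, ny) {
  n <- nx * ny
  L <- matrix(0, n, n)
  id <- function(ix, iy) (iy - 1) * nx + ix
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    i <- id(ix, iy)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      jx <- ix + d[1]; jy <- iy + d[2]
      if (jx >= 1 && jx <= nx && jy >= 1 && jy <= ny) {
        L[i, id(jx, jy)] <- 1
        L[i, i] <- L[i, i] - 1
      }
    }
  }
  L
}

# dense brute-force pressure solve: base solve() on a dense matrix built by
# looping over neighbour lists (no sparse algebra shared with the package path)
densePressure <- function(grid, u) {
  n <- nVoxels(grid)
  et <- edgeTable(grid)
  L <- matrix(0, n, n)
  for (r in seq_len(nrow(et))) {
    i <- et$from[r]; j <- et$to[r]; w <- et$w[r]
    L[i, j] <- L[i, j] + w
    L[j, i] <- L[j, i] + w
    L[i, i] <- L[i, i] - w
    L[j, j] <- L[j, j] - w
  }
  act <- which(u != 0)
  s <- as.numeric(u[act] == 2)
  p <- numeric(n)
  if (length(act) && any(s != 0))
    p[act] <- base::solve(-L[act, act, drop = FALSE], s)
  p
}

# length of the Voronoi edge shared by seeds i and j inside the bounding box:
# the bisector segment closer to (i, j) than to every other seed.  Built from
# the half-plane inequalities in bisector-parameter form, independent of the
# polygon-clipping construction.
voronoiEdgeLength <- function(seeds, bb, i, j) {
  xi <- seeds[i, ]; xj <- seeds[j, ]
  m <- (xi + xj) / 2
  dirv <- c(-(xj - xi)[2], (xj - xi)[1])
  dirv <- dirv / sqrt(sum(dirv^2))
  lo <- -Inf; hi <- Inf
  # equidistance to i and j holds along the whole bisector; impose closer
  # than every other seed k: |P - xi|^2 <= |P - xk|^2 is linear in t
  for (k in seq_len(nrow(seeds))) {
    if (k == i || k == j) next
    xk <- seeds[k, ]
    # P(t) = m + t dirv; expand |P-xi|^2 - |P-xk|^2 <= 0 -> a t <= b
    a <- 2 * sum(dirv * (xk - xi))
    b <- sum(xk^2) - sum(xi^2) - 2 * sum(m * (xk - xi))
    if (abs(a) < 1e-14) {
      if (b < 0) return(0) # bisector entirely outside
    } else if (a > 0) hi <- min(hi, b / a) else lo <- max(lo, b / a)
  }
  # clip to the box
  for (s in list(c(1, 1, bb[2]), c(-1, 1, -bb[1]), c(1, 2, bb[4]), c(-1, 2, -bb[3]))) {
    a <- s[1] * dirv[s[2]]
    b <- s[3] - s[1] * m[s[2]]
    if (abs(a) < 1e-14) {
      if (b < 0) return(0)
    } else if (a > 0) hi <- min(hi, b / a) else lo <- max(lo, b / a)
  }
  max(hi - lo, 0)
}

# the 1 x 3 occupied strip (u = 1, 2, 1) on a 7 x 5 Cartesian grid: the
# restricted system solves to p = (1/14, 2/7, 1/14)
makeStrip <- function() {
  g <- buildStructuredGrid("cartesian2d", c(7, 5))
  id <- function(ix, iy) (iy - 1) * 7 + ix
  A <- id(3, 3); B <- id(4, 3); C <- id(5, 3)
  u <- integer(35)
  u[c(A, C)] <- 1L
  u[B] <- 2L
  list(grid = g, state = initializeState(g, occupancy = u),
       A = A, B = B, C = C)
}

# random legal occupancy on a small grid (for property-style suites)
randomOccupancy <- function(grid, pOccupied = 0.4, pDouble = 0.3) {
  n <- nVoxels(grid)
  u <- integer(n)
  occ <- stats::runif(n) < pOccupied
  u[occ] <- 1L + (stats::runif(sum(occ)) < pDouble)
  # keep a free boundary: clear the outer ring
  u[externalBoundary(grid)] <- 0L
  u
}
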