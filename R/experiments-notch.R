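# Delta-Notch lateral inhibition on a growing hexagonal tissue.

#' Delta-Notch parameters
#'
#' Constructor for [DeltaNotchParams-class]; the defaults
#' `(a, b, v, k, h) = (0.01, 100, 1, 2, 2)` give strong lateral inhibition
#' with a sharply switching Notch response.
#'
#' @param a,b,v,k,h model constants (all positive).
#' @param speedFactor right-hand-side scaling (1 or 50).
#' @return a [DeltaNotchParams-class]
#' @export
deltaNotchParams <- function(a = 0.01, b = 100, v = 1, k = 2, h = 2,
                             speedFactor = 1) {
  new("DeltaNotchParams", a = a, b = b, v = v, k = k, h = h,
      speedFactor = speedFactor)
}

#' Notch activation and Delta inhibition response functions
#'
#' `notchActivation(x) = x^k / (a + x^k)` (increasing) and
#' `deltaInhibition(x) = 1 / (1 + b x^h)` (decreasing).
#'
#' @param x input level (mean neighbour Delta, respectively own Notch).
#' @param params a [DeltaNotchParams-class]
#' @export
notchActivation <- function(x, params = deltaNotchParams()) {
  x^params@k / (params@a + x^params@k)
}

#' @rdname notchActivation
#' @export
deltaInhibition <- function(x, params = deltaNotchParams()) {
  1 / (1 + params@b * x^params@h)
}

#' Cell-to-cell contact structure
#'
#' Sparse adjacency over the living cells: a cell is in contact with every
#' cell residing in an edge-sharing neighbour voxel, plus its co-occupant
#' when its own voxel is doubly occupied (each contact counted once).  Rows
#' follow the living cells in registry order.
#'
#' @param state a [CellState-class]
#' @param grid a [VoxelGrid-class]
#' @return list with the sparse 0/1 `adj` matrix and the contact counts
#'   `deg`.
#' @export
cellAdjacency <- function(state, grid) {
  live <- which(state@cellAlive)
  nc <- length(live)
  vox <- state@cellVoxel[live]
  n <- length(state@u)
  # up to two living cells per voxel: record their row indices
  c1 <- rep(NA_integer_, n); c2 <- rep(NA_integer_, n)
  o <- order(vox); vo <- vox[o]
  first <- !duplicated(vo)
  c1[vo[first]] <- o[first]
  c2[vo[!first]] <- o[!first]
  occ <- !is.na(c1)
  a <- grid@edgeFrom; b <- grid@edgeTo
  sel <- occ[a] & occ[b]
  a <- a[sel]; b <- b[sel]
  co <- which(!is.na(c2)) # doubly occupied voxels: co-occupant contact
  ii <- c(c1[a], c1[a], c2[a], c2[a], c1[co])
  jj <- c(c1[b], c2[b], c1[b], c2[b], c2[co])
  ok <- !is.na(ii) & !is.na(jj)
  ii <- ii[ok]; jj <- jj[ok]
  adj <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(nc, nc))
  list(adj = adj, deg = Matrix::rowSums(adj))
}

#' Delta-Notch right-hand side
#'
#' For each living cell, `n' = speedFactor * (f(dbar) - n)` and
#' `d' = speedFactor * v * (g(n) - d)`, with `f` the Notch activation,
#' `g` the Delta inhibition and `dbar` the mean Delta over the cell's
#' contacts (see [cellAdjacency()]); an isolated cell sees `dbar = 0`.
#'
#' @param t time (unused; the system is autonomous).
#' @param y numeric matrix with columns `n`, `d`, one row per living cell.
#' @param setup contact structure from [cellAdjacency()].
#' @param params a [DeltaNotchParams-class]
#' @return derivative matrix of the same shape.
#' @export
deltaNotchRhs <- function(t, y, setup, params = deltaNotchParams()) {
  if (any(y < -1e-8)) stop("negative Delta-Notch state")
  n <- y[, 1]; d <- y[, 2]
  dbar <- as.numeric(setup$adj %*% d)
  deg <- setup$deg
  dbar <- ifelse(deg > 0, dbar / pmax(deg, 1), 0)
  sf <- params@speedFactor
  cbind(n = sf * (notchActivation(dbar, params) - n),
        d = sf * params@v * (deltaInhibition(n, params) - d))
}

#' Homogeneous Delta-Notch fixed point
#'
#' Solves `n* = f(g(n*))` by root finding; `(n*, d* = g(n*))` is a fixed
#' point of the full coupled system for any contact topology (it is
#' unstable under lateral inhibition, which is what drives patterning).
#'
#' @param params a [DeltaNotchParams-class]
#' @return named numeric `c(n, d)`.
#' @export
deltaNotchFixedPoint <- function(params = deltaNotchParams()) {
  fn <- function(n) notchActivation(deltaInhibition(n, params), params) - n
  n <- stats::uniroot(fn, c(1e-12, 1), tol = 1e-12)$root
  c(n = n, d = deltaInhibition(n, params))
}

#' Delta-Notch signalling on a proliferating tissue
#'
#' A circular patch of singly occupied voxels on a hexagonal grid grows by
#' constant-rate proliferation of the cells inside the (fixed) initial
#' region, while every living cell integrates the Delta-Notch ODEs between
#' mechanical events; daughters inherit the mother's `(n, d)` state.  The
#' run halts exactly when the living-cell count reaches `cellTarget`.
#' Initial `(n, d)` values are drawn uniformly from `[0, 1]` to break the
#' symmetry of the unstable homogeneous state.
#'
#' @param radius initial patch radius (voxel units).
#' @param gridExtent hexagonal grid extent (columns, rows).
#' @param h voxel size.
#' @param proliferationRate per-cell rate inside the region.
#' @param cellTarget stop when this many living cells exist.
#' @param params a [DeltaNotchParams-class]
#' @param constants a [RateConstants-class]
#' @param snapshotTimes times at which to record state copies.
#' @param horizon safety time horizon.
#' @param seed RNG seed.
#' @param notchThreshold classification threshold for the high-Notch
#'   fraction.
#' @param monitorRhs if `TRUE`, record the median per-cell right-hand-side
#'   norm at every event time (a quasi-equilibrium diagnostic; doubles the
#'   per-event cost).
#' @return list with `grid`, `trajectory` ([SimulationTrajectory-class]),
#'   `finalState`, `highNotchFraction`, and (with `monitorRhs`)
#'   `rhsNormAtEvents`.
#' @export
deltaNotchExperiment <- function(radius = 5, gridExtent = c(51, 51), h = 1,
                                 proliferationRate = 1, cellTarget = 1000,
                                 params = deltaNotchParams(),
                                 constants = rateConstants(1, 1, 1),
                                 snapshotTimes = numeric(0), horizon = 1e4,
                                 seed = 1, notchThreshold = 0.5,
                                 monitorRhs = FALSE) {
  grid <- buildStructuredGrid("hexagonal", gridExtent, h = h, center = TRUE)
  co <- voxelCenters(grid)
  inRegion <- rowSums(co^2) <= (radius * h)^2
  vox <- which(inRegion)
  set.seed(seed)
  init <- initializeState(grid, occupancy = vox, fillCount = 1L,
                          internalInit = function(nc) {
                            m <- cbind(n = stats::runif(nc), d = stats::runif(nc))
                            m
                          })
  proliferationEvents <- function(state, grid, fields) {
    # only singly occupied voxels can host a division (the daughter shares
    # the mother's voxel); eligibility is by the fixed initial region
    elig <- which(state@u == 1L & inRegion)
    eventSet(type = rep("proliferate", length(elig)), from = elig,
             rate = rep(proliferationRate, length(elig)))
  }
  rhsNorm <- if (monitorRhs) {
    function(state, fields) {
      live <- which(state@cellAlive)
      y <- state@internal[live, , drop = FALSE]
      setup <- cellAdjacency(state, grid)
      dy <- deltaNotchRhs(state@time, y, setup, params)
      c(medianRhsNorm = stats::median(sqrt(rowSums(dy^2))),
        nCells = length(live))
    }
  } else NULL
  traj <- runSimulation(grid, init, constants, horizon = horizon,
                        snapshotTimes = snapshotTimes,
                        cellTarget = cellTarget,
                        extraEvents = proliferationEvents,
                        rhs = deltaNotchRhs, rhsSetup = cellAdjacency,
                        rhsParams = params, monitor = rhsNorm)
  fs <- finalState(traj)
  nVals <- internalState(fs)[fs@cellAlive, 1]
  list(grid = grid, trajectory = traj, finalState = fs,
       highNotchFraction = mean(nVals > notchThreshold),
       rhsNormAtEvents = runInfo(traj)$monitor)
}
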