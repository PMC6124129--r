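# Avascular tumour growth with oxygen-limited kinetics.

#' Avascular tumour parameters
#'
#' Constructor for [TumourParams-class].  Defaults are the reference
#' parameter set: `D1 = 0.01`, `D2 = 25`, `D3 = 0.01`, `lambda = 0.0015`,
#' `kappaProl = 0.65`, `rhoProl = 0.125`, `kappaDeath = 0.55`,
#' `rhoDeath = 0.125`, `rhoDeg = 0.01` (rates per second, thresholds on the
#' oxygen concentration normalised to 1 at the external boundary).
#'
#' @param lambda,kappaProl,rhoProl,kappaDeath,rhoDeath,rhoDeg kinetics.
#' @param D1,D2,D3 movement conversion factors.
#' @return a [TumourParams-class]
#' @export
tumourParams <- function(lambda = 0.0015, kappaProl = 0.65, rhoProl = 0.125,
                         kappaDeath = 0.55, rhoDeath = 0.125, rhoDeg = 0.01,
                         D1 = 0.01, D2 = 25, D3 = 0.01) {
  new("TumourParams", lambda = lambda, kappaProl = kappaProl,
      rhoProl = rhoProl, kappaDeath = kappaDeath, rhoDeath = rhoDeath,
      rhoDeg = rhoDeg, constants = rateConstants(D1, D2, D3))
}

#' Prefactorised oxygen solver data
#'
#' The oxygen system matrix is fixed by the grid (unknowns are all voxels
#' off the external boundary), so its Cholesky factorisation is computed
#' once and reused for every solve.
#'
#' @param grid a [VoxelGrid-class] with a non-empty external boundary.
#' @param L a [LaplacianOperator-class] for `grid`.
#' @return opaque list consumed by [tumourOxygen()].
#' @export
tumourOxygenCache <- function(grid, L = assembleLaplacian(grid)) {
  ext <- externalBoundary(grid)
  if (!any(ext)) stop("grid has no external boundary to source oxygen from")
  interior <- which(!ext)
  M <- laplacianMatrix(L)
  A <- -M[interior, interior, drop = FALSE]
  # boundary term: (-L)[interior, ext] %*% 1 moved to the right-hand side
  bterm <- as.numeric(Matrix::rowSums(-M[interior, which(ext), drop = FALSE]))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  list(interior = interior, factor = ch, bterm = bterm, n = nVoxels(grid))
}

#' Steady-state oxygen concentration
#'
#' Solves `-L c = -lambda * a(u)` over the whole fixed grid with `c = 1` on
#' the external boundary, where `a(u_i)` is the number of living cells in
#' voxel `i` (2, 1 or 0; dead cells consume no oxygen).  By the discrete
#' maximum principle, adding a cell anywhere never increases the
#' concentration at any voxel.
#'
#' @param state a [CellState-class]
#' @param grid a [VoxelGrid-class]
#' @param L a [LaplacianOperator-class] (ignored when `cache` is given).
#' @param lambda consumption rate per living cell.
#' @param cache optional result of [tumourOxygenCache()] for repeated
#'   solves.
#' @return a [ScalarField-class] of oxygen concentrations.
#' @export
tumourOxygen <- function(state, grid, L = assembleLaplacian(grid),
                         lambda = 0.0015, cache = NULL) {
  if (is.null(cache)) cache <- tumourOxygenCache(grid, L)
  aliveCount <- pmax(state@u, 0L)
  rhs <- -lambda * aliveCount[cache$interior] - cache$bterm
  ci <- as.numeric(Matrix::solve(cache$factor, rhs, system = "A"))
  cfull <- rep(1, cache$n)
  cfull[cache$interior] <- ci
  scalarField(cfull, name = "oxygen")
}

#' Oxygen-driven kinetic events
#'
#' Proliferation for singly occupied voxels with `c > kappaProl` at rate
#' `rhoProl`; death for singly occupied voxels with `c < kappaDeath` at rate
#' `rhoDeath` (the only case the model defines: a doubly occupied hypoxic
#' voxel must first lose a cell by movement); degradation of dead cells at
#' rate `rhoDeg` regardless of oxygen.  Threshold comparisons are strict, so
#' a concentration exactly at a threshold generates no event.
#'
#' @param state a [CellState-class]
#' @param oxygen a [ScalarField-class] from [tumourOxygen()].
#' @param params a [TumourParams-class]
#' @return an [EventSet-class]
#' @export
tumourEvents <- function(state, oxygen, params) {
  u <- state@u
  cv <- as.numeric(oxygen)
  prol <- which(u == 1L & cv > params@kappaProl)
  death <- which(u == 1L & cv < params@kappaDeath)
  deg <- which(u == -1L)
  eventSet(
    type = c(rep("proliferate", length(prol)), rep("die", length(death)),
             rep("degrade", length(deg))),
    from = c(prol, death, deg),
    rate = c(rep(params@rhoProl, length(prol)),
             rep(params@rhoDeath, length(death)),
             rep(params@rhoDeg, length(deg))))
}

#' Avascular tumour growth experiment
#'
#' Couples the pressure mechanics with the oxygen field: starting from a
#' 5 x 5 block of singly occupied voxels at the domain centre, cells
#' proliferate where oxygen is plentiful, become quiescent as the interior
#' concentration falls, and die near the centre once the concentration
#' drops below the survival threshold, producing the classical layered
#' structure (proliferating rim, quiescent annulus, necrotic core).  Early
#' growth with abundant oxygen is exponential.
#'
#' Per-event counts of proliferation-capable cells (alive, `c > kappaProl`),
#' quiescent cells (alive, `c <= kappaProl`) and dead cells are recorded in
#' the monitor series.
#'
#' @param params a [TumourParams-class]
#' @param gridExtent voxels per axis of the fixed Cartesian grid; the
#'   domain boundary is the oxygen source, so its distance from the tumour
#'   sets how quickly hypoxia develops.
#' @param h voxel size.
#' @param blockSize side of the initial singly-occupied block.
#' @param horizon time horizon (seconds).
#' @param seed RNG seed.
#' @param snapshotTimes times at which to record state copies.
#' @param stopAtNecrosis if `TRUE`, stop at the first death event.
#' @param maxEvents safety cap.
#' @return list with `grid`, `trajectory`, `counts` (matrix of time and
#'   per-type cell counts at event times), `firstQuiescentTime`,
#'   `firstDeathTime` (`NA` if never).
#' @export
tumourExperiment <- function(params = tumourParams(), gridExtent = c(101, 101),
                             h = 1, blockSize = 5, horizon = 1000, seed = 1,
                             snapshotTimes = numeric(0),
                             stopAtNecrosis = FALSE, maxEvents = Inf) {
  grid <- buildStructuredGrid("cartesian2d", gridExtent, h = h, center = TRUE)
  co <- voxelCenters(grid)
  half <- blockSize / 2 * h
  vox <- which(abs(co[, 1]) <= half * 1.0001 & abs(co[, 2]) <= half * 1.0001)
  init <- initializeState(grid, occupancy = vox, fillCount = 1L)
  L <- assembleLaplacian(grid)
  cache <- tumourOxygenCache(grid, L)
  auxFields <- function(state, grid) {
    list(oxygen = tumourOxygen(state, grid, lambda = params@lambda, cache = cache))
  }
  extra <- function(state, grid, fields) tumourEvents(state, fields$oxygen, params)
  mon <- function(state, fields) {
    cv <- as.numeric(fields$oxygen)
    aliveAtVox <- pmax(state@u, 0L)
    nProl <- sum(aliveAtVox[cv > params@kappaProl])
    c(proliferative = nProl,
      quiescent = sum(aliveAtVox) - nProl,
      dead = sum(state@u == -1L))
  }
  stopWhen <- if (stopAtNecrosis) {
    function(state, fields) any(state@u == -1L)
  } else NULL
  traj <- runSimulation(grid, init, params@constants, horizon = horizon,
                        snapshotTimes = snapshotTimes, auxFields = auxFields,
                        extraEvents = extra, monitor = mon,
                        stopWhen = stopWhen, seed = seed,
                        maxEvents = maxEvents)
  counts <- runInfo(traj)$monitor
  firstQ <- NA_real_; firstD <- NA_real_
  if (!is.null(counts)) {
    iq <- which(counts[, "quiescent"] > 0)[1]
    if (!is.na(iq)) firstQ <- counts[iq, "time"]
    idd <- which(counts[, "dead"] > 0)[1]
    if (!is.na(idd)) firstD <- counts[idd, "time"]
  }
  list(grid = grid, trajectory = traj, counts = counts,
       firstQuiescentTime = firstQ, firstDeathTime = firstD)
}
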