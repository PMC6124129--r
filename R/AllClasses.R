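#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t solve Cholesky forceSymmetric
NULL

#' Voxel tessellation of a planar or volumetric domain
#'
#' A `VoxelGrid` describes the fixed computational tessellation on which cell
#' populations live: voxel centre coordinates, the edge-sharing neighbour
#' topology, and the geometric ingredients (shared edge length/face area
#' `e_ij`, centre distance `d_ij`, voxel area/volume) from which the discrete
#' Laplacian is assembled.  Supported tessellations are Cartesian grids in two
#' and three dimensions, the regular pointy-top hexagonal lattice, and
#' unstructured Voronoi tessellations of user-supplied seed points.
#'
#' @slot kind character: one of `"cartesian2d"`, `"cartesian3d"`,
#'   `"hexagonal"`, `"voronoi"`.
#' @slot dim integer, spatial dimension (2 or 3).
#' @slot h numeric, characteristic voxel size (centre spacing on structured
#'   grids; `NA` for Voronoi grids).
#' @slot centers numeric matrix, one row per voxel.
#' @slot nbr list of integer vectors, the edge/face-sharing neighbours of each
#'   voxel; the relation is symmetric.
#' @slot edgeFrom,edgeTo integer vectors enumerating each undirected edge once
#'   (`edgeFrom < edgeTo`).
#' @slot edgeMeasure numeric, shared edge length (2D) or face area (3D) per
#'   edge; strictly positive.
#' @slot centerDist numeric, Euclidean distance between voxel centres per edge;
#'   strictly positive.
#' @slot externalBoundary logical, flags voxels on the fixed outer domain
#'   boundary (the oxygen source in the tumour model).
#' @slot voxelMeasure numeric, area (2D) or volume (3D) per voxel.
#' @slot meta list of construction metadata (grid extent, Voronoi cell
#'   polygons, ...).
#' @seealso [buildStructuredGrid()], [buildVoronoiGrid()],
#'   [assembleLaplacian()]
#' @export
setClass("VoxelGrid",
  slots = c(
    kind = "character",
    dim = "integer",
    h = "numeric",
    centers = "matrix",
    nbr = "list",
    edgeFrom = "integer",
    edgeTo = "integer",
    edgeMeasure = "numeric",
    centerDist = "numeric",
    externalBoundary = "logical",
    voxelMeasure = "numeric",
    meta = "list"
  )
)

setValidity("VoxelGrid", function(object) {
  n <- nrow(object@centers)
  ne <- length(object@edgeFrom)
  msg <- character()
  if (!object@dim %in% c(2L, 3L)) msg <- c(msg, "dim must be 2 or 3")
  if (ncol(object@centers) != object@dim)
    msg <- c(msg, "centers must have one column per spatial dimension")
  if (length(object@nbr) != n) msg <- c(msg, "nbr must have one entry per voxel")
  if (length(object@edgeTo) != ne || length(object@edgeMeasure) != ne ||
      length(object@centerDist) != ne)
    msg <- c(msg, "edge vectors must have equal length")
  if (ne > 0) {
    if (any(object@edgeFrom >= object@edgeTo))
      msg <- c(msg, "edges must be stored with edgeFrom < edgeTo")
    if (any(object@edgeMeasure <= 0)) msg <- c(msg, "edge measures must be positive")
    if (any(object@centerDist <= 0)) msg <- c(msg, "centre distances must be positive")
  }
  if (length(object@externalBoundary) != n || length(object@voxelMeasure) != n)
    msg <- c(msg, "per-voxel slots must have one entry per voxel")
  # neighbour symmetry (derived from the undirected edge list)
  for (e in seq_len(min(ne, 50L))) { # spot check; full check in checkGrid()
    i <- object@edgeFrom[e]; j <- object@edgeTo[e]
    if (!(j %in% object@nbr[[i]]) || !(i %in% object@nbr[[j]])) {
      msg <- c(msg, "neighbour lists inconsistent with edge list")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Discrete Laplacian over a voxel grid
#'
#' Sparse symmetric operator with off-diagonal weights `w_ij = e_ij / d_ij`
#' for every neighbouring voxel pair and diagonal `-sum_j w_ij`.  The sign
#' convention is the negative-semidefinite Laplacian, so the pressure system
#' solved by [computePressure()] reads `-L p = s(u)`.  On a uniform 2D
#' Cartesian grid with unit spacing this is the standard 5-point stencil
#' (diagonal -4, neighbours +1); in 3D the 7-point stencil.
#'
#' @slot op a sparse `Matrix` (voxels x voxels).
#' @slot gridKind character, the kind of grid the operator was assembled on.
#' @export
setClass("LaplacianOperator",
  slots = c(op = "Matrix", gridKind = "character")
)

setValidity("LaplacianOperator", function(object) {
  m <- object@op
  if (nrow(m) != ncol(m)) return("operator must be square")
  rs <- Matrix::rowSums(m)
  if (max(abs(rs)) > 1e-10 * max(1, max(abs(m@x))))
    return("row sums must vanish (constants in the kernel)")
  TRUE
})

#' One scalar value per voxel
#'
#' Thin wrapper around a numeric vector used for the cellular pressure `p`,
#' chemoattractant/-repellent concentrations (Slit `S`), and the oxygen
#' concentration `c`.  Behaves as a plain numeric vector in arithmetic.
#'
#' @slot name character label for the field.
#' @export
setClass("ScalarField", contains = "numeric", slots = c(name = "character"))

#' Conversion factors from edge currents to movement rates
#'
#' @slot D1 rate per unit current for moves into never-visited empty voxels
#'   (pristine extracellular matrix).
#' @slot D2 rate per unit current for moves into previously visited empty
#'   voxels.  Typically `D1 << D2`: unvisited matrix is less penetrable.
#' @slot D3 rate per unit current for crowding moves, a cell in a doubly
#'   occupied voxel entering a singly occupied neighbour.
#' @slot alphaAdh cell-cell adhesion constant (>= 0, default 0); see
#'   [adhesionCorrection()].
#' @slot chi1 chemotactic pressure-drift sensitivity (the advective term in
#'   the pressure equation); see [computePressureWithDrift()].
#' @slot chi2 active chemotactic movement affinity; see
#'   [activeDriftCurrent()].
#' @export
setClass("RateConstants",
  slots = c(D1 = "numeric", D2 = "numeric", D3 = "numeric",
            alphaAdh = "numeric", chi1 = "numeric", chi2 = "numeric")
)

setValidity("RateConstants", function(object) {
  v <- c(object@D1, object@D2, object@D3, object@alphaAdh, object@chi1, object@chi2)
  if (length(v) != 6 || anyNA(v)) return("all rate constants must be single finite numbers")
  if (any(c(object@D1, object@D2, object@D3, object@alphaAdh) < 0))
    return("D1, D2, D3 and alphaAdh must be nonnegative")
  TRUE
})

#' A set of enumerated discrete events with rates
#'
#' Holds the currently possible discrete events (cell moves, proliferation,
#' death, degradation) with their nonnegative rates, plus the cached total
#' rate used by the Gillespie direct method.  Events with zero rate are never
#' stored.
#'
#' @slot type character, one of `"move"`, `"proliferate"`, `"die"`,
#'   `"degrade"`.
#' @slot from integer, source voxel.
#' @slot to integer, destination voxel (`NA` for non-move events).
#' @slot rate numeric, strictly positive rates.
#' @slot totalRate numeric, `sum(rate)`.
#' @export
setClass("EventSet",
  slots = c(type = "character", from = "integer", to = "integer",
            rate = "numeric", totalRate = "numeric")
)

setValidity("EventSet", function(object) {
  n <- length(object@rate)
  if (length(object@type) != n || length(object@from) != n || length(object@to) != n)
    return("event columns must have equal length")
  if (n > 0 && any(object@rate <= 0)) return("stored rates must be positive")
  if (abs(object@totalRate - sum(object@rate)) > 1e-9 * max(1, sum(object@rate)))
    return("cached total rate is stale")
  TRUE
})

#' State of the discrete cell population
#'
#' Per-voxel occupancy, per-cell registry with identity and internal
#' (signalling) state, visited/dead bookkeeping, and the simulation clock.
#' Occupancy `u_i` takes values in `{-1, 0, 1, 2}`: the carrying capacity is
#' two cells per voxel, and `u_i = -1` marks a voxel occupied by a single
#' dead cell (tumour model).  The `visited` flag records whether a voxel has
#' ever contained a living cell and never reverts.
#'
#' The cell registry is stored as parallel vectors (`cellId`, `cellVoxel`,
#' `cellAlive`) plus a numeric `internal` matrix with one row per registered
#' cell (zero columns for mechanics-only runs).  Cell ids are never reused
#' within a run.
#'
#' @slot u integer occupancy per voxel.
#' @slot visited logical per voxel.
#' @slot time numeric, current simulation time (simulation time units).
#' @slot cellId,cellVoxel integer vectors over the registry.
#' @slot cellAlive logical vector over the registry.
#' @slot internal numeric matrix, per-cell internal state.
#' @slot nextId integer, next unused cell id.
#' @seealso [initializeState()], [applyEvent()], [checkState()]
#' @export
setClass("CellState",
  slots = c(u = "integer", visited = "logical", time = "numeric",
            cellId = "integer", cellVoxel = "integer", cellAlive = "logical",
            internal = "matrix", nextId = "integer")
)

setValidity("CellState", function(object) {
  msg <- character()
  if (any(object@u < -1L | object@u > 2L))
    msg <- c(msg, "occupancy must lie in {-1, 0, 1, 2}")
  nc <- length(object@cellId)
  if (length(object@cellVoxel) != nc || length(object@cellAlive) != nc ||
      nrow(object@internal) != nc)
    msg <- c(msg, "cell registry vectors must be aligned")
  if (anyDuplicated(object@cellId)) msg <- c(msg, "cell ids must be unique")
  if (sum(object@u == 2L) * 2L + sum(object@u == 1L) != sum(object@cellAlive))
    msg <- c(msg, "living-cell count must match occupancy")
  if (any(object@u != 0L & !object@visited))
    msg <- c(msg, "occupied voxels must be flagged visited")
  if (length(msg)) msg else TRUE
})

#' Result of an event-driven simulation run
#'
#' @slot snapshots list of [CellState-class] objects recorded at
#'   `snapshotTimes`.
#' @slot snapshotTimes numeric.
#' @slot events data.frame event log with columns `time`, `type`, `from`,
#'   `to`, `cell`.
#' @slot finalState the [CellState-class] at termination.
#' @slot info list of run metadata (seed, termination reason, running maxima,
#'   monitor series, ...).
#' @export
setClass("SimulationTrajectory",
  slots = c(snapshots = "list", snapshotTimes = "numeric",
            events = "data.frame", finalState = "CellState", info = "list")
)

#' Delta-Notch lateral-inhibition model parameters
#'
#' Dimensionless Collier-type lateral inhibition: Notch production is an
#' increasing Hill function `f(x) = x^k / (a + x^k)` of the mean Delta level
#' over neighbouring cells, and Delta production a decreasing Hill function
#' `g(x) = 1 / (1 + b x^h)` of the cell's own Notch.
#'
#' @slot a Notch activation threshold constant (default 0.01).
#' @slot b Delta inhibition strength (default 100).
#' @slot v Delta relative rate (default 1).
#' @slot k Hill exponent of `f` (default 2).
#' @slot h Hill exponent of `g` (default 2).
#' @slot speedFactor scaling of the whole right-hand side (1 couples the
#'   signalling time-scale to growth; 50 puts signalling in quasi-steady
#'   state between growth events).
#' @export
setClass("DeltaNotchParams",
  slots = c(a = "numeric", b = "numeric", v = "numeric",
            k = "numeric", h = "numeric", speedFactor = "numeric")
)

setValidity("DeltaNotchParams", function(object) {
  v <- c(object@a, object@b, object@v, object@k, object@h, object@speedFactor)
  if (anyNA(v) || any(v <= 0)) return("all Delta-Notch parameters must be positive")
  TRUE
})

#' Avascular tumour model parameters
#'
#' Oxygen-limited proliferation/death kinetics combined with the movement
#' conversion factors.  Rates are per second; oxygen thresholds refer to the
#' concentration normalised to 1 at the fixed external boundary.
#'
#' @slot lambda oxygen consumption rate per living cell.
#' @slot kappaProl minimum oxygen concentration for proliferation.
#' @slot rhoProl proliferation rate for singly occupied voxels above
#'   `kappaProl`.
#' @slot kappaDeath oxygen threshold for survival (`kappaDeath < kappaProl`
#'   in the regime studied).
#' @slot rhoDeath death rate below `kappaDeath`.
#' @slot rhoDeg degradation rate of dead cells.
#' @slot constants a [RateConstants-class] object (D1, D2, D3).
#' @export
setClass("TumourParams",
  slots = c(lambda = "numeric", kappaProl = "numeric", rhoProl = "numeric",
            kappaDeath = "numeric", rhoDeath = "numeric", rhoDeg = "numeric",
            constants = "RateConstants")
)

setValidity("TumourParams", function(object) {
  v <- c(object@lambda, object@kappaProl, object@rhoProl,
         object@kappaDeath, object@rhoDeath, object@rhoDeg)
  if (anyNA(v) || any(v < 0)) return("all tumour parameters must be nonnegative")
  TRUE
})
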