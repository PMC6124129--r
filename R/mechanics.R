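# Quasi-steady pressure solves, edge currents and movement-event enumeration.

#' Movement-rate conversion factors
#'
#' Constructor for [RateConstants-class].  All movement rates are products of
#' a dimensionless edge current (pressure or chemotactic gradient integrated
#' over the shared voxel edge) and one of these conversion factors, so the
#' factors carry the units of inverse time; the framework fixes no absolute
#' time unit.
#'
#' @param D1 rate per unit current into never-visited empty voxels.
#' @param D2 rate per unit current into previously visited empty voxels.
#' @param D3 rate per unit current for crowding moves (doubly occupied into
#'   singly occupied).
#' @param alphaAdh adhesion constant, `>= 0`.
#' @param chi1 chemotactic pressure-drift sensitivity.
#' @param chi2 active chemotactic movement affinity.
#' @return a [RateConstants-class]
#' @export
rateConstants <- function(D1 = 1, D2 = 1, D3 = 1, alphaAdh = 0,
                          chi1 = 0, chi2 = 0) {
  new("RateConstants", D1 = as.numeric(D1), D2 = as.numeric(D2),
      D3 = as.numeric(D3), alphaAdh = as.numeric(alphaAdh),
      chi1 = as.numeric(chi1), chi2 = as.numeric(chi2))
}

#' Create a scalar field over a grid
#'
#' @param values numeric vector, one value per voxel.
#' @param name label.
#' @return a [ScalarField-class]
#' @export
scalarField <- function(values, name = "field") {
  new("ScalarField", as.numeric(values), name = name)
}

.restrictedSolve <- function(L, act, rhs) {
  M <- -L[act, act, drop = FALSE]
  sol <- try(Matrix::solve(M, rhs), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("pressure solve failed: the populated region has no free boundary ",
         "(restricted Laplacian is singular)")
  as.numeric(sol)
}

#' Solve the quasi-steady cellular pressure
#'
#' Solves `-L p = s(u)` restricted to the populated voxels, with homogeneous
#' Dirichlet data `p = 0` on the discrete free boundary (the empty voxels
#' adjacent to the population) and `p = 0` outside.  The source is
#' `s(u_i) = 1` for doubly occupied voxels and 0 otherwise; dead cells
#' occupy voxels but are not sources.  By the discrete maximum principle the
#' solution is nonnegative, and it vanishes identically when no voxel is
#' overcrowded (the population is then in mechanical equilibrium).
#'
#' @param state a [CellState-class]
#' @param grid a [VoxelGrid-class]
#' @param L a [LaplacianOperator-class] for `grid` (assembled once and
#'   reused).
#' @return a [ScalarField-class] of pressures.
#' @export
computePressure <- function(state, grid, L = assembleLaplacian(grid)) {
  u <- state@u
  n <- length(u)
  p <- numeric(n)
  act <- which(u != 0L)
  src <- as.numeric(u[act] == 2L)
  if (length(act) == 0 || all(src == 0)) return(scalarField(p, "pressure"))
  if (length(act) == n)
    stop("pressure solve failed: the populated region has no free boundary")
  p[act] <- .restrictedSolve(laplacianMatrix(L), act, src)
  scalarField(p, "pressure")
}

#' Pressure with chemotactic drift
#'
#' Solves the steady drift-diffusion pressure problem
#' `-div(grad p + p * chi1 * grad S) = s(u)` on the populated voxels with
#' `p = 0` on the free boundary, using the edge-based discretization: the
#' flux on edge `(i, j)` is `(e_ij/d_ij) * ((p_i - p_j) + chi1 * pbar_ij *
#' (S_i - S_j))` with `pbar_ij` the arithmetic edge average of `p` (a
#' central, second-order scheme; adequate at the drift magnitudes used here,
#' with upwinding as the standard alternative for stronger advection).
#' Reduces exactly to [computePressure()] when `chi1 = 0` or `S` is
#' constant.
#'
#' @param state a [CellState-class]
#' @param grid a [VoxelGrid-class]
#' @param S a [ScalarField-class] (e.g. from [slitField()]).
#' @param chi1 drift sensitivity.
#' @param L a [LaplacianOperator-class] for `grid`.
#' @return a [ScalarField-class] of pressures.
#' @export
computePressureWithDrift <- function(state, grid, S, chi1,
                                     L = assembleLaplacian(grid)) {
  if (chi1 == 0) return(computePressure(state, grid, L))
  u <- state@u
  n <- length(u)
  Sv <- as.numeric(S)
  if (length(Sv) != n) stop("S must have one value per voxel")
  p <- numeric(n)
  act <- which(u != 0L)
  src <- as.numeric(u[act] == 2L)
  if (length(act) == 0 || all(src == 0)) return(scalarField(p, "pressure"))
  if (length(act) == n)
    stop("pressure solve failed: the populated region has no free boundary")
  pos <- integer(n); pos[act] <- seq_along(act)
  a <- grid@edgeFrom; b <- grid@edgeTo
  keep <- pos[a] > 0L | pos[b] > 0L
  a <- a[keep]; b <- b[keep]
  w <- (grid@edgeMeasure / grid@centerDist)[keep]
  dS <- Sv[a] - Sv[b]
  # flux_{i->j} = w [ (p_i - p_j) + chi1 (p_i + p_j)/2 (S_i - S_j) ]
  # row i of sum_j flux_ij = s_i:
  #   coefficient of p_i : w (1 + chi1 dS_ij / 2)
  #   coefficient of p_j : w (-1 + chi1 dS_ij / 2),  dS_ij = S_i - S_j
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  addTriplets <- function(rows, cols, vals) {
    ii <<- c(ii, rows); jj <<- c(jj, cols); xx <<- c(xx, vals)
  }
  selA <- pos[a] > 0L # row a contributions
  addTriplets(pos[a][selA], pos[a][selA], (w * (1 + chi1 * dS / 2))[selA])
  inB <- selA & pos[b] > 0L
  addTriplets(pos[a][inB], pos[b][inB], (w * (-1 + chi1 * dS / 2))[inB])
  selB <- pos[b] > 0L # row b contributions (edge direction reversed: dS -> -dS)
  addTriplets(pos[b][selB], pos[b][selB], (w * (1 - chi1 * dS / 2))[selB])
  inA <- selB & pos[a] > 0L
  addTriplets(pos[b][inA], pos[a][inA], (w * (-1 - chi1 * dS / 2))[inA])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(act), length(act)))
  sol <- try(Matrix::solve(A, src), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("drift-pressure solve failed (singular modified system); ",
         "active voxels: ", length(act), ", chi1 = ", chi1)
  p[act] <- as.numeric(sol)
  scalarField(p, "pressure")
}

.edgeIndex <- function(grid, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  idx <- which(grid@edgeFrom == lo & grid@edgeTo == hi)
  if (length(idx) != 1)
    stop(sprintf("voxels %d and %d are not neighbours", i, j))
  idx
}

#' Current across one voxel edge
#'
#' The pressure gradient integrated over the shared edge,
#' `I_ij = (e_ij/d_ij) (p_i - p_j)`; antisymmetric in `(i, j)`.  A positive
#' value drives movement from `i` to `j`.
#'
#' @param p a [ScalarField-class] of pressures.
#' @param grid a [VoxelGrid-class]
#' @param i,j neighbouring voxel indices.
#' @return numeric current.
#' @export
edgeCurrent <- function(p, grid, i, j) {
  idx <- .edgeIndex(grid, i, j)
  w <- grid@edgeMeasure[idx] / grid@centerDist[idx]
  w * (as.numeric(p)[i] - as.numeric(p)[j])
}

#' Adhesion resistance for a candidate move
#'
#' Cell-cell adhesion with cells in populated neighbour voxels `k` of the
#' source voxel `i` resists a move towards `j`.  The (nonpositive)
#' correction to the edge current is
#' `dI = d_ij * sum_k alphaAdh * e_ik * min(0, r_ij . r_ik)` over populated
#' neighbours `k != j`, with `r_ij`, `r_ik` unit vectors between voxel
#' centres: only neighbours with a component opposite to the direction of
#' motion pull back.  The correction is added to the edge current before
#' rate conversion and the resulting rate is floored at zero (a resistance
#' can stop, but never reverse, a move).
#'
#' @param state a [CellState-class]
#' @param grid a [VoxelGrid-class]
#' @param i,j neighbouring voxel indices (move `i -> j`).
#' @param alphaAdh adhesion constant `>= 0`.
#' @return numeric, `<= 0`.
#' @export
adhesionCorrection <- function(state, grid, i, j, alphaAdh) {
  if (alphaAdh == 0) return(0)
  idx <- .edgeIndex(grid, i, j)
  dij <- grid@centerDist[idx]
  ci <- grid@centers[i, ]
  rij <- (grid@centers[j, ] - ci); rij <- rij / sqrt(sum(rij^2))
  acc <- 0
  for (k in grid@nbr[[i]]) {
    if (k == j || state@u[k] == 0L) next
    idk <- .edgeIndex(grid, i, k)
    rik <- (grid@centers[k, ] - ci); rik <- rik / sqrt(sum(rik^2))
    acc <- acc + alphaAdh * grid@edgeMeasure[idk] * min(0, sum(rij * rik))
  }
  dij * acc
}

#' Active chemotactic current across an edge
#'
#' Pressure-independent movement current down the gradient of a sensed
#' field, `chi2 * (e_ij/d_ij) * (S_i - S_j)`.  Positive values drive moves
#' from `i` to `j`; the current is combined additively with the
#' pressure-driven current before rate classification.
#'
#' @param S a [ScalarField-class]
#' @param grid a [VoxelGrid-class]
#' @param i,j neighbouring voxel indices.
#' @param chi2 movement affinity.
#' @return numeric current.
#' @export
activeDriftCurrent <- function(S, grid, i, j, chi2) {
  idx <- .edgeIndex(grid, i, j)
  w <- grid@edgeMeasure[idx] / grid@centerDist[idx]
  chi2 * w * (as.numeric(S)[i] - as.numeric(S)[j])
}

#' Steady-state concentration of a line-source morphogen
#'
#' Closed-form steady state of diffusion with linear degradation and a line
#' source at `x1 = Xs`:
#' `S(x1, x2) = Q / (2 sqrt(k DS)) * exp(-sqrt(k/DS) |x1 - Xs|)`,
#' independent of `x2` and maximal on the source line.  Used for the Slit
#' chemo-repulsion experiment.
#'
#' @param grid a [VoxelGrid-class]
#' @param DS diffusivity (> 0).
#' @param k degradation rate (> 0).
#' @param Q source strength (> 0).
#' @param Xs source line position.
#' @return a [ScalarField-class]
#' @export
slitField <- function(grid, DS = 50, k = 0.1, Q = 2, Xs = 50) {
  stopifnot(DS > 0, k > 0, Q > 0)
  x1 <- voxelCenters(grid)[, 1]
  scalarField(Q / (2 * sqrt(k * DS)) * exp(-sqrt(k / DS) * abs(x1 - Xs)),
              name = "slit")
}

#' Build an event set
#'
#' Zero-rate events are dropped; the total rate is cached.
#'
#' @param type,from,to,rate parallel event columns.
#' @return an [EventSet-class]
#' @export
eventSet <- function(type = character(0), from = integer(0),
                     to = rep(NA_integer_, length(from)), rate = numeric(0)) {
  if (any(rate < 0)) stop("internal error: negative event rate")
  keep <- rate > 0
  new("EventSet", type = as.character(type[keep]), from = as.integer(from[keep]),
      to = as.integer(to[keep]), rate = as.numeric(rate[keep]),
      totalRate = sum(rate[keep]))
}

#' Merge event sets
#'
#' @param ... [EventSet-class] objects.
#' @return an [EventSet-class]
#' @export
mergeEventSets <- function(...) {
  sets <- list(...)
  new("EventSet",
      type = unlist(lapply(sets, function(s) s@type), use.names = FALSE),
      from = unlist(lapply(sets, function(s) s@from), use.names = FALSE),
      to = unlist(lapply(sets, function(s) s@to), use.names = FALSE),
      rate = unlist(lapply(sets, function(s) s@rate), use.names = FALSE),
      totalRate = sum(vapply(sets, function(s) s@totalRate, numeric(1))))
}

#' Enumerate pressure-driven movement events
#'
#' For every ordered neighbour pair `(i, j)` with positive combined current
#' (pressure plus, optionally, active chemotactic drift), a move event is
#' generated according to the three-case rate law: into an empty voxel at
#' rate `D1 * I` (never visited) or `D2 * I` (previously visited), and the
#' crowding case doubly occupied into singly occupied at `D3 * I`.  Voxels
#' at carrying capacity or holding a dead cell are never destinations, and
#' only voxels with living cells are sources.  With `alphaAdh > 0` the
#' adhesion correction is added to each candidate current and the resulting
#' rate floored at zero.  The destination's visited flag is read at
#' enumeration time.
#'
#' @param state a [CellState-class]
#' @param grid a [VoxelGrid-class]
#' @param p pressure [ScalarField-class] for the current state.
#' @param constants a [RateConstants-class]
#' @param S optional sensed field for active drift (used when
#'   `constants@chi2 > 0`).
#' @return an [EventSet-class] of `"move"` events.
#' @export
enumerateMoveEvents <- function(state, grid, p, constants, S = NULL) {
  u <- state@u
  vis <- state@visited
  a <- grid@edgeFrom; b <- grid@edgeTo
  occ <- u != 0L
  sel <- occ[a] | occ[b]
  a <- a[sel]; b <- b[sel]
  if (!length(a)) return(eventSet())
  w <- (grid@edgeMeasure / grid@centerDist)[sel]
  pv <- as.numeric(p)
  I <- w * (pv[a] - pv[b])
  chi2 <- constants@chi2
  if (chi2 != 0 && !is.null(S)) {
    Sv <- as.numeric(S)
    I <- I + chi2 * w * (Sv[a] - Sv[b])
  }
  pos <- I > 0
  from <- a; from[!pos] <- b[!pos]
  to <- b; to[!pos] <- a[!pos]
  Iabs <- abs(I)
  keep <- Iabs > 0 & u[from] >= 1L &
    (u[to] == 0L | (u[from] == 2L & u[to] == 1L))
  from <- from[keep]; to <- to[keep]; Iabs <- Iabs[keep]
  if (!length(from)) return(eventSet())
  if (constants@alphaAdh > 0) {
    corr <- vapply(seq_along(from), function(q) {
      adhesionCorrection(state, grid, from[q], to[q], constants@alphaAdh)
    }, numeric(1))
    Iabs <- pmax(Iabs + corr, 0)
  }
  D <- ifelse(u[to] == 1L, constants@D3,
              ifelse(vis[to], constants@D2, constants@D1))
  eventSet(type = rep("move", length(from)), from = from, to = to,
           rate = D * Iabs)
}
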