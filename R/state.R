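# Population state: occupancy, cell registry, event application.

#' Initialize a cell population on a grid
#'
#' @param grid a [VoxelGrid-class]
#' @param occupancy integer vector of per-voxel cell counts in `{0, 1, 2}`
#'   (length `nVoxels(grid)`), or a vector of voxel indices each receiving
#'   `fillCount` cells.
#' @param internalInit per-cell internal state: `NULL` (none), a named numeric
#'   vector replicated for every cell, a matrix with one row per cell, or a
#'   function `f(nCells)` returning such a matrix (useful for randomised
#'   initial signalling states).
#' @param fillCount cells per voxel when `occupancy` is given as indices.
#' @return a [CellState-class] with `t = 0`, consecutive cell ids starting at
#'   1 (assigned in voxel order) and `visited == (u != 0)`.
#' @examples
#' g <- buildStructuredGrid("cartesian2d", c(5, 5))
#' s <- initializeState(g, occupancy = rep(1, 25))
#' nLivingCells(s)  # 25
#' @export
initializeState <- function(grid, occupancy, internalInit = NULL, fillCount = 2L) {
  stopifnot(is(grid, "VoxelGrid"))
  n <- nVoxels(grid)
  if (length(occupancy) == n) {
    u <- as.integer(occupancy)
    if (any(u < 0L | u > 2L))
      stop("configuration error: initial occupancy must lie in {0, 1, 2}")
  } else {
    idx <- as.integer(occupancy)
    if (anyNA(idx) || any(idx < 1L | idx > n))
      stop("configuration error: occupancy voxel indices out of range")
    if (!fillCount %in% 1:2)
      stop("configuration error: fillCount must be 1 or 2")
    u <- integer(n)
    u[idx] <- as.integer(fillCount)
  }
  if (any(u < 0L | u > 2L))
    stop("configuration error: initial occupancy must lie in {0, 1, 2}")
  nc <- sum(u)
  voxelOfCell <- rep(seq_len(n), times = u)
  internal <- .resolveInternalInit(internalInit, nc)
  state <- new("CellState",
    u = u, visited = u != 0L, time = 0,
    cellId = seq_len(nc), cellVoxel = as.integer(voxelOfCell),
    cellAlive = rep(TRUE, nc), internal = internal,
    nextId = nc + 1L)
  validObject(state)
  state
}

.resolveInternalInit <- function(internalInit, nc) {
  if (is.null(internalInit)) {
    matrix(numeric(0), nrow = nc, ncol = 0)
  } else if (is.function(internalInit)) {
    m <- internalInit(nc)
    stopifnot(is.matrix(m), nrow(m) == nc)
    m
  } else if (is.matrix(internalInit)) {
    stopifnot(nrow(internalInit) == nc)
    internalInit
  } else {
    m <- matrix(rep(as.numeric(internalInit), each = nc), nrow = nc)
    colnames(m) <- names(internalInit)
    m
  }
}

#' Populated domain and its free boundary
#'
#' Returns the set of populated voxels (occupancy non-zero, including voxels
#' holding a dead cell) and the discrete free boundary: the empty voxels
#' sharing an edge with a populated one.  The pressure field is pinned to
#' zero on this boundary.
#'
#' @param state a [CellState-class]
#' @param grid a [VoxelGrid-class]
#' @return list with integer vectors `domain` and `boundary` (disjoint).
#' @export
activeDomain <- function(state, grid) {
  dom <- which(state@u != 0L)
  if (length(dom) == 0) return(list(domain = integer(0), boundary = integer(0)))
  nb <- unique(unlist(grid@nbr[dom], use.names = FALSE))
  bd <- nb[state@u[nb] == 0L]
  list(domain = dom, boundary = sort(bd))
}

#' Apply a discrete event to the population
#'
#' Applies one of the four event types atomically, updating occupancy,
#' registry, and visited flags together:
#' \describe{
#'   \item{move}{one cell moves from voxel `from` to neighbour `to`; requires
#'     living cells in `from` and `u[to] < u[from]` with `u[to]` in `{0, 1}`
#'     (a voxel at carrying capacity, or holding a dead cell, is never a
#'     destination).  When `from` is doubly occupied the moving cell is drawn
#'     uniformly at random among its living cells (cells are mechanically
#'     indistinguishable; identity only matters for internal state).}
#'   \item{proliferate}{requires `u[from] == 1`; the daughter is placed in the
#'     mother's voxel (`u: 1 -> 2`), creating a pressure source, and inherits
#'     the mother's internal state.}
#'   \item{die}{requires exactly one living cell in `from`; converts it to a
#'     dead cell (`u: 1 -> -1`).}
#'   \item{degrade}{requires `u[from] == -1`; removes the dead cell
#'     (`u: -1 -> 0`, visited stays `TRUE`).}
#' }
#' A violated precondition signals an engine bug and raises an error; it is
#' never silently ignored.
#'
#' @param state a [CellState-class]
#' @param type one of `"move"`, `"proliferate"`, `"die"`, `"degrade"`.
#' @param from source voxel index.
#' @param to destination voxel index (moves only).
#' @return list with the updated `state` and the `cell` id affected.
#' @export
applyEvent <- function(state, type, from, to = NA_integer_) {
  u <- state@u
  switch(type,
    move = {
      if (is.na(to)) stop("illegal event: move without destination")
      if (u[from] < 1L || u[to] < 0L || u[to] > 1L || u[to] >= u[from])
        stop(sprintf("illegal event: move %d -> %d with u = (%d, %d)",
                     from, to, u[from], u[to]))
      cand <- which(state@cellVoxel == from & state@cellAlive)
      cell <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
      state@cellVoxel[cell] <- as.integer(to)
      state@u[from] <- u[from] - 1L
      state@u[to] <- u[to] + 1L
      state@visited[to] <- TRUE
      list(state = state, cell = state@cellId[cell])
    },
    proliferate = {
      if (u[from] != 1L)
        stop(sprintf("illegal event: proliferation in voxel %d with u = %d",
                     from, u[from]))
      mother <- which(state@cellVoxel == from & state@cellAlive)
      state@u[from] <- 2L
      state@cellId <- c(state@cellId, state@nextId)
      state@cellVoxel <- c(state@cellVoxel, as.integer(from))
      state@cellAlive <- c(state@cellAlive, TRUE)
      state@internal <- rbind(state@internal, state@internal[mother, , drop = FALSE])
      newId <- state@nextId
      state@nextId <- state@nextId + 1L
      list(state = state, cell = newId)
    },
    die = {
      if (u[from] != 1L)
        stop(sprintf("illegal event: death in voxel %d with u = %d", from, u[from]))
      cell <- which(state@cellVoxel == from & state@cellAlive)
      state@cellAlive[cell] <- FALSE
      state@u[from] <- -1L
      list(state = state, cell = state@cellId[cell])
    },
    degrade = {
      if (u[from] != -1L)
        stop(sprintf("illegal event: degradation in voxel %d with u = %d",
                     from, u[from]))
      cell <- which(state@cellVoxel == from & !state@cellAlive)
      keep <- setdiff(seq_along(state@cellId), cell)
      id <- state@cellId[cell]
      state@cellId <- state@cellId[keep]
      state@cellVoxel <- state@cellVoxel[keep]
      state@cellAlive <- state@cellAlive[keep]
      state@internal <- state@internal[keep, , drop = FALSE]
      state@u[from] <- 0L
      list(state = state, cell = id)
    },
    stop(sprintf("illegal event: unknown type '%s'", type))
  )
}

#' Full consistency check of a population state
#'
#' Verifies the registry/occupancy correspondence voxel by voxel: `u_i` in
#' `{1, 2}` means exactly `u_i` living cells registered there, `u_i = -1`
#' exactly one dead cell, `u_i = 0` none; visited covers all occupied voxels;
#' total living cells equal `sum(max(u, 0))`.  Used by tests and by the
#' engine in debug mode.
#'
#' @param state a [CellState-class]
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
checkState <- function(state) {
  stopifnot(is(state, "CellState"))
  n <- length(state@u)
  living <- tabulate(state@cellVoxel[state@cellAlive], nbins = n)
  dead <- tabulate(state@cellVoxel[!state@cellAlive], nbins = n)
  expectLiving <- pmax(state@u, 0L)
  expectDead <- as.integer(state@u == -1L)
  if (!all(living == expectLiving))
    stop("state invariant violated: living-cell registry inconsistent with occupancy")
  if (!all(dead == expectDead))
    stop("state invariant violated: dead-cell registry inconsistent with occupancy")
  if (any(state@u != 0L & !state@visited))
    stop("state invariant violated: occupied voxel not flagged visited")
  if (sum(state@cellAlive) != sum(expectLiving))
    stop("state invariant violated: living-cell count mismatch")
  invisible(TRUE)
}
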