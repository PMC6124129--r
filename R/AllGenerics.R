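# Generics and accessors.  Slots are never accessed with @ by user code;
# these accessors are the supported surface.

#' @rdname VoxelGrid-class
#' @param object,x a [VoxelGrid-class]
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))

#' @rdname VoxelGrid-class
#' @export
setMethod("nVoxels", "VoxelGrid", function(object) nrow(object@centers))

#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelCenters", function(object) standardGeneric("voxelCenters"))

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelCenters", "VoxelGrid", function(object) object@centers)

#' @rdname VoxelGrid-class
#' @param i voxel index (omit for the full neighbour list)
#' @export
setGeneric("voxelNeighbours", function(object, i) standardGeneric("voxelNeighbours"))

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelNeighbours", "VoxelGrid", function(object, i) {
  if (missing(i)) object@nbr else object@nbr[[i]]
})

#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelMeasure", function(object) standardGeneric("voxelMeasure"))

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelMeasure", "VoxelGrid", function(object) object@voxelMeasure)

#' @rdname VoxelGrid-class
#' @export
setGeneric("externalBoundary", function(object) standardGeneric("externalBoundary"))

#' @rdname VoxelGrid-class
#' @export
setMethod("externalBoundary", "VoxelGrid", function(object) object@externalBoundary)

#' Edge table of a voxel grid
#'
#' One row per undirected edge with the shared-boundary measure `e_ij`, the
#' centre distance `d_ij` and the Laplacian weight `w_ij = e_ij / d_ij`.
#'
#' @param object a [VoxelGrid-class]
#' @return a data.frame with columns `from`, `to`, `e`, `d`, `w`.
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "VoxelGrid", function(object) {
  data.frame(from = object@edgeFrom, to = object@edgeTo,
             e = object@edgeMeasure, d = object@centerDist,
             w = object@edgeMeasure / object@centerDist)
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %s, %dD, %d voxels, %d edges\n",
              object@kind, object@dim, nVoxels(object), length(object@edgeFrom)))
  if (!is.na(object@h)) cat(sprintf("  voxel size h = %g\n", object@h))
  cat(sprintf("  external boundary voxels: %d\n", sum(object@externalBoundary)))
})

#' @rdname LaplacianOperator-class
#' @param object a [LaplacianOperator-class]
#' @export
setGeneric("laplacianMatrix", function(object) standardGeneric("laplacianMatrix"))

#' @rdname LaplacianOperator-class
#' @export
setMethod("laplacianMatrix", "LaplacianOperator", function(object) object@op)

setMethod("show", "LaplacianOperator", function(object) {
  cat(sprintf("LaplacianOperator on a %s grid: %d x %d, %d nonzeros\n",
              object@gridKind, nrow(object@op), ncol(object@op),
              length(object@op@x)))
})

#' @rdname CellState-class
#' @param object a [CellState-class]
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname CellState-class
#' @export
setMethod("occupancy", "CellState", function(object) object@u)

#' @rdname CellState-class
#' @export
setGeneric("visitedVoxels", function(object) standardGeneric("visitedVoxels"))

#' @rdname CellState-class
#' @export
setMethod("visitedVoxels", "CellState", function(object) object@visited)

#' @rdname CellState-class
#' @export
setGeneric("simTime", function(object) standardGeneric("simTime"))

#' @rdname CellState-class
#' @export
setMethod("simTime", "CellState", function(object) object@time)

#' @rdname CellState-class
#' @export
setGeneric("nLivingCells", function(object) standardGeneric("nLivingCells"))

#' @rdname CellState-class
#' @export
setMethod("nLivingCells", "CellState", function(object) sum(object@cellAlive))

#' Cell registry as a data.frame
#'
#' @param object a [CellState-class]
#' @return data.frame with columns `id`, `voxel`, `alive` and one column per
#'   internal-state variable.
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))

#' @rdname cellTable
#' @export
setMethod("cellTable", "CellState", function(object) {
  df <- data.frame(id = object@cellId, voxel = object@cellVoxel,
                   alive = object@cellAlive)
  if (ncol(object@internal) > 0) {
    st <- as.data.frame(object@internal)
    names(st) <- colnames(object@internal)
    df <- cbind(df, st)
  }
  df
})

#' Per-cell internal (signalling) state
#'
#' @param object a [CellState-class]
#' @return numeric matrix, one row per registered cell.
#' @export
setGeneric("internalState", function(object) standardGeneric("internalState"))

#' @rdname internalState
#' @export
setMethod("internalState", "CellState", function(object) object@internal)

setMethod("show", "CellState", function(object) {
  cat(sprintf("CellState at t = %g: %d living cells (%d dead) on %d voxels\n",
              object@time, sum(object@cellAlive), sum(!object@cellAlive),
              length(object@u)))
  cat(sprintf("  occupancy: %d empty, %d single, %d double, %d necrotic; %d visited\n",
              sum(object@u == 0L), sum(object@u == 1L), sum(object@u == 2L),
              sum(object@u == -1L), sum(object@visited)))
})

#' @rdname EventSet-class
#' @param object an [EventSet-class]
#' @export
setGeneric("totalRate", function(object) standardGeneric("totalRate"))

#' @rdname EventSet-class
#' @export
setMethod("totalRate", "EventSet", function(object) object@totalRate)

#' @rdname EventSet-class
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @rdname EventSet-class
#' @export
setMethod("nEvents", "EventSet", function(object) length(object@rate))

#' Events as a data.frame
#'
#' @param object an [EventSet-class]
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname eventTable
#' @export
setMethod("eventTable", "EventSet", function(object) {
  data.frame(type = object@type, from = object@from, to = object@to,
             rate = object@rate)
})

setMethod("show", "EventSet", function(object) {
  cat(sprintf("EventSet: %d events, total rate %g\n",
              length(object@rate), object@totalRate))
  if (length(object@rate)) print(table(object@type))
})

setMethod("show", "SimulationTrajectory", function(object) {
  cat(sprintf("SimulationTrajectory: %d events, %d snapshots, final t = %g\n",
              nrow(object@events), length(object@snapshots),
              object@finalState@time))
  if (!is.null(object@info$termination))
    cat(sprintf("  terminated: %s\n", object@info$termination))
})

#' @rdname SimulationTrajectory-class
#' @param object a [SimulationTrajectory-class]
#' @export
setGeneric("eventLog", function(object) standardGeneric("eventLog"))

#' @rdname SimulationTrajectory-class
#' @export
setMethod("eventLog", "SimulationTrajectory", function(object) object@events)

#' @rdname SimulationTrajectory-class
#' @export
setGeneric("finalState", function(object) standardGeneric("finalState"))

#' @rdname SimulationTrajectory-class
#' @export
setMethod("finalState", "SimulationTrajectory", function(object) object@finalState)

#' @rdname SimulationTrajectory-class
#' @export
setGeneric("snapshots", function(object) standardGeneric("snapshots"))

#' @rdname SimulationTrajectory-class
#' @export
setMethod("snapshots", "SimulationTrajectory", function(object) object@snapshots)

#' @rdname SimulationTrajectory-class
#' @export
setGeneric("runInfo", function(object) standardGeneric("runInfo"))

#' @rdname SimulationTrajectory-class
#' @export
setMethod("runInfo", "SimulationTrajectory", function(object) object@info)
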