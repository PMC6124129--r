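# Snapshot and event-log writers.  All writers are deterministic: stable
# column order, numbers at full double precision.

.fmtNum <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

.writeTable <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmtNum), stringsAsFactors = FALSE)
  names(out) <- names(df)
  ok <- try(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("I/O failure writing %s: %s", path, attr(ok, "condition")$message))
  invisible(path)
}

#' Write a per-voxel snapshot
#'
#' One CSV row per voxel: time, voxel id, centre coordinates, occupancy,
#' visited flag, and one column per supplied scalar field.  With
#' `cells = TRUE` a companion file (suffix `_cells`) stores the per-cell
#' registry including internal states.
#'
#' @param state a [CellState-class]
#' @param grid a [VoxelGrid-class]
#' @param path output CSV path.
#' @param fields named list of [ScalarField-class]s to append.
#' @param cells also write the per-cell table.
#' @return invisibly, the path written.
#' @export
writeSnapshot <- function(state, grid, path, fields = list(), cells = FALSE) {
  co <- voxelCenters(grid)
  df <- data.frame(time = rep(state@time, nVoxels(grid)),
                   voxel = seq_len(nVoxels(grid)))
  for (k in seq_len(ncol(co))) df[[c("x", "y", "z")[k]]] <- co[, k]
  df$u <- state@u
  df$visited <- as.integer(state@visited)
  for (nm in names(fields)) df[[nm]] <- as.numeric(fields[[nm]])
  .writeTable(df, path)
  if (cells) {
    cpath <- sub("\\.csv$", "_cells.csv", path)
    if (identical(cpath, path)) cpath <- paste0(path, "_cells")
    ct <- cellTable(state)
    ct <- cbind(time = rep(state@time, nrow(ct)), ct)
    .writeTable(ct, cpath)
  }
  invisible(path)
}

#' Read a snapshot written by [writeSnapshot()]
#'
#' @param path CSV path.
#' @return list with `time`, `u` (integer occupancy), `visited` (logical)
#'   and the full data.frame as `table`.
#' @export
readSnapshot <- function(path) {
  df <- utils::read.csv(path)
  u <- as.integer(df$u)
  if (any(u < -1L | u > 2L)) stop("invalid snapshot: occupancy out of range")
  list(time = df$time[1], u = u, visited = df$visited != 0, table = df)
}

#' Write / read an event log
#'
#' Tabular record of every applied event: time, type, source voxel,
#' destination voxel, cell id.  Two runs with equal seeds and
#' configurations produce byte-identical logs.
#'
#' @param events event data.frame (from [eventLog()]).
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeEventLog <- function(events, path) {
  .writeTable(events, path)
}

#' @rdname writeEventLog
#' @export
readEventLog <- function(path) {
  utils::read.csv(path)
}
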