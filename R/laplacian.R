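#' Assemble the discrete Laplacian of a voxel grid
#'
#' Builds the sparse symmetric operator with off-diagonal weights
#' `w_ij = e_ij / d_ij` for neighbouring voxels and diagonal `-sum_j w_ij`
#' (two-point flux form; equivalently P1 finite elements with a lumped mass
#' matrix, which reduces to the classical finite-difference stencils on
#' structured grids).  Row sums vanish exactly, so constants lie in the
#' kernel before any boundary restriction.  Assembly is pure: the grid is
#' not modified.
#'
#' @param grid a [VoxelGrid-class]
#' @return a [LaplacianOperator-class]
#' @examples
#' g <- buildStructuredGrid("cartesian2d", c(3, 3))
#' L <- laplacianMatrix(assembleLaplacian(g))
#' L[5, ]  # 5-point stencil row: -4 on the diagonal, +1 for each neighbour
#' @export
assembleLaplacian <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  n <- nVoxels(grid)
  if (any(grid@edgeMeasure <= 0))
    stop("assembly error: grid contains a zero-measure edge")
  w <- grid@edgeMeasure / grid@centerDist
  deg <- numeric(n)
  if (length(w)) {
    ta <- tapply(c(w, w), c(grid@edgeFrom, grid@edgeTo), sum)
    deg[as.integer(names(ta))] <- as.numeric(ta)
  }
  op <- Matrix::sparseMatrix(
    i = c(grid@edgeFrom, grid@edgeTo, seq_len(n)),
    j = c(grid@edgeTo, grid@edgeFrom, seq_len(n)),
    x = c(w, w, -deg),
    dims = c(n, n))
  new("LaplacianOperator", op = op, gridKind = grid@kind)
}
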