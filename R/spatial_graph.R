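# Cell-level spatial graphs: Euclidean distance matrices, symmetrized
# k-nearest-neighbour adjacency, GCN normalization, and cross-layer graphs
# on stacked 3D coordinates.

#' Euclidean distance matrix of cell coordinates
#'
#' @param coords cells x d coordinate matrix (d = 2 or 3), rownames are
#'   cell ids.
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
euclideanDistances <- function(coords) {
  if (!is.matrix(coords)) coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("at least one cell is required")
  if (!all(is.finite(coords)))
    stop("validation error: non-finite coordinates")
  D <- as.matrix(dist(coords, method = "euclidean"))
  dimnames(D) <- if (is.null(rownames(coords))) NULL
                 else list(rownames(coords), rownames(coords))
  D
}

#' Symmetrized k-nearest-neighbour adjacency
#'
#' For every cell the `nNeighbors` nearest other cells (smallest
#' off-diagonal entries of its distance-matrix row) become neighbours;
#' the directed result is then symmetrized by logical OR with its
#' transpose. Equidistant neighbours are broken stably by node index.
#'
#' @param D symmetric distance matrix.
#' @param nNeighbors neighbourhood size; must be smaller than the number
#'   of cells. The default 6 reflects the assumption that in solid tissue
#'   a cell touches several immediate neighbours.
#' @return binary symmetric adjacency with zero diagonal.
#' @export
knnAdjacency <- function(D, nNeighbors = 6) {
  assertSquareSymmetric(D, "distance matrix")
  n <- nrow(D)
  if (nNeighbors < 1 || nNeighbors >= n)
    stop("validation error: 'nNeighbors' must be in [1, n_cells - 1]")
  A <- matrix(0, n, n, dimnames = dimnames(D))
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf   # self never a neighbour
    nb <- order(d)[seq_len(nNeighbors)]   # order() is stable on ties
    A[i, nb] <- 1
  }
  A <- 1 * (A | t(A))
  diag(A) <- 0
  A
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes the GCN propagation operator
#' `D_tilde^{-1/2} (A + I) D_tilde^{-1/2}`, where `D_tilde` is the degree
#' matrix of `A + I`. Isolated nodes are safe: the self-loop gives them
#' degree 1.
#'
#' @param A binary symmetric adjacency with zero diagonal.
#' @return dense symmetric matrix.
#' @export
normalizeAdjacency <- function(A) {
  assertBinaryAdjacency(A)
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Cross-layer kNN graph on stacked 3D coordinates
#'
#' Builds the symmetrized kNN adjacency in 3D Euclidean space and
#' annotates every edge as intra-layer or inter-layer.
#'
#' @param coords3d cells x 3 coordinate matrix.
#' @param layer per-cell slice label (length = number of cells).
#' @param nNeighbors neighbourhood size.
#' @return list with `adjacency` (binary matrix) and `edges` (data.frame
#'   `node_i`, `node_j`, `layer_i`, `layer_j`, `type`).
#' @export
crossLayerGraph <- function(coords3d, layer, nNeighbors = 6) {
  if (!is.matrix(coords3d)) coords3d <- as.matrix(coords3d)
  if (ncol(coords3d) != 3L) stop("'coords3d' must have 3 columns")
  if (length(layer) != nrow(coords3d))
    stop("'layer' length must match the number of cells")
  A <- knnAdjacency(euclideanDistances(coords3d), nNeighbors)
  idx <- edgeIndices(A)
  ids <- rownames(coords3d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords3d)))
  edges <- data.frame(
    node_i = ids[idx[, "i"]], node_j = ids[idx[, "j"]],
    layer_i = layer[idx[, "i"]], layer_j = layer[idx[, "j"]],
    stringsAsFactors = FALSE)
  edges$type <- ifelse(edges$layer_i == edges$layer_j,
                       "intra-layer", "inter-layer")
  list(adjacency = A, edges = edges)
}

#' Inter-layer edges of a cross-layer graph
#'
#' @param graph result of [crossLayerGraph()].
#' @return the subset of edges crossing layers.
#' @export
interLayerEdges <- function(graph) {
  graph$edges[graph$edges$type == "inter-layer", , drop = FALSE]
}
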