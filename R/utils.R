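#' @importFrom stats rnorm runif plogis dist sd
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. `seed = NULL` runs code unseeded.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Independent RNG streams: capture a seeded RNG state in an environment and
# resume it for isolated blocks (used to keep the adversarial module's draws
# from perturbing the model stream).
makeRngStream <- function(seed) {
  env <- new.env(parent = emptyenv())
  withSeed(seed, {
    env$state <- get(".Random.seed", envir = globalenv())
  })
  env
}

withStream <- function(stream, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

assertSquareSymmetric <- function(A, what = "adjacency matrix",
                                  tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(what, " must be a square matrix")
  if (!all(is.finite(A))) stop(what, " contains non-finite entries")
  if (max(abs(A - t(A))) > tol) stop(what, " must be symmetric")
  invisible(A)
}

assertBinaryAdjacency <- function(A) {
  assertSquareSymmetric(A)
  if (any(A != 0 & A != 1)) stop("adjacency entries must be 0 or 1")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  invisible(A)
}

assertExpression <- function(X) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("expression must be a numeric matrix (cells x genes)")
  if (!all(is.finite(X))) stop("expression contains non-finite values")
  if (!is.null(rownames(X)) && anyDuplicated(rownames(X)))
    stop("duplicated cell identifiers")
  if (!is.null(colnames(X)) && anyDuplicated(colnames(X)))
    stop("duplicated gene identifiers")
  invisible(X)
}

# Upper-triangle (i < j) index pairs of the nonzero entries of A.
edgeIndices <- function(A) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

nonEdgeIndices <- function(A) {
  idx <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

#' Write a symmetric adjacency matrix as an edge list
#'
#' Each unordered edge (i < j) becomes one row `node_i  node_j  weight`.
#'
#' @param A square symmetric matrix (binary adjacency or edge weights).
#' @param path output file.
#' @param nodeIds node labels; defaults to `rownames(A)` or `1..n`.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(A, path, nodeIds = NULL) {
  assertSquareSymmetric(A)
  if (is.null(nodeIds)) nodeIds <- rownames(A)
  if (is.null(nodeIds)) nodeIds <- as.character(seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  df <- data.frame(node_i = nodeIds[idx[, 1]], node_j = nodeIds[idx[, 2]],
                   weight = A[idx], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sparse adjacency matrix in MatrixMarket format
#'
#' @param A square matrix.
#' @param path output `.mtx` file; node labels go to a `<stem>_nodes.txt`
#'   sidecar when present.
#' @return the path, invisibly.
#' @export
writeAdjacencyMM <- function(A, path) {
  assertSquareSymmetric(A)
  Matrix::writeMM(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                  path)
  if (!is.null(rownames(A))) {
    sidecar <- sub("\\.mtx$", "_nodes.txt", path)
    writeLines(rownames(A), sidecar)
  }
  invisible(path)
}
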