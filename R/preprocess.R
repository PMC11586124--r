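# Expression-matrix ingestion, filtering, standardization and controlled
# Gaussian noise injection for the robustness experiments.

#' Read an expression matrix
#'
#' Dense CSV/TSV files carry gene names in the header and cell ids in the
#' first column. MatrixMarket input reads `<stem>.mtx` plus the
#' `<stem>_cells.txt` and `<stem>_genes.txt` label sidecars.
#'
#' @param path input file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`; inferred from the extension
#'   when `NULL`.
#' @param transpose set `TRUE` when the stored matrix is genes x cells.
#' @return numeric matrix, cells in rows, genes in columns.
#' @export
readExpression <- function(path, format = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension: ", path))
  }
  format <- match.arg(format, c("csv", "tsv", "mtx"))
  if (format == "mtx") {
    M <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    cellsFile <- paste0(stem, "_cells.txt")
    genesFile <- paste0(stem, "_genes.txt")
    if (!file.exists(cellsFile) || !file.exists(genesFile))
      stop("mtx input requires sidecars ", basename(cellsFile), " and ",
           basename(genesFile))
    cells <- readLines(cellsFile)
    genes <- readLines(genesFile)
    if (transpose) M <- t(M)
    if (length(cells) != nrow(M))
      stop("format error: ", length(cells), " cell labels for ",
           nrow(M), " rows")
    if (length(genes) != ncol(M))
      stop("format error: ", length(genes), " gene labels for ",
           ncol(M), " columns")
    dimnames(M) <- list(cells, genes)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- read.delim(path, sep = sep, row.names = 1, check.names = FALSE,
                      stringsAsFactors = FALSE)
    M <- as.matrix(tab)
    if (!is.numeric(M)) {
      bad <- which(!vapply(tab, is.numeric, TRUE))[1]
      stop("parse error: non-numeric entries in column '",
           colnames(tab)[bad], "'")
    }
    if (transpose) M <- t(M)
  }
  assertExpression(M)
  M
}

#' Write an expression matrix
#'
#' Inverse of [readExpression()] for the dense formats, plus MatrixMarket
#' with label sidecars.
#'
#' @param X cells x genes matrix with dimnames.
#' @param path output file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return the path, invisibly.
#' @export
writeExpression <- function(X, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  assertExpression(X)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                "generalMatrix"), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(X), paste0(stem, "_cells.txt"))
    writeLines(colnames(X), paste0(stem, "_genes.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = rownames(X), X, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Drop all-zero cells and genes
#'
#' Removes rows (cells) and columns (genes) whose entries are all zero,
#' preserving the order of the survivors. Idempotent.
#'
#' @param X cells x genes matrix.
#' @return the filtered matrix.
#' @export
filterAllZero <- function(X) {
  assertExpression(X)
  keepCells <- rowSums(X != 0) > 0
  keepGenes <- colSums(X != 0) > 0
  if (!any(keepCells) || !any(keepGenes))
    stop("degenerate input: filtering removed every cell or gene")
  X[keepCells, keepGenes, drop = FALSE]
}

#' Standardize expression per gene
#'
#' Z-scores every gene column to mean 0 and unit population standard
#' deviation (divisor n, not n-1). Zero-variance genes map to all-zero
#' columns rather than raising, so noise-free synthetic data survive.
#'
#' @param X cells x genes matrix.
#' @return standardized matrix of the same shape.
#' @export
standardizeExpression <- function(X) {
  assertExpression(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sdPop <- sqrt(colMeans(Xc^2))
  zero <- sdPop == 0
  sdPop[zero] <- 1
  Z <- sweep(Xc, 2, sdPop, "/")
  Z[, zero] <- 0
  Z
}

#' Add i.i.d. Gaussian noise to an expression matrix
#'
#' @param X cells x genes matrix.
#' @param stdDev noise standard deviation (>= 0); 0 returns the input
#'   unchanged without consuming random numbers.
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return matrix of the same shape and labels.
#' @export
addGaussianNoise <- function(X, stdDev, seed = NULL) {
  assertExpression(X)
  if (!is.numeric(stdDev) || length(stdDev) != 1L || stdDev < 0)
    stop("validation error: 'stdDev' must be a single non-negative number")
  if (stdDev == 0) return(X)
  withSeed(seed, X + matrix(rnorm(length(X), sd = stdDev),
                            nrow(X), ncol(X), dimnames = dimnames(X)))
}
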