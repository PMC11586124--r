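# Ligand-receptor pair databases: ingestion, merging/deduplication, and
# gene-level adjacency construction.

.normSymbol <- function(x) toupper(trimws(x))

# Canonical key: species | sorted-normalized ligand subunits | sorted-
# normalized receptor subunits. Direction (ligand side vs receptor side) is
# preserved; subunit order within a side is not.
.pairKey <- function(species, ligandSubunits, receptorSubunits) {
  paste(species,
        paste(sort(.normSymbol(ligandSubunits)), collapse = "&"),
        paste(sort(.normSymbol(receptorSubunits)), collapse = "&"),
        sep = "|")
}

.makePairsDF <- function(ligand, receptor, species, source, delimiter) {
  ligandSubunits <- strsplit(ligand, delimiter, fixed = TRUE)
  receptorSubunits <- strsplit(receptor, delimiter, fixed = TRUE)
  ligandSubunits <- lapply(ligandSubunits, trimws)
  receptorSubunits <- lapply(receptorSubunits, trimws)
  key <- mapply(.pairKey, species, ligandSubunits, receptorSubunits,
                USE.NAMES = FALSE)
  df <- data.frame(ligand = trimws(ligand), receptor = trimws(receptor),
                   species = species, source = source, key = key,
                   stringsAsFactors = FALSE)
  df$ligandSubunits <- ligandSubunits
  df$receptorSubunits <- receptorSubunits
  df
}

.dedupPairs <- function(df) df[!duplicated(df$key), , drop = FALSE]

#' Load a ligand-receptor pair table
#'
#' Reads a TSV/CSV table with at least `ligand` and `receptor` columns
#' (optionally `species` and `source`). Multi-subunit complexes are split
#' on `delimiter`. Rows duplicated under the canonical key (species,
#' normalized symbols, subunits sorted within each side, direction
#' preserved) are collapsed, first occurrence winning.
#'
#' @param path path to the table.
#' @param species species to assign when the file has no `species` column;
#'   one of `"human"` or `"mouse"`.
#' @param delimiter complex-subunit delimiter (default `"_"`).
#' @param sep field separator; inferred from the file extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return an [LRDatabase-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("ligand\treceptor", "TGFB1\tTGFBR1", "ITGA5_ITGB1\tFN1"), tf)
#' db <- readLRTable(tf, species = "human")
#' speciesCounts(db)
#' @export
readLRTable <- function(path, species = NULL, delimiter = "_", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(tab) <- tolower(names(tab))
  for (col in c("ligand", "receptor"))
    if (!col %in% names(tab))
      stop("format error: missing required column '", col, "'")
  if ("species" %in% names(tab)) {
    sp <- tolower(trimws(tab$species))
  } else {
    if (is.null(species))
      stop("no 'species' column; supply the 'species' argument")
    sp <- rep(tolower(species), nrow(tab))
  }
  bad <- setdiff(unique(sp), c("human", "mouse"))
  if (length(bad) && nrow(tab) > 0)
    stop("validation error: unknown species value(s): ",
         paste(bad, collapse = ", "))
  src <- if ("source" %in% names(tab)) as.character(tab$source)
         else rep(basename(path), nrow(tab))
  df <- .makePairsDF(as.character(tab$ligand), as.character(tab$receptor),
                     sp, src, delimiter)
  if (nrow(df) && (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor))))
    stop("validation error: empty ligand or receptor symbol")
  methods::new("LRDatabase", pairs = .dedupPairs(df), delimiter = delimiter)
}

#' Merge ligand-receptor databases and remove redundant pairs
#'
#' Unions the pair collections and collapses exact duplicates under the
#' canonical key, keeping the first occurrence so ordering is stable.
#' Merging a database with itself is the identity.
#'
#' @param ... [LRDatabase-class] objects, or a single list of them.
#' @return an [LRDatabase-class] with unique pairs.
#' @export
mergeLRDatabases <- function(...) {
  dbs <- list(...)
  if (length(dbs) == 1L && is.list(dbs[[1]]) && !methods::is(dbs[[1]], "LRDatabase"))
    dbs <- dbs[[1]]
  if (length(dbs) == 0L) stop("at least one database is required")
  for (db in dbs)
    if (!methods::is(db, "LRDatabase")) stop("inputs must be LRDatabase")
  allPairs <- do.call(rbind, lapply(dbs, function(d) d@pairs))
  if (is.null(allPairs))
    allPairs <- .makePairsDF(character(), character(), character(),
                             character(), dbs[[1]]@delimiter)
  methods::new("LRDatabase", pairs = .dedupPairs(allPairs),
               delimiter = dbs[[1]]@delimiter)
}

#' Build a gene-level adjacency matrix from an L-R database
#'
#' Over an ordered gene list, entry (i, j) is 1 iff some ligand-receptor
#' pair relates gene i and gene j in either direction. Complexes
#' contribute an edge between every ligand-side subunit and every
#' receptor-side subunit present in the gene list. The result is
#' symmetric with a zero diagonal.
#'
#' @param geneIds ordered unique gene symbols.
#' @param db an [LRDatabase-class].
#' @return binary symmetric matrix with `geneIds` dimnames.
#' @export
geneAdjacency <- function(geneIds, db) {
  if (length(geneIds) == 0L) stop("validation error: empty gene list")
  if (anyDuplicated(geneIds)) stop("gene ids must be unique")
  if (!methods::is(db, "LRDatabase")) stop("'db' must be an LRDatabase")
  n <- length(geneIds)
  A <- matrix(0, n, n, dimnames = list(geneIds, geneIds))
  lookup <- stats::setNames(seq_len(n), .normSymbol(geneIds))
  p <- db@pairs
  for (r in seq_len(nrow(p))) {
    li <- lookup[.normSymbol(p$ligandSubunits[[r]])]
    ri <- lookup[.normSymbol(p$receptorSubunits[[r]])]
    li <- li[!is.na(li)]
    ri <- ri[!is.na(ri)]
    for (i in li) for (j in ri) {
      if (i != j) {
        A[i, j] <- 1
        A[j, i] <- 1
      }
    }
  }
  A
}
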