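# Seeded synthetic data: spatial tissues with community structure,
# multi-slice stacks with planted rigid transforms, toy ligand-receptor
# databases, and a synthetic stand-in for the curated SCTDB reference
# tables. Every generator is a pure function of its parameters and seed.

#' Simulate a spatial tissue fixture
#'
#' Cells are drawn from spatially separated community blobs (Gaussian
#' clusters whose centres are placed irregularly by golden-angle spacing
#' with varying radius, so the tissue has no rotational symmetry —
#' symmetric layouts would make slice matching ill-posed); expression is
#' a community-specific
#' mean profile (low-rank signal, per-gene means drawn
#' `N(0, signalStrength^2)`) plus i.i.d. `N(0, noiseSd^2)` noise, so graph
#' structure is statistically recoverable from the features. The
#' ground-truth adjacency is the symmetrized kNN graph of the
#' coordinates.
#'
#' @param nCells,nGenes,nCommunities fixture dimensions. Defaults give the
#'   desk-scale benchmark fixture (200 cells, 50 genes, 4 communities).
#' @param nNeighbors kNN neighbourhood size of the ground-truth graph.
#' @param signalStrength sd of community mean profiles; 0 makes
#'   expression independent of the communities.
#' @param noiseSd per-entry expression noise sd.
#' @param blobSd spatial spread of each community blob.
#' @param centerRadius radius of the circle the community centres sit on.
#' @param seed RNG seed.
#' @return a [TissueFixture-class].
#' @export
simulateTissue <- function(nCells = 200, nGenes = 50, nCommunities = 4,
                           nNeighbors = 6, signalStrength = 1,
                           noiseSd = 0.3, blobSd = 1, centerRadius = 7,
                           seed = 0) {
  if (nCells < nCommunities || nCommunities < 1)
    stop("validation error: need nCells >= nCommunities >= 1")
  withSeed(seed, {
    communities <- sort(rep_len(seq_len(nCommunities), nCells))
    k <- seq_len(nCommunities) - 1
    ang <- k * 2.399963                      # golden angle, irregular
    rad <- centerRadius * (0.7 + 0.3 * k / max(1, nCommunities - 1))
    centers <- cbind(rad * cos(ang), rad * sin(ang))
    coords <- centers[communities, , drop = FALSE] +
      matrix(rnorm(2 * nCells, sd = blobSd), nCells, 2)
    ids <- sprintf("cell%03d", seq_len(nCells))
    dimnames(coords) <- list(ids, c("x", "y"))
    meanProfiles <- matrix(rnorm(nCommunities * nGenes,
                                 sd = signalStrength),
                           nCommunities, nGenes)
    expr <- meanProfiles[communities, , drop = FALSE] +
      matrix(rnorm(nCells * nGenes, sd = noiseSd), nCells, nGenes)
    dimnames(expr) <- list(ids, sprintf("gene%03d", seq_len(nGenes)))
    A <- knnAdjacency(euclideanDistances(coords), nNeighbors)
    methods::new("TissueFixture", coords = coords, expression = expr,
                 adjacency = A, communities = as.integer(communities),
                 config = list(nCells = nCells, nGenes = nGenes,
                               nCommunities = nCommunities,
                               nNeighbors = nNeighbors,
                               signalStrength = signalStrength,
                               noiseSd = noiseSd, blobSd = blobSd,
                               centerRadius = centerRadius, seed = seed))
  })
}

.rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Simulate a multi-slice stack with planted rigid transforms
#'
#' Each slice is the base tissue's coordinates under a cumulative planted
#' rotation/translation, plus coordinate jitter, with a seeded random
#' subset of cells dropped. Ground-truth transforms (mapping base
#' coordinates into each slice's frame) and the surviving counterpart map
#' are returned.
#'
#' @param base a [TissueFixture-class].
#' @param nSlices number of slices (>= 2).
#' @param rotationDeg per-step planted rotation (slice s is rotated by
#'   `(s-1) * rotationDeg`).
#' @param translation per-step planted translation (length 2).
#' @param jitterSd coordinate jitter sd.
#' @param dropoutFrac fraction of cells dropped per slice, in [0, 1).
#' @param seed RNG seed.
#' @return list with `slices` (coordinate matrices, rownames are cell
#'   ids), `transforms` (planted [RigidTransform-class] base -> slice),
#'   and `expression` per slice.
#' @export
simulateMultislice <- function(base, nSlices = 3, rotationDeg = 15,
                               translation = c(2, 1), jitterSd = 0.01,
                               dropoutFrac = 0.05, seed = 0) {
  stopifnot(methods::is(base, "TissueFixture"))
  if (nSlices < 2) stop("validation error: nSlices must be >= 2")
  if (dropoutFrac < 0 || dropoutFrac >= 1)
    stop("validation error: dropoutFrac must be in [0, 1)")
  X <- tissueCoords(base)
  E <- tissueExpression(base)
  n <- nrow(X)
  withSeed(seed, {
    slices <- vector("list", nSlices)
    transforms <- vector("list", nSlices)
    for (s in seq_len(nSlices)) {
      tr <- methods::new("RigidTransform",
                         rotation = .rot2((s - 1) * rotationDeg),
                         translation = (s - 1) * translation, scale = 1)
      transforms[[s]] <- tr
      Y <- applyTransform(tr, X)
      if (jitterSd > 0)
        Y <- Y + matrix(rnorm(2 * n, sd = jitterSd), n, 2)
      keep <- seq_len(n)
      if (dropoutFrac > 0) {
        drop_n <- floor(dropoutFrac * n)
        if (drop_n > 0) keep <- sort(sample.int(n, n - drop_n))
      }
      Ys <- Y[keep, , drop = FALSE]
      rownames(Ys) <- rownames(X)[keep]
      colnames(Ys) <- c("x", "y")
      slices[[s]] <- Ys
    }
    list(slices = slices, transforms = transforms,
         expression = lapply(slices, function(sl)
           E[rownames(sl), , drop = FALSE]),
         config = list(nSlices = nSlices, rotationDeg = rotationDeg,
                       translation = translation, jitterSd = jitterSd,
                       dropoutFrac = dropoutFrac, seed = seed))
  })
}

#' Simulate a toy ligand-receptor database
#'
#' Seeded random L-R pairs over a gene universe; a fraction of pairs get
#' a two-subunit complex on the ligand side.
#'
#' @param geneIds gene symbol universe.
#' @param nPairs number of unique pairs.
#' @param complexFrac fraction of pairs with a multi-subunit side.
#' @param species species label.
#' @param seed RNG seed.
#' @param delimiter complex subunit delimiter.
#' @return an [LRDatabase-class].
#' @export
simulateLRDatabase <- function(geneIds, nPairs, complexFrac = 0,
                               species = "human", seed = 0,
                               delimiter = "_") {
  g <- length(geneIds)
  if (g < 3) stop("need at least 3 genes")
  maxPairs <- g * (g - 1)
  if (nPairs > maxPairs)
    stop("validation error: nPairs exceeds the number of possible pairs")
  withSeed(seed, {
    pick <- sample.int(maxPairs, nPairs)
    li <- (pick - 1) %% g + 1
    rj <- (pick - 1) %/% g + 1
    rj <- ifelse(rj >= li, rj + 1, rj)     # bijection onto ordered pairs
    ligand <- geneIds[li]
    receptor <- geneIds[rj]
    nCx <- round(complexFrac * nPairs)
    if (nCx > 0) {
      cx <- seq_len(nCx)
      partner <- vapply(cx, function(i) {
        cand <- setdiff(seq_len(g), c(li[i], rj[i]))
        geneIds[cand[sample.int(length(cand), 1)]]
      }, character(1))
      ligand[cx] <- paste(ligand[cx], partner, sep = delimiter)
    }
    df <- .dedupPairs(.makePairsDF(ligand, receptor,
                                   rep(species, length(ligand)),
                                   rep("synthetic", length(ligand)),
                                   delimiter))
    # complex construction can (rarely) collide under the canonical key;
    # top up with fresh simple pairs until the requested count is exact
    guard <- 0L
    while (nrow(df) < nPairs && guard < 100L) {
      guard <- guard + 1L
      need <- nPairs - nrow(df)
      i2 <- sample.int(g, need, replace = TRUE)
      j2 <- sample.int(g - 1, need, replace = TRUE)
      j2 <- ifelse(j2 >= i2, j2 + 1, j2)
      extra <- .makePairsDF(geneIds[i2], geneIds[j2],
                            rep(species, need), rep("synthetic", need),
                            delimiter)
      df <- .dedupPairs(rbind(df, extra))
    }
    if (nrow(df) != nPairs)
      stop("could not generate the requested number of unique pairs")
    methods::new("LRDatabase", pairs = df, delimiter = delimiter)
  })
}

#' Write synthetic SCTDB-style reference tables
#'
#' The curated SCTDB reference (merged, literature-supported human and
#' mouse L-R tables) is not shipped with this package; this generator
#' writes a *synthetic* stand-in with the
#' same published unique-pair counts (5786 human, 4806 mouse by default)
#' over a synthetic gene-symbol universe. Redundancy is injected on
#' purpose — duplicated rows, case variants and reordered complex
#' subunits — so that the load + merge + dedup pipeline is genuinely
#' exercised when the counts are recomputed.
#'
#' @param dir output directory (created if missing).
#' @param nHuman,nMouse unique pair counts after deduplication.
#' @param complexFrac fraction of pairs with a 2-subunit ligand complex.
#' @param redundantFrac fraction of extra redundant rows appended.
#' @param seed RNG seed.
#' @return named character vector with the `human` and `mouse` table
#'   paths (files are named `synthetic_sctdb_<species>.tsv`).
#' @export
simulateSCTDB <- function(dir = tempdir(), nHuman = 5786, nMouse = 4806,
                          complexFrac = 0.1, redundantFrac = 0.05,
                          seed = 0) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(human = file.path(dir, "synthetic_sctdb_human.tsv"),
             mouse = file.path(dir, "synthetic_sctdb_mouse.tsv"))
  counts <- c(human = nHuman, mouse = nMouse)
  prefix <- c(human = "HSG", mouse = "MMG")
  withSeed(seed, {
    for (sp in c("human", "mouse")) {
      genes <- sprintf("%s%04d", prefix[[sp]], seq_len(2000))
      db <- simulateLRDatabase(genes, counts[[sp]],
                               complexFrac = complexFrac, species = sp,
                               seed = sample.int(2^30, 1))
      p <- lrPairs(db)
      lig <- p$ligand
      rec <- p$receptor
      nRed <- round(redundantFrac * nrow(p))
      if (nRed > 0) {
        ridx <- sample.int(nrow(p), nRed, replace = TRUE)
        ligR <- lig[ridx]
        recR <- rec[ridx]
        # case variants and reordered complex subunits collapse under the
        # canonical key
        flip <- grepl("_", ligR)
        ligR[flip] <- vapply(strsplit(ligR[flip], "_", fixed = TRUE),
                             function(s) paste(rev(s), collapse = "_"),
                             character(1))
        lower <- !flip & (seq_len(nRed) %% 2 == 0)
        ligR[lower] <- tolower(ligR[lower])
        lig <- c(lig, ligR)
        rec <- c(rec, recR)
      }
      ord <- sample.int(length(lig))
      tab <- data.frame(ligand = lig[ord], receptor = rec[ord],
                        species = sp, source = "synthetic-sctdb",
                        stringsAsFactors = FALSE)
      write.table(tab, paths[[sp]], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  })
  paths
}
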