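# Link-prediction evaluation: AUROC / average precision / accuracy,
# seeded negative-edge sampling, and the two benchmark experiments
# (edge-removal recovery and Gaussian-noise robustness) reported in the
# per-seed-plus-average layout.

.checkScores <- function(labels, scores, needBoth = TRUE) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (length(labels) == 0L) stop("empty input")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (needBoth && (sum(labels == 1) == 0L || sum(labels == 0) == 0L))
    stop("undefined metric: both classes must be present")
  invisible(NULL)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve swept over all distinct score
#' thresholds; equivalently the rank statistic where tied
#' positive/negative pairs count one half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
rocAUC <- function(labels, scores) {
  .checkScores(labels, scores)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Average precision
#'
#' Step-wise `AP = sum_n (R_n - R_{n-1}) P_n` over the score-sorted
#' threshold sweep (one threshold per distinct score value).
#'
#' @inheritParams rocAUC
#' @return AP in `(0, 1]`.
#' @export
averagePrecision <- function(labels, scores) {
  .checkScores(labels, scores)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  npred <- seq_along(y)
  # thresholds end where the next score differs (or at the end)
  cut <- which(diff(s) != 0)
  cut <- c(cut, length(s))
  P <- tp[cut] / npred[cut]
  R <- tp[cut] / sum(y)
  sum(diff(c(0, R)) * P)
}

#' Classification accuracy at a threshold
#'
#' `(TP + TN) / (TP + TN + FP + FN)` with predictions
#' `score >= threshold`.
#'
#' @inheritParams rocAUC
#' @param threshold hard-call cutoff (default 0.5).
#' @return accuracy in `[0, 1]`.
#' @export
accuracyScore <- function(labels, scores, threshold = 0.5) {
  .checkScores(labels, scores, needBoth = FALSE)
  mean((scores >= threshold) == (labels == 1))
}

#' Seeded negative-edge sampling
#'
#' Draws `k` distinct unordered node pairs that are non-edges of `A`
#' (excluding the diagonal), reproducibly for a given seed and disjoint
#' from the positive edges by construction.
#'
#' @param A binary symmetric adjacency.
#' @param k number of negative pairs.
#' @param seed RNG seed.
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
sampleNegativeEdges <- function(A, k, seed = NULL) {
  assertBinaryAdjacency(A)
  non <- nonEdgeIndices(A)
  if (k > nrow(non))
    stop("validation error: requested ", k, " negatives but only ",
         nrow(non), " non-edges exist")
  pick <- withSeed(seed, sample.int(nrow(non), k))
  non[pick, , drop = FALSE]
}

#' Assemble a per-seed report with condition averages
#'
#' Appends an arithmetic-mean average per condition in the classic
#' "Seed 1 ... Seed k | Average" layout. Full precision is retained in
#' the object; display rounds to 3 decimals.
#'
#' @param rows data.frame with columns `condition`, `seed`, `acc`,
#'   `auroc`, `ap`.
#' @param metadata optional configuration snapshot.
#' @return an [EvalReport-class].
#' @export
seedReport <- function(rows, metadata = list()) {
  if (nrow(rows) < 1L) stop("at least one row is required")
  conds <- unique(rows$condition)
  avg <- do.call(rbind, lapply(conds, function(cc) {
    sub <- rows[rows$condition == cc, , drop = FALSE]
    data.frame(condition = cc, acc = mean(sub$acc),
               auroc = mean(sub$auroc), ap = mean(sub$ap),
               stringsAsFactors = FALSE)
  }))
  methods::new("EvalReport", rows = rows, averages = avg,
               metadata = metadata)
}

# Shared engine for the two benchmarks: remove a fraction of edges
# (seeded), optionally add expression noise, train, and score the held-out
# positives against an equal-size negative sample from the original
# graph's non-edges.
.maskedRecoveryRun <- function(X, A, fraction, seed, noiseSd = 0,
                               trainConfig = list(), keepCurves = FALSE) {
  edges <- edgeIndices(A)
  nRemove <- round(fraction * nrow(edges))
  if (nRemove < 1L)
    stop("fraction ", fraction, " removes no edges")
  removed <- withSeed(seed,
                      edges[sample.int(nrow(edges), nRemove), ,
                            drop = FALSE])
  Atrain <- A
  Atrain[removed] <- 0
  Atrain[removed[, c(2, 1), drop = FALSE]] <- 0
  if (sum(Atrain) == 0)
    stop("edge removal left an empty graph")
  Xrun <- addGaussianNoise(X, noiseSd, seed = seed + 77003)
  negatives <- sampleNegativeEdges(A, nRemove, seed = seed + 33331)
  evalEdges <- list(pos = removed, neg = negatives)
  cfg <- c(list(X = Xrun, A = Atrain, seed = seed,
                evalEdges = if (keepCurves) evalEdges else NULL),
           trainConfig)
  fit <- do.call(trainVGAE, cfg)
  P <- edgeProbabilities(fit)
  scores <- c(P[removed], P[negatives])
  labels <- rep(c(1, 0), c(nrow(removed), nrow(negatives)))
  list(acc = accuracyScore(labels, scores),
       auroc = rocAUC(labels, scores),
       ap = averagePrecision(labels, scores),
       fit = fit)
}

#' Edge-removal recovery experiment
#'
#' For every (fraction, seed): removes that fraction of edges uniformly
#' at random, trains on the remainder, and scores the removed (held-out
#' positive) edges against an equal-size seeded negative sample with
#' AUROC, AP and ACC.
#'
#' @param X node features (cells x genes).
#' @param A binary symmetric adjacency (the full ground-truth graph).
#' @param fractions edge-removal fractions in (0, 1).
#' @param seeds integer seeds replicating each condition.
#' @param trainConfig named list of extra arguments for [trainVGAE()].
#' @return an [EvalReport-class] with one row per (fraction, seed).
#' @export
edgeRemovalExperiment <- function(X, A,
                                  fractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                  seeds = 0:4, trainConfig = list()) {
  stopifnot(all(fractions > 0 & fractions < 1))
  rows <- list()
  for (f in fractions) for (s in seeds) {
    res <- .maskedRecoveryRun(X, A, f, s, trainConfig = trainConfig)
    rows[[length(rows) + 1L]] <-
      data.frame(condition = sprintf("fraction=%g", f), seed = s,
                 acc = res$acc, auroc = res$auroc, ap = res$ap,
                 stringsAsFactors = FALSE)
  }
  seedReport(do.call(rbind, rows),
             metadata = list(experiment = "edge_removal",
                             fractions = fractions, seeds = seeds,
                             trainConfig = trainConfig))
}

#' Gaussian-noise robustness experiment
#'
#' For every (noise sd, seed): injects i.i.d. Gaussian noise into the
#' (standardized) expression, removes `maskFraction` of the edges, trains,
#' and scores the masked edges. At `stdDev = 0` a row coincides with the
#' edge-removal experiment at the same fraction and seed. Per-epoch
#' AUROC/AP curves are retained for plotting.
#'
#' @inheritParams edgeRemovalExperiment
#' @param stdDevs noise standard deviations (default 0..7).
#' @param maskFraction fraction of edges held out for scoring.
#' @return list with `report` (an [EvalReport-class]) and `curves`
#'   (named list of per-epoch metric data.frames).
#' @export
noiseExperiment <- function(X, A, stdDevs = 0:7, seeds = 0:4,
                            maskFraction = 0.1, trainConfig = list()) {
  stopifnot(all(stdDevs >= 0))
  rows <- list()
  curves <- list()
  for (sd in stdDevs) for (s in seeds) {
    res <- .maskedRecoveryRun(X, A, maskFraction, s, noiseSd = sd,
                              trainConfig = trainConfig,
                              keepCurves = TRUE)
    lab <- sprintf("std_dev=%g", sd)
    rows[[length(rows) + 1L]] <-
      data.frame(condition = lab, seed = s, acc = res$acc,
                 auroc = res$auroc, ap = res$ap, stringsAsFactors = FALSE)
    curves[[sprintf("%s,seed=%d", lab, s)]] <- res$fit@metricHistory
  }
  list(report = seedReport(do.call(rbind, rows),
                           metadata = list(experiment = "noise",
                                           stdDevs = stdDevs,
                                           seeds = seeds,
                                           maskFraction = maskFraction,
                                           trainConfig = trainConfig)),
       curves = curves)
}

#' Top communicating genes subnetwork
#'
#' Ranks genes by total communication probability (row sums of the
#' reconstructed probability matrix, diagonal excluded) and returns the
#' induced subnetwork on the top `k` genes as a ranked edge list.
#'
#' @param probs gene-level reconstructed probability matrix.
#' @param geneIds gene symbols aligned with `probs`.
#' @param k number of top genes (clamped to the gene count with a
#'   warning).
#' @return data.frame `gene_a`, `gene_b`, `probability`, decreasing.
#' @export
topGeneNetwork <- function(probs, geneIds, k = 10) {
  assertSquareSymmetric(probs, "probability matrix")
  if (length(geneIds) != nrow(probs))
    stop("geneIds length must match probs")
  if (k > length(geneIds)) {
    warning("k exceeds gene count; clamping to ", length(geneIds))
    k <- length(geneIds)
  }
  strength <- rowSums(probs) - diag(probs)
  top <- order(strength, decreasing = TRUE)[seq_len(k)]
  sub <- probs[top, top, drop = FALSE]
  idx <- which(upper.tri(sub), arr.ind = TRUE)
  df <- data.frame(gene_a = geneIds[top][idx[, 1]],
                   gene_b = geneIds[top][idx[, 2]],
                   probability = sub[idx], stringsAsFactors = FALSE)
  df <- df[order(-df$probability), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an evaluation report
#'
#' @param report an [EvalReport-class].
#' @param path output file; `.json`/`.jsonl` writes JSON lines, anything
#'   else TSV (rows then average rows, marked in the `seed` column).
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  avg <- reportAverages(report)
  avg$seed <- "Average"
  rows <- reportRows(report)
  rows$seed <- as.character(rows$seed)
  out <- rbind(rows[, c("condition", "seed", "acc", "auroc", "ap")],
               avg[, c("condition", "seed", "acc", "auroc", "ap")])
  if (grepl("\\.jsonl?$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (r in seq_len(nrow(out)))
      writeLines(jsonlite::toJSON(as.list(out[r, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  } else {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
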