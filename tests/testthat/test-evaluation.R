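test_that("AUROC handles separation, inversion, ties and oracles", {
  expect_equal(rocAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(rocAUC(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
  expect_error(rocAUC(c(1, 1), c(0.5, 0.6)), "undefined")

  set.seed(77)
  for (rep in 1:20) {
    lb <- rbinom(12, 1, 0.5)
    if (sum(lb) %in% c(0, 12)) lb[1:2] <- c(0, 1)
    sc <- sample(seq(0, 1, 0.25), 12, replace = TRUE)  # forced ties
    expect_equal(rocAUC(lb, sc), oracleAUC(lb, sc), tolerance = 1e-12)
  }
})

test_that("average precision matches the threshold-sweep definition", {
  expect_equal(averagePrecision(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(averagePrecision(c(0, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)),
               0.5)
  set.seed(13)
  for (rep in 1:20) {
    lb <- rbinom(15, 1, 0.4)
    if (sum(lb) %in% c(0, 15)) lb[1:2] <- c(0, 1)
    sc <- round(runif(15), 1)
    expect_equal(averagePrecision(lb, sc), oracleAP(lb, sc),
                 tolerance = 1e-12)
  }
})

test_that("accuracy counts the confusion matrix at the threshold", {
  # TP=3 TN=1 FP=1 FN=0 -> 0.8
  expect_equal(accuracyScore(c(1, 1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6, 0.1)),
               0.8)
  expect_equal(accuracyScore(c(1, 0), c(0.9, 0.1)), 1)
  set.seed(4)
  lb <- rbinom(20, 1, 0.5)
  sc <- runif(20)
  expect_equal(accuracyScore(lb, sc), oracleACC(lb, sc))
  # permutation invariance
  pm <- sample(20)
  expect_equal(accuracyScore(lb[pm], sc[pm]), accuracyScore(lb, sc))
})

test_that("rank metrics are invariant under monotone transforms", {
  set.seed(99)
  lb <- rbinom(30, 1, 0.5); lb[1:2] <- c(0, 1)
  sc <- rnorm(30)
  expect_equal(rocAUC(lb, sc), rocAUC(lb, exp(sc)), tolerance = 1e-12)
  expect_equal(averagePrecision(lb, sc), averagePrecision(lb, 3 * sc + 7),
               tolerance = 1e-12)
  # complement identity for tie-free scores
  expect_equal(rocAUC(lb, sc) + rocAUC(lb, -sc), 1, tolerance = 1e-12)
})

test_that("metrics agree with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(123)
  for (rep in 1:10) {
    lb <- rbinom(40, 1, 0.5); lb[1:2] <- c(0, 1)
    sc <- round(rnorm(40), 1)
    ref <- as.numeric(suppressMessages(pROC::auc(lb, sc,
                                                 direction = "<")))
    expect_equal(rocAUC(lb, sc), ref, tolerance = 1e-12)
  }
})

test_that("negative-edge sampling is seeded, disjoint and bounded", {
  A <- 1 - diag(4)
  expect_error(sampleNegativeEdges(A, 1), "non-edges")

  set.seed(2)
  B <- oracleKnn(euclideanDistances(matrix(rnorm(24), 12, 2)), 2)
  non <- which(upper.tri(B) & B == 0)
  all_neg <- sampleNegativeEdges(B, length(non), seed = 1)
  expect_equal(sort(all_neg[, 1] + 12 * (all_neg[, 2] - 1)), sort(non))

  s1 <- sampleNegativeEdges(B, 5, seed = 42)
  s2 <- sampleNegativeEdges(B, 5, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(B[s1] == 0))
  expect_true(all(s1[, 1] < s1[, 2]))
})

test_that("seed reports append exact arithmetic-mean average rows", {
  rows <- data.frame(
    condition = "after",
    seed = 1:5,
    acc = c(0.891, 0.883, 0.892, 0.859, 0.867),
    auroc = c(0.928, 0.928, 0.936, 0.919, 0.917),
    ap = c(0.891, 0.893, 0.901, 0.89, 0.88))
  rep <- seedReport(rows)
  avg <- reportAverages(rep)
  expect_equal(round(avg$acc, 3), 0.878)
  expect_equal(round(avg$auroc, 3), 0.926)
  expect_equal(round(avg$ap, 3), 0.891)
  expect_equal(avg$acc, mean(rows$acc), tolerance = 1e-15)

  single <- seedReport(rows[1, ])
  expect_equal(reportAverages(single)$auroc, 0.928)
})

test_that("top-gene networks rank by communication strength", {
  set.seed(10)
  g <- 12
  P <- matrix(runif(g * g), g); P <- (P + t(P)) / 2
  ids <- sprintf("G%02d", 1:g)
  full <- topGeneNetwork(P, ids, g)
  expect_equal(nrow(full), choose(g, 2))

  P2 <- P; P2[3, ] <- 0.99; P2[, 3] <- 0.99
  expect_equal(topGeneNetwork(P2, ids, 3)$gene_a[1] == "G03" ||
               topGeneNetwork(P2, ids, 3)$gene_b[1] == "G03", TRUE)

  top <- topGeneNetwork(P, ids, 5)
  strength <- rowSums(P) - diag(P)
  expTop <- sort(ids[order(strength, decreasing = TRUE)[1:5]])
  expect_equal(sort(unique(c(top$gene_a, top$gene_b))), expTop)
  expect_true(all(diff(top$probability) <= 0))
  expect_warning(topGeneNetwork(P, ids, 50), "clamping")
})

test_that("benchmark experiments produce consistent seeded reports", {
  fx <- smallTissue()
  X <- standardizeExpression(tissueExpression(fx))
  A <- tissueAdjacency(fx)
  cfgFast <- list(epochs = 8, hiddenDims = c(16, 16, 8), latentDim = 8)

  er <- edgeRemovalExperiment(X, A, fractions = c(0.1, 0.3), seeds = 0:1,
                              trainConfig = cfgFast)
  rows <- reportRows(er)
  expect_equal(nrow(rows), 4L)
  for (cond in unique(rows$condition)) {
    expect_equal(reportAverages(er)$acc[reportAverages(er)$condition == cond],
                 mean(rows$acc[rows$condition == cond]), tolerance = 1e-15)
  }

  ne <- noiseExperiment(X, A, stdDevs = c(0, 2), seeds = 0:1,
                        maskFraction = 0.1, trainConfig = cfgFast)
  nr <- reportRows(ne$report)
  expect_equal(nrow(nr), 4L)
  expect_true(all(vapply(ne$curves, nrow, 1L) == 8L))
  expect_true(all(is.finite(nr$auroc)))

  # a zero-noise row equals the edge-removal run at the same mask/seed
  base <- reportRows(edgeRemovalExperiment(X, A, fractions = 0.1,
                                           seeds = 0:1,
                                           trainConfig = cfgFast))
  noise0 <- nr[nr$condition == "std_dev=0", c("seed", "acc", "auroc", "ap")]
  rownames(noise0) <- rownames(base) <- NULL
  expect_equal(noise0, base[, c("seed", "acc", "auroc", "ap")])
})
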