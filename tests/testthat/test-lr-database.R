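test_that("L-R tables load with species handling and complex splitting", {
  tf <- writeTempTSV(data.frame(ligand = c("L1", "L2"),
                                receptor = c("R1", "R2")))
  db <- readLRTable(tf, species = "human")
  expect_s4_class(db, "LRDatabase")
  expect_equal(length(db), 2L)
  expect_equal(speciesCounts(db), c(human = 2L, mouse = 0L))

  tf2 <- writeTempTSV(data.frame(ligand = "ITGA5_ITGB1", receptor = "FN1",
                                 species = "human"))
  db2 <- readLRTable(tf2)
  expect_equal(lrPairs(db2)$ligandSubunits[[1]], c("ITGA5", "ITGB1"))
  expect_equal(lrPairs(db2)$receptorSubunits[[1]], "FN1")

  tf3 <- writeTempTSV(data.frame(ligand = character(),
                                 receptor = character()))
  expect_equal(length(readLRTable(tf3, species = "mouse")), 0L)
})

test_that("malformed L-R tables are rejected with informative errors", {
  tf <- writeTempTSV(data.frame(ligand = "L1", partner = "R1"))
  expect_error(readLRTable(tf, species = "human"), "receptor")
  tf2 <- writeTempTSV(data.frame(ligand = "L1", receptor = "R1",
                                 species = "rat"))
  expect_error(readLRTable(tf2), "species")
  tf3 <- writeTempTSV(data.frame(ligand = "L1", receptor = "R1"))
  expect_error(readLRTable(tf3), "species")
})

test_that("merging collapses duplicates under the canonical key", {
  mk <- function(lig, rec) {
    tf <- writeTempTSV(data.frame(ligand = lig, receptor = rec))
    readLRTable(tf, species = "human")
  }
  a <- mk("L1", "R1")
  b <- mk("l1 ", "R1")      # case/whitespace variant, same canonical key
  expect_equal(length(mergeLRDatabases(a, b)), 1L)

  d1 <- mk(c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  d2 <- mk(c("C1", "C2", "C3", "C4"), c("D1", "D2", "D3", "D4"))
  expect_equal(length(mergeLRDatabases(d1, d2)), 7L)

  # direction is preserved: L->R and R->L are distinct pairs
  fwd <- mk("L1", "R1"); rev <- mk("R1", "L1")
  expect_equal(length(mergeLRDatabases(fwd, rev)), 2L)

  # reordered complex subunits collapse
  c1 <- mk("ITGA5_ITGB1", "FN1"); c2 <- mk("ITGB1_ITGA5", "FN1")
  expect_equal(length(mergeLRDatabases(c1, c2)), 1L)
})

test_that("merge_and_dedup is idempotent and order-stable", {
  db <- simulateLRDatabase(sprintf("G%02d", 1:20), 12, complexFrac = 0.25,
                           seed = 3)
  m <- mergeLRDatabases(db, db)
  expect_equal(length(m), length(db))
  expect_equal(lrPairs(m)$key, lrPairs(db)$key)
})

test_that("gene adjacency marks related genes symmetrically", {
  tf <- writeTempTSV(data.frame(ligand = "g1", receptor = "g2"))
  db <- readLRTable(tf, species = "human")
  A <- geneAdjacency(c("g1", "g2", "g3"), db)
  expect_equal(A, matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3,
                         dimnames = list(c("g1", "g2", "g3"),
                                         c("g1", "g2", "g3"))))

  empty <- readLRTable(writeTempTSV(data.frame(ligand = character(),
                                               receptor = character())),
                       species = "human")
  expect_true(all(geneAdjacency(c("a", "b"), empty) == 0))
  expect_error(geneAdjacency(character(), db), "empty gene list")
})

test_that("gene adjacency matches a brute-force membership oracle", {
  genes <- sprintf("G%02d", 1:20)
  db <- simulateLRDatabase(genes, 15, complexFrac = 0.2, seed = 11)
  A <- geneAdjacency(genes, db)
  # oracle: double loop over all gene pairs testing pair membership
  related <- function(a, b) {
    p <- lrPairs(db)
    any(vapply(seq_len(nrow(p)), function(r) {
      (a %in% p$ligandSubunits[[r]] && b %in% p$receptorSubunits[[r]]) ||
      (b %in% p$ligandSubunits[[r]] && a %in% p$receptorSubunits[[r]])
    }, logical(1)))
  }
  B <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    if (i != j && related(genes[i], genes[j])) B[i, j] <- 1
  expect_equal(unname(A), B)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
})

test_that("gene adjacency restricted to a subset equals the submatrix", {
  genes <- sprintf("G%02d", 1:15)
  db <- simulateLRDatabase(genes, 10, seed = 5)
  A <- geneAdjacency(genes, db)
  sub <- genes[c(2, 5, 9, 14)]
  expect_equal(geneAdjacency(sub, db), A[sub, sub])
})
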