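test_that("the initial matching is uniform with uniform marginals", {
  P <- initMatching(2, 2)
  expect_equal(P, matrix(0.25, 2, 2))
  expect_equal(initMatching(1, 1), matrix(1))
  P35 <- initMatching(3, 5)
  expect_true(all(P35 == 1 / 15))
  expect_equal(rowSums(P35), rep(1 / 3, 3))
  expect_equal(colSums(P35), rep(1 / 5, 5))
})

test_that("the GW cost matches the quadruple-loop oracle", {
  set.seed(9)
  X <- matrix(rnorm(10), 5, 2)
  DX <- euclideanDistances(X)
  expect_equal(gwCost(DX, DX, diag(5) / 5), 0, tolerance = 1e-12)

  DX2 <- euclideanDistances(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE))
  DY2 <- euclideanDistances(matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE))
  P2 <- initMatching(2, 2)
  expect_equal(gwCost(DX2, DY2, P2), oracleGW(DX2, DY2, P2),
               tolerance = 1e-10)

  for (rep in 1:3) {
    set.seed(rep)
    A <- matrix(rnorm(14), 7, 2); B <- matrix(rnorm(12), 6, 2)
    DA <- euclideanDistances(A); DB <- euclideanDistances(B)
    P <- matrix(runif(42), 7, 6); P <- P / sum(P)
    expect_equal(gwCost(DA, DB, P), oracleGW(DA, DB, P),
                 tolerance = 1e-10)
  }
})

test_that("self-alignment recovers the identity with near-zero cost", {
  fx <- simulateTissue(nCells = 50, seed = 0)
  co <- tissueCoords(fx)
  al <- alignSlices(coordsX = co, coordsY = co)
  expect_lt(alignmentCost(al), 1e-3)
  expect_gte(mean(apply(transportPlan(al), 1, which.max) == 1:50), 0.95)
  expect_lt(max(abs(rowSums(transportPlan(al)) - 1 / 50)), 1e-8)
  expect_lt(max(abs(colSums(transportPlan(al)) - 1 / 50)), 1e-6)

  # rigid transforms leave the distance matrices, hence the cost, alone
  moved <- sweep(co %*% t(rot2(90)), 2, c(3, -2), "+")
  al2 <- alignSlices(coordsX = co, coordsY = moved)
  expect_lt(abs(alignmentCost(al2) - alignmentCost(al)), 1e-6)

  # a permuted copy is unscrambled
  set.seed(1)
  pm <- sample(50)
  al3 <- alignSlices(coordsX = co, coordsY = co[pm, ])
  expect_gte(mean(apply(transportPlan(al3), 1, which.max) == order(pm)),
             0.95)
  expect_error(alignSlices(coordsX = co, coordsY = co, epsilon = -1),
               "epsilon")
})

test_that("Procrustes recovers exact and jittered planted transforms", {
  set.seed(5)
  X <- matrix(rnorm(60, sd = 2), 30, 2)

  idt <- procrustesTransform(X, X)
  expect_equal(idt@rotation, diag(2), tolerance = 1e-10)
  expect_equal(idt@translation, c(0, 0), tolerance = 1e-10)

  Y <- sweep(X %*% t(rot2(90)), 2, c(1, 2), "+")
  tr <- procrustesTransform(X, Y)
  expect_equal(tr@rotation, rot2(90), tolerance = 1e-8)
  expect_equal(tr@translation, c(1, 2), tolerance = 1e-8)
  expect_lt(max(abs(applyTransform(tr, X) - Y)), 1e-8)

  set.seed(6)
  Yj <- sweep(X %*% t(rot2(37)), 2, c(-2, 5), "+") +
    matrix(rnorm(60, sd = 0.01), 30, 2)
  trj <- procrustesTransform(X, Yj)
  expect_lt(abs(angleOf(trj@rotation) - 37), 1)
  rms <- sqrt(mean((applyTransform(trj, X) - Yj)^2))
  expect_lt(rms, 3 * 0.01)

  expect_error(procrustesTransform(matrix(1, 5, 2), matrix(2, 5, 2)),
               "degenerate")
})

test_that("transform algebra composes, inverts and round-trips text files", {
  t1 <- procrustesTransform(matrix(rnorm(20), 10, 2),
                            matrix(rnorm(20), 10, 2))
  t2 <- new("RigidTransform", rotation = rot2(25), translation = c(1, -3),
            scale = 1)
  X <- matrix(rnorm(14), 7, 2)
  expect_equal(applyTransform(composeTransforms(t2, t1), X),
               applyTransform(t2, applyTransform(t1, X)),
               tolerance = 1e-10)
  expect_equal(applyTransform(invertTransform(t2), applyTransform(t2, X)),
               X, tolerance = 1e-10)

  tf <- tempfile(fileext = ".txt")
  writeTransform(t2, tf)
  back <- readTransform(tf)
  expect_equal(back@rotation, t2@rotation, tolerance = 1e-15)
  expect_equal(back@translation, t2@translation, tolerance = 1e-15)
})

test_that("stacking assigns layer spacing and preserves aligned frames", {
  s1 <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("c", 1:10), NULL))
  idt <- new("RigidTransform", rotation = diag(2), translation = c(0, 0),
             scale = 1)
  st <- stackSlices(list(s1, s1), list(idt, idt), 10)
  expect_equal(unique(st$coords[, "z"]), c(0, 10))
  expect_equal(unname(st$coords[1:10, 1:2]), unname(s1))
  expect_error(stackSlices(list(s1), list(idt), -1), "layerSpacing")

  # jittered copies with planted transforms stack onto a vertical line
  tr <- new("RigidTransform", rotation = rot2(30), translation = c(2, 1),
            scale = 1)
  s2 <- applyTransform(tr, s1) + matrix(rnorm(20, sd = 0.005), 10, 2)
  rownames(s2) <- rownames(s1)
  st2 <- stackSlices(list(s1, s2), list(idt, invertTransform(tr)), 5)
  a <- st2$coords[st2$layer == 1, 1:2]
  b <- st2$coords[st2$layer == 2, 1:2]
  expect_lt(max(sqrt(rowSums((a - b)^2))), 0.05)
})

test_that("mutual-NN refinement sharpens a soft-plan Procrustes fit", {
  base <- simulateTissue(nCells = 120, seed = 3)
  ms <- simulateMultislice(base, nSlices = 2, seed = 3)
  x <- ms$slices[[2]]; y <- ms$slices[[1]]
  al <- suppressWarnings(alignSlices(coordsX = x, coordsY = y,
                                     nRestarts = 1))
  rough <- procrustesTransform(x, y, transportPlan(al))
  fine <- refineTransform(x, y, rough)
  expect_lt(abs(angleOf(fine@rotation) + ms$config$rotationDeg), 0.5)
  expect_gte(mutualNNFraction(applyTransform(fine, x), y), 0.9)
})
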