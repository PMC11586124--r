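test_that("the GCN encoder is permutation-equivariant and matches hand arithmetic", {
  set.seed(2)
  P <- matrix(rnorm(24), 12, 2)
  A <- knnAdjacency(euclideanDistances(P), 3)
  Ahat <- normalizeAdjacency(A)
  X <- matrix(rnorm(12 * 5), 12, 5)
  w <- initEncoderWeights(5, c(7, 6, 4), 3, seed = 1)
  enc <- encodeGraph(X, Ahat, w)

  pm <- sample(12)
  encP <- encodeGraph(X[pm, ], normalizeAdjacency(A[pm, pm]), w)
  expect_equal(encP$mu, enc$mu[pm, ], tolerance = 1e-12)
  expect_equal(encP$logSigma, enc$logSigma[pm, ], tolerance = 1e-12)

  # zero input with any weights gives zero latents (no biases anywhere)
  encZ <- encodeGraph(matrix(0, 12, 5), Ahat, w)
  expect_true(all(encZ$mu == 0) && all(encZ$logSigma == 0))

  # 2-node toy graph with hand-chosen 1x1 weights
  A2 <- matrix(c(0, 1, 1, 0), 2)
  Ah2 <- normalizeAdjacency(A2)       # all entries 0.5
  X2 <- matrix(c(2, -1), 2, 1)
  w2 <- list(W0 = matrix(3), W1 = matrix(0.5), W2 = matrix(2),
             Wmu = matrix(1.5), Wsig = matrix(-1))
  h <- Ah2 %*% X2 * 3
  h <- pmax(h, 0)
  h <- pmax(Ah2 %*% h * 0.5, 0)
  h <- pmax(Ah2 %*% h * 2, 0)
  m3 <- Ah2 %*% h
  e2 <- encodeGraph(X2, Ah2, w2)
  expect_equal(e2$mu, m3 * 1.5, tolerance = 1e-10)
  expect_equal(e2$logSigma, m3 * -1, tolerance = 1e-10)

  expect_error(encodeGraph(X[1:5, ], Ahat, w), "shape error")
})

test_that("reparameterization is exact, seeded and statistically correct", {
  mu <- matrix(1:6 / 2, 3, 2)
  ls <- matrix(log(2), 3, 2)
  expect_equal(reparameterize(mu, ls, epsilon = mu * 0)$z, mu)
  r1 <- reparameterize(mu, ls, seed = 4)
  r2 <- reparameterize(mu, ls, seed = 4)
  expect_identical(r1$z, r2$z)
  expect_equal(r1$z, mu + exp(ls) * r1$epsilon)

  big <- reparameterize(matrix(2, 1e5, 1), matrix(log(3), 1e5, 1),
                        seed = 1)
  expect_gt(mean(big$z), 1.97); expect_lt(mean(big$z), 2.03)
  expect_gt(sd(big$z), 2.97); expect_lt(sd(big$z), 3.03)
})

test_that("the inner-product decoder matches the explicit Gram matrix", {
  expect_equal(decodeLatent(matrix(0, 4, 3)), matrix(0.5, 4, 4))
  z2 <- matrix(c(1, -1), 2, 1)
  expect_equal(decodeLatent(z2)[1, 2], plogis(-1))

  set.seed(8)
  z <- matrix(rnorm(6 * 4), 6, 4)
  Pz <- decodeLatent(z)
  expect_equal(Pz, plogis(z %*% t(z)), tolerance = 1e-12)
  expect_equal(Pz, t(Pz))
})

test_that("reconstruction and KL losses match closed forms and oracles", {
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(reconstructionLoss(A, matrix(0.5, 2, 2)), log(2))
  expect_lt(reconstructionLoss(A, matrix(1 - 1e-13, 2, 2)), 1e-10)

  set.seed(12)
  A5 <- oracleKnn(euclideanDistances(matrix(rnorm(10), 5, 2)), 2)
  P5 <- matrix(runif(25, 0.05, 0.95), 5, 5)
  P5 <- (P5 + t(P5)) / 2
  naive <- 0; cnt <- 0
  for (i in 1:5) for (j in 1:5) if (i != j) {
    naive <- naive - (A5[i, j] * log(P5[i, j]) +
                      (1 - A5[i, j]) * log(1 - P5[i, j]))
    cnt <- cnt + 1
  }
  expect_equal(reconstructionLoss(A5, P5), naive / cnt, tolerance = 1e-12)

  expect_equal(klLoss(matrix(0, 3, 2), matrix(0, 3, 2)), 0)
  expect_equal(klLoss(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)

  # quadrature oracle: KL between diagonal Gaussians, per dimension
  set.seed(3)
  mu <- matrix(rnorm(4, sd = 0.8), 1, 4)
  ls <- matrix(rnorm(4, sd = 0.3), 1, 4)
  klq <- sum(vapply(1:4, function(j) {
    integrand <- function(x) {
      lq <- dnorm(x, mu[j], exp(ls[j]), log = TRUE)
      exp(lq) * (lq - dnorm(x, 0, 1, log = TRUE))
    }
    integrate(integrand, -30, 30, rel.tol = 1e-10)$value
  }, numeric(1)))
  expect_equal(klLoss(mu, ls), klq, tolerance = 1e-6)
})

test_that("the discriminator separates shifted latents but not the prior", {
  set.seed(31)
  dz <- 4
  dw <- initDiscWeights(dz, 32, seed = 2)
  zPrior <- matrix(rnorm(1e4 * dz), 1e4, dz)
  prior <- matrix(rnorm(1e4 * dz), 1e4, dz)
  acc <- NA
  for (i in 1:50) {
    st <- adversarialStep(zPrior, prior, dw, lr = 0.05)
    dw <- st$discWeights
    acc <- st$discAccuracy
  }
  expect_gt(acc, 0.45); expect_lt(acc, 0.55)

  dw2 <- initDiscWeights(dz, 32, seed = 2)
  zFar <- matrix(rnorm(500 * dz) + 10, 500, dz)
  prior2 <- matrix(rnorm(500 * dz), 500, dz)
  for (i in 1:50) {
    st <- adversarialStep(zFar, prior2, dw2, lr = 0.05)
    dw2 <- st$discWeights
  }
  expect_gt(st$discAccuracy, 0.95)
  expect_true(is.finite(st$discLoss) && is.finite(st$genLoss))
})

test_that("analytic encoder gradients agree with finite differences", {
  set.seed(42)
  n <- 8
  A <- oracleKnn(euclideanDistances(matrix(rnorm(2 * n), n, 2)), 2)
  Ahat <- normalizeAdjacency(A)
  X <- matrix(rnorm(n * 5), n, 5)
  w <- initEncoderWeights(5, c(4, 4, 3), 2, seed = 3)
  eps <- matrix(rnorm(n * 2), n, 2)
  posW <- 3; beta <- 1
  lossFn <- function(w) {
    fw <- spatialCCI:::.vgaeForward(X, Ahat, w)
    z <- fw$mu + exp(fw$logSigma) * eps
    reconstructionLoss(A, plogis(z %*% t(z)), posWeight = posW) +
      beta * klLoss(fw$mu, fw$logSigma)
  }
  fw <- spatialCCI:::.vgaeForward(X, Ahat, w)
  sig <- exp(fw$logSigma)
  z <- fw$mu + sig * eps
  G <- spatialCCI:::.reconGradS(A, plogis(z %*% t(z)), posW)
  dz <- (G + t(G)) %*% z
  dmu <- dz + beta * fw$mu / n
  dls <- dz * eps * sig + beta * (sig^2 - 1) / n
  gWmu <- t(fw$M3) %*% dmu
  dM3 <- dmu %*% t(w$Wmu) + dls %*% t(w$Wsig)
  dU3 <- (Ahat %*% dM3) * (fw$U3 > 0)
  gW2 <- t(fw$M2) %*% dU3
  h <- 1e-6
  for (probe in list(list("Wmu", gWmu), list("W2", gW2))) {
    k <- probe[[1]]; ana <- probe[[2]]
    num <- ana * 0
    for (i in seq_along(num)) {
      wp <- w; wp[[k]][i] <- wp[[k]][i] + h
      wm <- w; wm[[k]][i] <- wm[[k]][i] - h
      num[i] <- (lossFn(wp) - lossFn(wm)) / (2 * h)
    }
    expect_lt(max(abs(num - ana)), 1e-7)
  }
})

test_that("training reduces the loss, is seed-reproducible, and beta regularizes", {
  fx <- smallTissue()
  X <- standardizeExpression(tissueExpression(fx))
  A <- tissueAdjacency(fx)

  fit1 <- trainVGAE(X, A, epochs = 30, seed = 1)
  h <- lossHistory(fit1)
  expect_equal(nrow(h), 30L)
  expect_lt(h$total[30], h$total[1])
  expect_true(all(is.finite(h$total)))

  fit2 <- trainVGAE(X, A, epochs = 30, seed = 1)
  expect_identical(lossHistory(fit1), lossHistory(fit2))
  expect_identical(edgeProbabilities(fit1), edgeProbabilities(fit2))

  f0 <- trainVGAE(X, A, epochs = 20, beta = 0, advWeight = 0, seed = 2)
  f1 <- trainVGAE(X, A, epochs = 20, beta = 1, advWeight = 0, seed = 2)
  expect_gte(tail(lossHistory(f0)$kl, 1), tail(lossHistory(f1)$kl, 1))
})

test_that("fit containers expose ranked edges and survive checkpoints", {
  fx <- smallTissue()
  X <- standardizeExpression(tissueExpression(fx))
  fit <- trainVGAE(X, tissueAdjacency(fx), epochs = 5, seed = 1)

  re <- rankedEdges(fit)
  expect_true(all(diff(re$probability) <= 0))
  expect_equal(nrow(re), choose(nrow(X), 2))
  expect_equal(fit@z, fit@mu + exp(fit@logSigma) * fit@epsilon)

  cp <- tempfile(fileext = ".rds")
  writeCheckpoint(fit, cp)
  back <- readCheckpoint(cp)
  expect_identical(edgeProbabilities(back), edgeProbabilities(fit))
  expect_identical(back@weights, fit@weights)
})
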