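# Variational graph autoencoder: three-layer GCN encoder with separate
# mean / log-sd heads, reparameterized Gaussian latent, inner-product
# decoder, weighted cross-entropy + KL objective, and an adversarial
# regularizer pushing the latent distribution toward the standard-normal
# prior. Forward pass, backpropagation and Adam are implemented directly
# on dense matrices; training is full-batch.

.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -r, r), nin, nout)
}

#' Initialize encoder weights
#'
#' Glorot-uniform initialization for the three shared GCN layers and the
#' two linear graph-convolution heads (mean and log standard deviation).
#'
#' @param nFeatures input feature dimension.
#' @param hiddenDims integer vector of the three GCN layer widths.
#' @param latentDim latent dimension.
#' @param seed RNG seed (caller's RNG state restored).
#' @return named list of weight matrices `W0`, `W1`, `W2`, `Wmu`, `Wsig`.
#' @export
initEncoderWeights <- function(nFeatures, hiddenDims = c(64, 64, 32),
                               latentDim = 16, seed = NULL) {
  if (length(hiddenDims) != 3L)
    stop("the encoder uses exactly 3 GCN layers; 'hiddenDims' needs 3 values")
  withSeed(seed, list(
    W0 = .glorot(nFeatures, hiddenDims[1]),
    W1 = .glorot(hiddenDims[1], hiddenDims[2]),
    W2 = .glorot(hiddenDims[2], hiddenDims[3]),
    Wmu = .glorot(hiddenDims[3], latentDim),
    Wsig = .glorot(hiddenDims[3], latentDim)))
}

# Forward pass with cached intermediates for backpropagation.
.vgaeForward <- function(X, Ahat, w) {
  M0 <- Ahat %*% X
  U1 <- M0 %*% w$W0; H1 <- pmax(U1, 0)
  M1 <- Ahat %*% H1
  U2 <- M1 %*% w$W1; H2 <- pmax(U2, 0)
  M2 <- Ahat %*% H2
  U3 <- M2 %*% w$W2; H3 <- pmax(U3, 0)
  M3 <- Ahat %*% H3
  list(M0 = M0, U1 = U1, M1 = M1, U2 = U2, M2 = M2, U3 = U3, M3 = M3,
       mu = M3 %*% w$Wmu, logSigma = M3 %*% w$Wsig)
}

#' Graph-convolutional encoding
#'
#' Runs the three ReLU GCN layers `H^(l) = ReLU(A_hat H^(l-1) W^(l-1))`
#' followed by the linear heads `mu = A_hat H W_mu` and
#' `log sigma = A_hat H W_sig`. Deterministic given its inputs.
#'
#' @param X node-feature matrix (cells x genes), rows aligned with `Ahat`.
#' @param Ahat symmetrically normalized adjacency
#'   (see [normalizeAdjacency()]).
#' @param weights list from [initEncoderWeights()].
#' @return list with matrices `mu` and `logSigma`.
#' @export
encodeGraph <- function(X, Ahat, weights) {
  if (nrow(X) != nrow(Ahat))
    stop("shape error: X has ", nrow(X), " rows but Ahat is ",
         nrow(Ahat), " x ", ncol(Ahat))
  if (ncol(X) != nrow(weights$W0))
    stop("shape error: layer W0 expects ", nrow(weights$W0),
         " input features, got ", ncol(X))
  f <- .vgaeForward(X, Ahat, weights)
  list(mu = f$mu, logSigma = f$logSigma)
}

#' Reparameterized latent sample
#'
#' `z = mu + exp(logSigma) * epsilon` with `epsilon ~ N(0, I)`. Supplying
#' `epsilon` directly bypasses the RNG.
#'
#' @param mu,logSigma latent Gaussian parameters (same shape).
#' @param seed RNG seed for the standard-normal draw.
#' @param epsilon optional pre-drawn noise matrix.
#' @return list with `z` and the `epsilon` used.
#' @export
reparameterize <- function(mu, logSigma, seed = NULL, epsilon = NULL) {
  if (!identical(dim(mu), dim(logSigma)))
    stop("shape error: mu and logSigma must have the same shape")
  if (is.null(epsilon))
    epsilon <- withSeed(seed, matrix(rnorm(length(mu)), nrow(mu), ncol(mu)))
  list(z = mu + exp(logSigma) * epsilon, epsilon = epsilon)
}

#' Inner-product decoder
#'
#' Edge probabilities `probs[i, j] = logistic(z_i . z_j)`; symmetric by
#' construction.
#'
#' @param z latent coordinate matrix (nodes x latent dim).
#' @return n x n probability matrix.
#' @export
decodeLatent <- function(z) {
  if (!all(is.finite(z))) stop("non-finite latent coordinates")
  plogis(z %*% t(z))
}

#' Weighted binary cross-entropy reconstruction loss
#'
#' Mean cross-entropy of decoded probabilities against the adjacency,
#' over off-diagonal entries (self-loops excluded from the objective).
#' `posWeight` multiplies the positive-class term; training uses
#' `#non-edges / #edges` to counter graph sparsity, while the default 1
#' is the plain unweighted mean.
#'
#' @param A binary symmetric adjacency.
#' @param probs probability matrix from [decodeLatent()].
#' @param posWeight positive-class weight (default 1 = unweighted).
#' @param clampEps probabilities are clamped to `[clampEps, 1 - clampEps]`.
#' @return non-negative scalar.
#' @export
reconstructionLoss <- function(A, probs, posWeight = 1, clampEps = 1e-12) {
  if (!identical(dim(A), dim(probs)))
    stop("shape error: A and probs must match")
  p <- pmin(pmax(probs, clampEps), 1 - clampEps)
  off <- !diag(nrow = nrow(A))
  y <- A[off]
  p <- p[off]
  mean(-(posWeight * y * log(p) + (1 - y) * log(1 - p)))
}

#' KL divergence to the standard-normal prior
#'
#' Diagonal-Gaussian KL summed over latent dimensions and averaged over
#' nodes: `1/2 sum_j (mu_j^2 + sigma_j^2 - 1 - log sigma_j^2)`.
#' Non-negative; zero iff `mu = 0`, `sigma = 1`.
#'
#' @param mu,logSigma latent Gaussian parameters.
#' @return non-negative scalar.
#' @export
klLoss <- function(mu, logSigma) {
  if (!identical(dim(mu), dim(logSigma)))
    stop("shape error: mu and logSigma must have the same shape")
  mean(0.5 * rowSums(mu^2 + exp(2 * logSigma) - 1 - 2 * logSigma))
}

#' Initialize discriminator weights
#'
#' Two-layer MLP (latent -> hidden ReLU -> logit) used by the adversarial
#' regularizer to separate prior samples from encoder latents.
#'
#' @param latentDim latent dimension.
#' @param hidden hidden width.
#' @param seed RNG seed.
#' @return list `W1`, `b1`, `w2`, `b2`.
#' @export
initDiscWeights <- function(latentDim, hidden = 64, seed = NULL) {
  withSeed(seed, list(
    W1 = .glorot(latentDim, hidden), b1 = rep(0, hidden),
    w2 = .glorot(hidden, 1L), b2 = 0))
}

.discForward <- function(z, dw) {
  A1 <- sweep(z %*% dw$W1, 2, dw$b1, "+")
  H <- pmax(A1, 0)
  s <- drop(H %*% dw$w2) + dw$b2
  list(A1 = A1, H = H, s = s, p = plogis(s))
}

# Gradient of mean BCE(disc(z), target) wrt discriminator weights and z.
.discGrads <- function(z, target, dw) {
  fw <- .discForward(z, dw)
  n <- nrow(z)
  ds <- (fw$p - target) / n                 # d mean-BCE / d logit
  dH <- outer(ds, drop(dw$w2))
  dA1 <- dH * (fw$A1 > 0)
  list(gW1 = t(z) %*% dA1, gb1 = colSums(dA1),
       gw2 = t(fw$H) %*% matrix(ds, ncol = 1), gb2 = sum(ds),
       gz = dA1 %*% t(dw$W1),
       p = fw$p)
}

#' One adversarial regularization step
#'
#' Trains the discriminator one gradient step to separate prior samples
#' (label 1) from encoder latents (label 0), then evaluates the generator
#' loss `-mean(log D(z))` that pushes the encoder latents toward the
#' standard-normal prior.
#'
#' @param z encoder latent sample (treated as fixed for the
#'   discriminator update).
#' @param priorSamples matrix of the same shape drawn from N(0, I).
#' @param discWeights list from [initDiscWeights()].
#' @param lr learning rate of the discriminator gradient step.
#' @return list with `discLoss`, `genLoss`, updated `discWeights`,
#'   `genGradZ` (gradient of the generator loss in z) and `discAccuracy`.
#' @export
adversarialStep <- function(z, priorSamples, discWeights, lr = 0.01) {
  if (!identical(dim(z), dim(priorSamples)))
    stop("shape error: z and priorSamples must have the same shape")
  zc <- rbind(priorSamples, z)
  target <- rep(c(1, 0), each = nrow(z))
  g <- .discGrads(zc, target, discWeights)
  pc <- pmin(pmax(g$p, 1e-12), 1 - 1e-12)
  discLoss <- mean(-(target * log(pc) + (1 - target) * log(1 - pc)))
  discAccuracy <- mean((g$p >= 0.5) == (target == 1))
  dw <- discWeights
  dw$W1 <- dw$W1 - lr * g$gW1
  dw$b1 <- dw$b1 - lr * g$gb1
  dw$w2 <- dw$w2 - lr * g$gw2
  dw$b2 <- dw$b2 - lr * g$gb2
  # generator: fool the updated discriminator into calling z "prior"
  gg <- .discGrads(z, rep(1, nrow(z)), dw)
  pg <- pmin(pmax(gg$p, 1e-12), 1 - 1e-12)
  list(discLoss = discLoss, genLoss = mean(-log(pg)), discWeights = dw,
       genGradZ = gg$gz, discAccuracy = discAccuracy)
}

# --- Adam -------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Gradient of the weighted reconstruction BCE wrt the logit matrix S,
# off-diagonal entries only, normalized like reconstructionLoss().
.reconGradS <- function(A, P, posWeight) {
  n <- nrow(A)
  G <- (-posWeight * A * (1 - P) + (1 - A) * P) / (n * (n - 1))
  diag(G) <- 0
  G
}

#' Train the variational graph autoencoder
#'
#' Full-batch Adam training of the three-layer GCN encoder, inner-product
#' decoder and (optionally) the adversarial prior regularizer. Each epoch:
#' one reparameterized forward pass, the weighted cross-entropy +
#' `beta`-weighted KL objective, one discriminator step and one
#' encoder/decoder step. A fixed seed reproduces the loss history exactly.
#' The adversarial module draws from its own RNG stream, so setting
#' `advWeight = 0` (which skips it entirely) leaves the model trajectory
#' of the remaining terms unchanged.
#'
#' Both regularizers (KL and adversarial) are warmed up linearly from 0
#' to their target weights across the run (`warmup = TRUE`, the default):
#' early epochs fit the graph reconstruction before the prior pull is at
#' full strength, which prevents premature latent collapse in short
#' training budgets. The recorded `kl` and `gen` losses are unweighted;
#' `total` applies the effective epoch weights.
#'
#' @param X node features (cells x genes), typically standardized.
#' @param A binary symmetric adjacency with zero diagonal.
#' @param epochs training epochs (default 30).
#' @param lr Adam learning rate.
#' @param adamBeta1,adamBeta2 Adam moment decay constants. The first
#'   moment default 0.5 follows common adversarial-training practice;
#'   high momentum oscillates in the discriminator game and slows
#'   convergence in short full-batch runs.
#' @param hiddenDims widths of the three GCN layers.
#' @param latentDim latent dimension.
#' @param beta KL weight (default 1).
#' @param advWeight adversarial generator-loss weight; 0 disables the
#'   adversarial module.
#' @param discHidden discriminator hidden width.
#' @param warmup ramp the KL and adversarial weights linearly over the
#'   run (recommended); `FALSE` applies full weights from epoch 1.
#' @param seed run seed controlling weight init, reparameterization draws
#'   and the adversarial stream.
#' @param evalEdges optional list with integer index matrices `pos` and
#'   `neg` (columns i, j); when given, held-out AUROC/AP are recorded per
#'   epoch.
#' @return a [CCIFit-class] object.
#' @export
trainVGAE <- function(X, A, epochs = 30, lr = 0.01,
                      hiddenDims = c(64, 64, 32), latentDim = 32,
                      beta = 1, advWeight = 1, discHidden = 64,
                      warmup = TRUE, adamBeta1 = 0.5, adamBeta2 = 0.999,
                      seed = 1, evalEdges = NULL) {
  assertExpression(X)
  assertBinaryAdjacency(A)
  if (nrow(X) != nrow(A)) stop("X rows must match adjacency dimension")
  if (epochs < 1) stop("'epochs' must be >= 1")
  n <- nrow(A)
  Ahat <- normalizeAdjacency(A)
  nEdges <- sum(A) / 2
  nNon <- n * (n - 1) / 2 - nEdges
  posWeight <- if (nEdges > 0) nNon / nEdges else 1

  modelStream <- makeRngStream(seed)
  advStream <- makeRngStream(seed + 1000003)

  w <- withStream(modelStream,
                  initEncoderWeights(ncol(X), hiddenDims, latentDim))
  dw <- withStream(advStream, initDiscWeights(latentDim, discHidden))
  adam <- .adamInit(w)
  adamD <- .adamInit(dw)

  hist <- vector("list", epochs)
  mhist <- vector("list", epochs)
  fw <- NULL; z <- NULL; epsMat <- NULL; P <- NULL

  for (ep in seq_len(epochs)) {
    ramp <- if (warmup) ep / epochs else 1
    betaEp <- beta * ramp
    advEp <- advWeight * ramp
    fw <- .vgaeForward(X, Ahat, w)
    epsMat <- withStream(modelStream,
                         matrix(rnorm(n * latentDim), n, latentDim))
    sig <- exp(fw$logSigma)
    z <- fw$mu + sig * epsMat
    S <- z %*% t(z)
    P <- plogis(S)

    recon <- reconstructionLoss(A, P, posWeight = posWeight)
    kl <- klLoss(fw$mu, fw$logSigma)

    G <- .reconGradS(A, P, posWeight)
    dz <- (G + t(G)) %*% z

    discLoss <- NA_real_; genLoss <- NA_real_
    if (advWeight > 0) {
      prior <- withStream(advStream,
                          matrix(rnorm(n * latentDim), n, latentDim))
      gD <- .discGrads(rbind(prior, z),
                       rep(c(1, 0), each = n), dw)
      pc <- pmin(pmax(gD$p, 1e-12), 1 - 1e-12)
      tgt <- rep(c(1, 0), each = n)
      discLoss <- mean(-(tgt * log(pc) + (1 - tgt) * log(1 - pc)))
      upd <- .adamStep(dw, list(W1 = gD$gW1, b1 = gD$gb1,
                                w2 = gD$gw2, b2 = gD$gb2),
                       adamD, lr, adamBeta1, adamBeta2)
      dw <- upd$params; adamD <- upd$state
      gG <- .discGrads(z, rep(1, n), dw)
      pg <- pmin(pmax(gG$p, 1e-12), 1 - 1e-12)
      genLoss <- mean(-log(pg))
      dz <- dz + advEp * gG$gz
    }

    dmu <- dz + betaEp * fw$mu / n
    dlogSigma <- dz * epsMat * sig + betaEp * (sig^2 - 1) / n

    dM3 <- dmu %*% t(w$Wmu) + dlogSigma %*% t(w$Wsig)
    gWmu <- t(fw$M3) %*% dmu
    gWsig <- t(fw$M3) %*% dlogSigma
    dH3 <- Ahat %*% dM3
    dU3 <- dH3 * (fw$U3 > 0)
    gW2 <- t(fw$M2) %*% dU3
    dM2 <- dU3 %*% t(w$W2)
    dH2 <- Ahat %*% dM2
    dU2 <- dH2 * (fw$U2 > 0)
    gW1 <- t(fw$M1) %*% dU2
    dM1 <- dU2 %*% t(w$W1)
    dH1 <- Ahat %*% dM1
    dU1 <- dH1 * (fw$U1 > 0)
    gW0 <- t(fw$M0) %*% dU1

    total <- recon + betaEp * kl +
      if (advWeight > 0) advEp * genLoss else 0
    if (!is.finite(total))
      stop("NaN/Inf loss at epoch ", ep, "; try a smaller learning rate")

    upd <- .adamStep(w, list(W0 = gW0, W1 = gW1, W2 = gW2,
                             Wmu = gWmu, Wsig = gWsig), adam, lr,
                     adamBeta1, adamBeta2)
    w <- upd$params; adam <- upd$state

    hist[[ep]] <- data.frame(epoch = ep, recon = recon, kl = kl,
                             disc = discLoss, gen = genLoss, total = total)
    if (!is.null(evalEdges)) {
      Pmu <- plogis(fw$mu %*% t(fw$mu))
      sc <- c(Pmu[evalEdges$pos], Pmu[evalEdges$neg])
      lb <- rep(c(1, 0), c(nrow(evalEdges$pos), nrow(evalEdges$neg)))
      mhist[[ep]] <- data.frame(epoch = ep,
                                auroc = rocAUC(lb, sc),
                                ap = averagePrecision(lb, sc))
    }
  }

  # final reconstruction from the trained weights; evaluation decodes the
  # posterior mean (sampling is a training-time device), so the reported
  # probability matrix is sigma(mu mu^T). A reparameterized sample with
  # its epsilon draw is kept alongside for generative use.
  fwF <- .vgaeForward(X, Ahat, w)
  epsF <- withStream(modelStream,
                     matrix(rnorm(n * latentDim), n, latentDim))
  zF <- fwF$mu + exp(fwF$logSigma) * epsF
  probs <- plogis(fwF$mu %*% t(fwF$mu))
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(probs) <- list(ids, ids)

  methods::new("CCIFit",
    mu = fwF$mu, logSigma = fwF$logSigma, z = zF, epsilon = epsF,
    probs = probs, weights = w, discWeights = dw,
    lossHistory = do.call(rbind, hist),
    metricHistory = if (is.null(evalEdges)) data.frame()
                    else do.call(rbind, mhist),
    config = list(epochs = epochs, lr = lr, hiddenDims = hiddenDims,
                  latentDim = latentDim, beta = beta,
                  advWeight = advWeight, discHidden = discHidden,
                  warmup = warmup, adamBeta1 = adamBeta1,
                  adamBeta2 = adamBeta2, seed = seed,
                  posWeight = posWeight),
    nodeIds = ids)
}

#' Export a reconstructed network as a ranked edge list
#'
#' @param fit a [CCIFit-class].
#' @param threshold optional probability cutoff; edges below it are
#'   dropped.
#' @return data.frame `node_i`, `node_j`, `probability`, ranked by
#'   decreasing probability (upper triangle only).
#' @export
rankedEdges <- function(fit, threshold = NULL) {
  P <- edgeProbabilities(fit)
  idx <- which(upper.tri(P), arr.ind = TRUE)
  df <- data.frame(node_i = fit@nodeIds[idx[, 1]],
                   node_j = fit@nodeIds[idx[, 2]],
                   probability = P[idx], stringsAsFactors = FALSE)
  df <- df[order(-df$probability), , drop = FALSE]
  if (!is.null(threshold)) df <- df[df$probability >= threshold, ,
                                    drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Save / load a fitted model checkpoint
#'
#' Versioned RDS container holding weights, configuration and latent
#' state.
#'
#' @param fit a [CCIFit-class].
#' @param path checkpoint file.
#' @return `writeCheckpoint` the path invisibly; `readCheckpoint` the
#'   restored [CCIFit-class].
#' @export
writeCheckpoint <- function(fit, path) {
  saveRDS(list(format = "spatialCCI-checkpoint", version = 1L, fit = fit),
          path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "spatialCCI-checkpoint"))
    stop("not a spatialCCI checkpoint: ", path)
  obj$fit
}
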