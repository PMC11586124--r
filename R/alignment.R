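# Multi-slice alignment: entropically regularized Gromov-Wasserstein
# matching between consecutive tissue slices (square loss, Peyre-style
# tensor contraction, log-domain Sinkhorn-Knopp projections), weighted
# Procrustes rigid-transform estimation, and stacking into 3D.

#' Uniform initial matching matrix
#'
#' Every entry `1 / (n * m)`, so both marginals are uniform.
#'
#' @param n,m point counts of the two slices.
#' @return n x m matrix.
#' @export
initMatching <- function(n, m) {
  if (n < 1 || m < 1) stop("'n' and 'm' must be >= 1")
  matrix(1 / (n * m), n, m)
}

#' Gromov-Wasserstein cost of a transport plan
#'
#' `GW(C, P) = sum_{i,j,k,l} (D_X(i,j) - D_Y(k,l))^2 P(i,k) P(j,l)`,
#' evaluated by tensor contraction (exact for any non-negative `P`, not
#' just ones with uniform marginals).
#'
#' @param DX,DY intra-slice distance matrices.
#' @param P transport plan (n x m).
#' @return non-negative scalar.
#' @export
gwCost <- function(DX, DY, P) {
  if (nrow(P) != nrow(DX) || ncol(P) != nrow(DY))
    stop("shape error: P must be nrow(DX) x nrow(DY)")
  r <- rowSums(P)
  cs <- colSums(P)
  drop(t(r) %*% (DX^2) %*% r) + drop(t(cs) %*% (DY^2) %*% cs) -
    2 * sum((DX %*% P %*% DY) * P)
}

.logsumexpRows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}

# Log-domain Sinkhorn projection onto uniform marginals (a = 1/n, b = 1/m)
# for cost matrix C at temperature eps. Stops either on the potential
# change (`tol`) or, when `marginTol` is given, on the worst row-marginal
# violation of the implied plan (columns are exact after every g-update).
.sinkhorn <- function(C, eps, maxIter = 100, tol = 1e-12,
                      f = NULL, g = NULL, marginTol = NULL) {
  n <- nrow(C); m <- ncol(C)
  loga <- -log(n); logb <- -log(m)
  if (is.null(f)) f <- rep(0, n)
  if (is.null(g)) g <- rep(0, m)
  K <- -C / eps
  P <- NULL
  for (it in seq_len(maxIter)) {
    fOld <- f
    # f update: f_i = eps*(loga - logsumexp_j((-C_ij + g_j)/eps))
    f <- eps * (loga - .logsumexpRows(sweep(K, 2, g / eps, "+")))
    g <- eps * (logb - .logsumexpRows(t(K + f / eps)))
    if (!is.null(marginTol) && (it %% 5 == 0 || it == maxIter)) {
      P <- exp(sweep(K + f / eps, 2, g / eps, "+"))
      if (max(abs(rowSums(P) - 1 / n)) < marginTol) break
    } else if (is.null(marginTol) && max(abs(f - fOld)) < tol) break
  }
  if (is.null(P)) P <- exp(sweep(K + f / eps, 2, g / eps, "+"))
  list(P = P, f = f, g = g)
}

#' Entropic Gromov-Wasserstein slice alignment
#'
#' Minimizes the square-loss Gromov-Wasserstein objective between the two
#' intra-slice distance matrices under entropic regularization. Each outer
#' iteration linearizes the objective at the current plan (cost
#' `const - 2 D_X P D_Y`) and projects onto the uniform marginals with
#' log-domain Sinkhorn-Knopp scaling. The temperature is annealed
#' geometrically from `epsilonStart` down to `epsilon`, warm-starting the
#' potentials at every level, which reaches sharp (near-permutation)
#' plans at a small final temperature in few total iterations.
#'
#' Gromov-Wasserstein objectives are non-convex; near-symmetric point
#' clouds have spurious local optima. `nRestarts > 1` additionally runs
#' the annealed solve from seeded perturbed initializations and keeps
#' the plan with the lowest cost.
#'
#' @param DX,DY intra-slice Euclidean distance matrices.
#' @param coordsX,coordsY alternative input: slice coordinates from which
#'   distance matrices are computed.
#' @param epsilon final entropic regularization, as a fraction of the
#'   mean squared distance (default 1e-4).
#' @param epsilonStart initial annealing temperature (same units).
#' @param annealRatio geometric factor between annealing levels.
#' @param nRestarts number of perturbed-initialization solves.
#' @param seed seed for the restart perturbations.
#' @param maxIter maximum total outer iterations per restart.
#' @param tol marginal-constraint tolerance of the returned plan.
#' @return a [SliceAlignment-class] with the plan, Sinkhorn scalers and
#'   the Gromov-Wasserstein cost of the returned plan.
#' @export
alignSlices <- function(DX = NULL, DY = NULL, coordsX = NULL,
                        coordsY = NULL, epsilon = 1e-4,
                        epsilonStart = 0.05, annealRatio = 4,
                        nRestarts = 2, seed = 0, maxIter = 1000,
                        tol = 1e-8) {
  if (is.null(DX)) {
    if (is.null(coordsX) || is.null(coordsY))
      stop("supply either distance matrices or coordinates for both slices")
    DX <- euclideanDistances(coordsX)
    DY <- euclideanDistances(coordsY)
  }
  assertSquareSymmetric(DX, "DX")
  assertSquareSymmetric(DY, "DY")
  n <- nrow(DX); m <- nrow(DY)
  if (n < 2 || m < 2) stop("both slices need at least 2 points")
  if (epsilon <= 0) stop("validation error: 'epsilon' must be positive")

  scale <- mean(c(DX^2, DY^2))
  if (scale == 0) scale <- 1
  a <- rep(1 / n, n); b <- rep(1 / m, m)
  # constant part of the linearized cost at uniform-ish marginals
  cX <- drop((DX^2) %*% a)          # length n
  cY <- drop((DY^2) %*% b)          # length m
  constC <- outer(cX, rep(1, m)) + outer(rep(1, n), cY)

  # geometric annealing schedule down to the requested temperature
  epsStart <- max(epsilon, epsilonStart)
  nLevels <- max(1L, ceiling(log(epsStart / epsilon) / log(annealRatio))
                 + 1L)
  levels <- epsilon * annealRatio^(seq(nLevels - 1L, 0L)) * scale
  levels[1] <- epsStart * scale

  solveFrom <- function(P) {
    f <- NULL; g <- NULL
    converged <- FALSE
    total <- 0L
    cost <- gwCost(DX, DY, P)
    # a level ends when the objective stalls (plan-change criteria stall
    # long before the objective stops improving)
    for (li in seq_along(levels)) {
      eps <- levels[li]
      levelCap <- if (li == length(levels)) 30L else 12L
      converged <- FALSE
      itLevel <- 0L
      nStalled <- 0L
      while (total < maxIter && itLevel < levelCap) {
        total <- total + 1L
        itLevel <- itLevel + 1L
        C <- constC - 2 * (DX %*% P %*% DY)
        sk <- .sinkhorn(C, eps, f = f, g = g, maxIter = 25)
        f <- sk$f; g <- sk$g
        P <- sk$P
        costNew <- gwCost(DX, DY, P)
        if (abs(costNew - cost) < 1e-8 * (1 + abs(cost)))
          nStalled <- nStalled + 1L
        else nStalled <- 0L
        cost <- costNew
        if (itLevel >= 3L && nStalled >= 2L) { converged <- TRUE; break }
      }
    }
    # final tight Sinkhorn projection, then an exact rounding step
    # (scale rows/columns down, repair the deficit with a rank-one
    # correction) so both marginals meet `tol`
    C <- constC - 2 * (DX %*% P %*% DY)
    sk <- .sinkhorn(C, levels[length(levels)], f = f, g = g,
                    maxIter = 500, marginTol = tol)
    P <- sk$P
    P <- P * pmin(1, (1 / n) / rowSums(P))
    P <- t(t(P) * pmin(1, (1 / m) / colSums(P)))
    ea <- pmax(1 / n - rowSums(P), 0)
    eb <- pmax(1 / m - colSums(P), 0)
    if (sum(ea) > 0 && sum(eb) > 0)
      P <- P + outer(ea, eb) / sum(ea)
    list(P = P, f = sk$f, g = sk$g, cost = gwCost(DX, DY, P),
         iterations = total, converged = converged)
  }

  best <- solveFrom(initMatching(n, m))
  if (nRestarts > 1) withSeed(seed, {
    for (r in seq_len(nRestarts - 1L)) {
      P0 <- matrix(runif(n * m, 0.25, 1.75), n, m) / (n * m)
      cand <- solveFrom(P0)
      if (cand$cost < best$cost) best <- cand
    }
  })
  if (!best$converged)
    warning("Gromov-Wasserstein alignment did not converge in ", maxIter,
            " iterations; returning the best iterate")
  eps <- levels[length(levels)]
  methods::new("SliceAlignment", plan = best$P,
               u = exp(best$f / eps), v = exp(best$g / eps),
               gwCost = best$cost,
               iterations = best$iterations, converged = best$converged)
}

#' Weighted Procrustes rigid transform
#'
#' Closed-form least-squares rotation + translation mapping `X` onto `Y`
#' under soft correspondence weights `P` (a transport plan; any
#' non-negative matrix with positive total mass works):
#' minimizes `sum_ik P_ik || R x_i + t - y_k ||^2` via the SVD of the
#' weighted cross-covariance. Reflections are excluded (det(R) = +1)
#' unless `allowReflection`; an optional isotropic scale is available but
#' off by default.
#'
#' @param X,Y point-set coordinate matrices (n x d and m x d, d = 2 or 3).
#' @param P correspondence weights (n x m); identity-like hard pairings
#'   work as 0/1 matrices. Defaults to the identity pairing when `X` and
#'   `Y` have equal row counts.
#' @param allowReflection permit det(R) = -1 solutions.
#' @param scale estimate an isotropic scale factor as well.
#' @return a [RigidTransform-class].
#' @export
procrustesTransform <- function(X, Y, P = NULL, allowReflection = FALSE,
                                scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- ncol(X)
  if (ncol(Y) != d || !(d %in% c(2L, 3L)))
    stop("X and Y must both be n x d with d = 2 or 3")
  if (is.null(P)) {
    if (nrow(X) != nrow(Y))
      stop("default identity pairing needs equal point counts")
    P <- diag(nrow(X)) / nrow(X)
  }
  tot <- sum(P)
  if (tot <= 0) stop("correspondence weights sum to zero")
  wX <- rowSums(P) / tot
  wY <- colSums(P) / tot
  xbar <- drop(t(X) %*% wX)
  ybar <- drop(t(Y) %*% wY)
  Xc <- sweep(X, 2, xbar)
  Yc <- sweep(Y, 2, ybar)
  H <- t(Xc) %*% (P / tot) %*% Yc         # d x d cross-covariance (X -> Y)
  if (max(abs(H)) == 0 && max(abs(Xc)) < 1e-12)
    stop("degenerate input: all points coincide")
  sv <- svd(H)
  S <- diag(d)
  detUV <- det(sv$v %*% t(sv$u))
  if (!allowReflection && detUV < 0) S[d, d] <- -1
  R <- sv$v %*% S %*% t(sv$u)
  s <- 1
  if (scale) {
    varX <- sum((Xc^2) * wX)
    s <- sum(sv$d * diag(S)) / varX
  }
  t <- ybar - s * drop(R %*% xbar)
  methods::new("RigidTransform", rotation = R, translation = t, scale = s)
}

#' Iteratively refine a rigid transform with mutual-nearest-neighbour
#' correspondences
#'
#' Starting from an initial estimate (typically the weighted Procrustes
#' fit of a Gromov-Wasserstein plan), alternates between matching mutual
#' nearest neighbours of the mapped point sets and re-fitting the
#' closed-form Procrustes transform on those hard pairs, until the
#' transform stabilizes. This removes the local bias a soft transport
#' plan inherits from dropout and entropic blur.
#'
#' @param X,Y point sets (n x d, m x d).
#' @param transform initial [RigidTransform-class] mapping X toward Y.
#' @param maxIter maximum refinement iterations.
#' @param tol stop when the maximum point movement between iterations
#'   falls below `tol`.
#' @return refined [RigidTransform-class].
#' @export
refineTransform <- function(X, Y, transform, maxIter = 20, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  prev <- applyTransform(transform, X)
  for (it in seq_len(maxIter)) {
    Xm <- applyTransform(transform, X)
    D <- outer(rowSums(Xm^2), rep(1, nrow(Y))) +
      outer(rep(1, nrow(Xm)), rowSums(Y^2)) - 2 * Xm %*% t(Y)
    nn12 <- max.col(-D, ties.method = "first")
    nn21 <- max.col(-t(D), ties.method = "first")
    mutual <- which(nn21[nn12] == seq_len(nrow(Xm)))
    if (length(mutual) < ncol(X) + 1) break
    P <- matrix(0, nrow(Xm), nrow(Y))
    P[cbind(mutual, nn12[mutual])] <- 1
    transform <- procrustesTransform(X, Y, P,
                                     scale = abs(transform@scale - 1) >
                                       1e-12)
    Xm2 <- applyTransform(transform, X)
    if (max(abs(Xm2 - prev)) < tol) break
    prev <- Xm2
  }
  transform
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param X points (n x d).
#' @return transformed points `scale * R X + t`.
#' @export
applyTransform <- function(transform, X) {
  X <- as.matrix(X)
  sweep(transform@scale * X %*% t(transform@rotation), 2,
        transform@translation, "+")
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first` then `second`.
#'
#' @param second,first [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(second, first) {
  methods::new("RigidTransform",
    rotation = second@rotation %*% first@rotation,
    translation = drop(second@scale * second@rotation %*%
                         first@translation) + second@translation,
    scale = second@scale * first@scale)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rin <- t(transform@rotation)
  methods::new("RigidTransform", rotation = Rin,
    translation = drop(-Rin %*% transform@translation) / transform@scale,
    scale = 1 / transform@scale)
}

#' Stack aligned slices into 3D coordinates
#'
#' Maps every slice into the first slice's 2D frame with the supplied
#' transforms and assigns `z = (slice index - 1) * layerSpacing`.
#'
#' @param slices list of n_s x 2 coordinate matrices (rownames are cell
#'   ids).
#' @param transforms list of [RigidTransform-class], one per slice,
#'   mapping that slice into the first slice's frame (identity for the
#'   first).
#' @param layerSpacing positive distance between consecutive layers.
#' @return list with `coords` (total x 3 matrix) and `layer` (per-cell
#'   slice index).
#' @export
stackSlices <- function(slices, transforms, layerSpacing) {
  if (!is.numeric(layerSpacing) || layerSpacing <= 0)
    stop("validation error: 'layerSpacing' must be positive")
  if (length(slices) != length(transforms))
    stop("one transform per slice is required")
  out <- vector("list", length(slices))
  layer <- integer(0)
  for (s in seq_along(slices)) {
    xy <- applyTransform(transforms[[s]], slices[[s]])
    z <- rep((s - 1) * layerSpacing, nrow(xy))
    M <- cbind(xy, z)
    colnames(M) <- c("x", "y", "z")
    rownames(M) <- rownames(slices[[s]])
    out[[s]] <- M
    layer <- c(layer, rep(s, nrow(xy)))
  }
  list(coords = do.call(rbind, out), layer = layer)
}

#' Write / read a rigid transform as structured text
#'
#' Plain-text container: rotation rows, translation, scale.
#'
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @return `writeTransform` the path invisibly; `readTransform` the
#'   restored object.
#' @export
writeTransform <- function(transform, path) {
  d <- nrow(transform@rotation)
  lines <- c(sprintf("# spatialCCI rigid transform v1 (d=%d)", d),
             apply(transform@rotation, 1, function(r)
               paste(sprintf("%.17g", r), collapse = " ")),
             paste(sprintf("%.17g", transform@translation), collapse = " "),
             sprintf("%.17g", transform@scale))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  lines <- readLines(path)
  d <- as.integer(sub(".*d=(\\d+).*", "\\1", lines[1]))
  vals <- lapply(lines[-1], function(l) as.numeric(strsplit(l, " ")[[1]]))
  R <- do.call(rbind, vals[seq_len(d)])
  methods::new("RigidTransform", rotation = R,
               translation = vals[[d + 1]], scale = vals[[d + 2]])
}

#' Fraction of shared points that are mutual nearest neighbours
#'
#' For two point sets with row names, considers the ids present in both
#' and reports the fraction that are each other's nearest neighbour
#' across the sets — the standard check that aligned counterpart cells
#' actually coincide.
#'
#' @param X,Y coordinate matrices with row names.
#' @return fraction in `[0, 1]`.
#' @export
mutualNNFraction <- function(X, Y) {
  common <- intersect(rownames(X), rownames(Y))
  if (length(common) == 0L) stop("no shared point ids")
  D <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * X %*% t(Y)
  nn12 <- rownames(Y)[max.col(-D, ties.method = "first")]
  names(nn12) <- rownames(X)
  nn21 <- rownames(X)[max.col(-t(D), ties.method = "first")]
  names(nn21) <- rownames(Y)
  mean(nn12[common] == common & nn21[common] == common)
}
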