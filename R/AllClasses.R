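#' @import methods
NULL

#' Ligand-receptor pair database
#'
#' Holds an ordered collection of curated ligand-receptor (L-R) pairs.
#' Multi-subunit complexes are kept as ordered subunit lists per side;
#' the display symbol joins subunits with the configured delimiter.
#' Pairs are unique under the canonical key: species, upper-cased trimmed
#' symbols, subunits sorted within each side, ligand->receptor direction
#' preserved.
#'
#' @slot pairs data.frame with columns `ligand`, `receptor`, `species`,
#'   `source`, `key` and list-columns `ligandSubunits`, `receptorSubunits`.
#' @slot delimiter subunit delimiter used for display symbols.
#' @export
setClass("LRDatabase",
  representation(pairs = "data.frame", delimiter = "character"),
  prototype(pairs = data.frame(), delimiter = "_")
)

setValidity("LRDatabase", function(object) {
  p <- object@pairs
  if (nrow(p) == 0L) return(TRUE)
  need <- c("ligand", "receptor", "species", "source", "key",
            "ligandSubunits", "receptorSubunits")
  if (!all(need %in% names(p)))
    return(paste("pairs is missing columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (any(!nzchar(p$ligand)) || any(!nzchar(p$receptor)))
    return("empty ligand or receptor symbol")
  subs <- c(unlist(p$ligandSubunits), unlist(p$receptorSubunits))
  if (any(!nzchar(subs))) return("empty complex subunit symbol")
  if (!all(p$species %in% c("human", "mouse")))
    return("species must be 'human' or 'mouse'")
  if (anyDuplicated(p$key))
    return("duplicate pairs under the canonical key")
  TRUE
})

#' Fitted variational graph autoencoder
#'
#' Result container returned by [trainVGAE()]: latent Gaussian parameters
#' per node, the sampled latent coordinates, reconstructed edge
#' probabilities, trained weights and the per-epoch loss history.
#'
#' @slot mu,logSigma,z,epsilon n x d latent matrices (mean, log standard
#'   deviation, reparameterized sample, and the standard-normal draw used).
#' @slot probs n x n reconstructed edge-probability matrix (inner-product
#'   decoder through the logistic function).
#' @slot weights encoder/decoder weight matrices.
#' @slot discWeights adversarial discriminator weights.
#' @slot lossHistory data.frame, one row per epoch.
#' @slot metricHistory data.frame of per-epoch held-out AUROC/AP (possibly
#'   empty).
#' @slot config training configuration snapshot.
#' @slot nodeIds node labels.
#' @export
setClass("CCIFit",
  representation(mu = "matrix", logSigma = "matrix", z = "matrix",
                 epsilon = "matrix", probs = "matrix", weights = "list",
                 discWeights = "list", lossHistory = "data.frame",
                 metricHistory = "data.frame", config = "list",
                 nodeIds = "character")
)

setValidity("CCIFit", function(object) {
  if (!identical(dim(object@mu), dim(object@logSigma)))
    return("mu and logSigma dimensions differ")
  if (!identical(dim(object@mu), dim(object@z)))
    return("z dimensions differ from mu")
  if (nrow(object@probs) != ncol(object@probs))
    return("probs must be square")
  if (nrow(object@probs) != nrow(object@mu))
    return("probs dimension differs from node count")
  TRUE
})

#' Rigid transform between two point sets
#'
#' @slot rotation d x d rotation matrix (orthonormal, det +1 unless
#'   reflections were explicitly allowed).
#' @slot translation length-d translation vector.
#' @slot scale isotropic scale factor (1 unless scaling was requested).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 scale = "numeric"),
  prototype(scale = 1)
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  d <- nrow(R)
  if (ncol(R) != d) return("rotation must be square")
  if (length(object@translation) != d)
    return("translation length must match rotation dimension")
  if (max(abs(crossprod(R) - diag(d))) > 1e-6)
    return("rotation is not orthonormal")
  TRUE
})

#' Gromov-Wasserstein slice alignment
#'
#' @slot plan n x m transport plan with (near-)uniform marginals.
#' @slot u,v final Sinkhorn scaling vectors (log-domain potentials are
#'   exponentiated).
#' @slot gwCost Gromov-Wasserstein cost of the returned plan.
#' @slot iterations outer iterations performed.
#' @slot converged whether the plan change dropped below tolerance.
#' @export
setClass("SliceAlignment",
  representation(plan = "matrix", u = "numeric", v = "numeric",
                 gwCost = "numeric", iterations = "integer",
                 converged = "logical")
)

setValidity("SliceAlignment", function(object) {
  if (any(object@plan < 0)) return("transport plan has negative entries")
  if (length(object@u) != nrow(object@plan) ||
      length(object@v) != ncol(object@plan))
    return("scaling vector lengths do not match the plan")
  if (object@gwCost < -1e-12) return("gwCost must be non-negative")
  TRUE
})

#' Seed-replicated evaluation report
#'
#' Tabular report in the per-seed layout: one row per (condition, seed)
#' with ACC / AUROC / AP, plus per-condition arithmetic-mean average rows.
#' Full precision is retained; `show()` rounds to 3 decimals for display.
#'
#' @slot rows data.frame with columns `condition`, `seed`, `acc`, `auroc`,
#'   `ap`.
#' @slot averages data.frame with columns `condition`, `acc`, `auroc`, `ap`.
#' @slot metadata configuration snapshot.
#' @export
setClass("EvalReport",
  representation(rows = "data.frame", averages = "data.frame",
                 metadata = "list"),
  prototype(metadata = list())
)

setValidity("EvalReport", function(object) {
  need <- c("condition", "seed", "acc", "auroc", "ap")
  if (!all(need %in% names(object@rows)))
    return("rows must have condition, seed, acc, auroc, ap")
  for (cond in unique(object@rows$condition)) {
    sub <- object@rows[object@rows$condition == cond, ]
    avg <- object@averages[object@averages$condition == cond, ]
    if (nrow(avg) != 1L) return("exactly one average row per condition")
    for (m in c("acc", "auroc", "ap")) {
      if (abs(mean(sub[[m]]) - avg[[m]]) > 1e-12)
        return(sprintf("average of %s for condition '%s' is not the mean",
                       m, cond))
    }
  }
  TRUE
})

#' Synthetic tissue fixture
#'
#' A seeded synthetic tissue: spatially clustered cell communities,
#' community-driven low-rank expression, and the ground-truth symmetrized
#' kNN adjacency derived from the coordinates. Internal consistency
#' (adjacency equals the kNN graph of the coordinates at the recorded
#' neighbourhood size) is asserted at construction.
#'
#' @slot coords n x 2 coordinate matrix, rownames are cell ids.
#' @slot expression n x g expression matrix (cells x genes).
#' @slot adjacency n x n binary symmetric ground-truth CCI graph.
#' @slot communities integer community label per cell.
#' @slot config generator parameters including the seed.
#' @export
setClass("TissueFixture",
  representation(coords = "matrix", expression = "matrix",
                 adjacency = "matrix", communities = "integer",
                 config = "list")
)

setValidity("TissueFixture", function(object) {
  n <- nrow(object@coords)
  if (nrow(object@expression) != n) return("expression row count mismatch")
  if (!all(dim(object@adjacency) == n)) return("adjacency dimension mismatch")
  if (length(object@communities) != n) return("communities length mismatch")
  if (!all(is.finite(object@expression))) return("non-finite expression")
  k <- object@config$nNeighbors
  if (!is.null(k)) {
    A <- knnAdjacency(euclideanDistances(object@coords), k)
    if (!identical(unname(A), unname(object@adjacency)))
      return("adjacency is not the kNN graph of the coordinates")
  }
  TRUE
})
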