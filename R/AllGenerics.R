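#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lrPairs", function(object) standardGeneric("lrPairs"))

#' @rdname accessors
#' @export
setGeneric("speciesCounts", function(object) standardGeneric("speciesCounts"))

#' @rdname accessors
#' @export
setGeneric("latentMeans", function(object) standardGeneric("latentMeans"))

#' @rdname accessors
#' @export
setGeneric("latentLogSd", function(object) standardGeneric("latentLogSd"))

#' @rdname accessors
#' @export
setGeneric("edgeProbabilities",
           function(object) standardGeneric("edgeProbabilities"))

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname accessors
#' @export
setGeneric("transportPlan", function(object) standardGeneric("transportPlan"))

#' @rdname accessors
#' @export
setGeneric("alignmentCost", function(object) standardGeneric("alignmentCost"))

#' @rdname accessors
#' @export
setGeneric("reportRows", function(object) standardGeneric("reportRows"))

#' @rdname accessors
#' @export
setGeneric("reportAverages",
           function(object) standardGeneric("reportAverages"))

#' @rdname accessors
#' @export
setMethod("lrPairs", "LRDatabase", function(object) object@pairs)

#' @rdname accessors
#' @export
setMethod("speciesCounts", "LRDatabase", function(object) {
  if (nrow(object@pairs) == 0L)
    return(c(human = 0L, mouse = 0L))
  tab <- table(factor(object@pairs$species, levels = c("human", "mouse")))
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname accessors
#' @export
setMethod("length", "LRDatabase", function(x) nrow(x@pairs))

#' @rdname accessors
#' @export
setMethod("latentMeans", "CCIFit", function(object) object@mu)

#' @rdname accessors
#' @export
setMethod("latentLogSd", "CCIFit", function(object) object@logSigma)

#' @rdname accessors
#' @export
setMethod("edgeProbabilities", "CCIFit", function(object) object@probs)

#' @rdname accessors
#' @export
setMethod("lossHistory", "CCIFit", function(object) object@lossHistory)

#' @rdname accessors
#' @export
setMethod("transportPlan", "SliceAlignment", function(object) object@plan)

#' @rdname accessors
#' @export
setMethod("alignmentCost", "SliceAlignment", function(object) object@gwCost)

#' @rdname accessors
#' @export
setMethod("reportRows", "EvalReport", function(object) object@rows)

#' @rdname accessors
#' @export
setMethod("reportAverages", "EvalReport", function(object) object@averages)

setMethod("show", "LRDatabase", function(object) {
  sc <- speciesCounts(object)
  cat("LRDatabase with", nrow(object@pairs), "ligand-receptor pairs\n")
  cat("  species:", paste(sprintf("%s = %d", names(sc), sc),
                          collapse = ", "), "\n")
  ncx <- sum(vapply(object@pairs$ligandSubunits, length, 1L) > 1L |
             vapply(object@pairs$receptorSubunits, length, 1L) > 1L)
  cat("  multi-subunit complexes:", ncx, "\n")
})

setMethod("show", "CCIFit", function(object) {
  cat("CCIFit:", nrow(object@mu), "nodes, latent dim", ncol(object@mu), "\n")
  h <- object@lossHistory
  if (nrow(h) > 0L)
    cat(sprintf("  trained %d epochs; total loss %.4f -> %.4f\n",
                nrow(h), h$total[1], h$total[nrow(h)]))
})

setMethod("show", "SliceAlignment", function(object) {
  cat(sprintf("SliceAlignment: %d x %d plan, GW cost %.6g (%s in %d iter)\n",
              nrow(object@plan), ncol(object@plan), object@gwCost,
              if (object@converged) "converged" else "not converged",
              object@iterations))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- if (nrow(object@rotation) == 2L)
    sprintf(" (%.2f deg)", atan2(object@rotation[2, 1],
                                 object@rotation[1, 1]) * 180 / pi)
  else ""
  cat("RigidTransform in", nrow(object@rotation), "dimensions", ang, "\n")
  cat("  translation:", paste(signif(object@translation, 4),
                              collapse = ", "), "\n")
  if (abs(object@scale - 1) > 1e-12)
    cat("  scale:", signif(object@scale, 6), "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", nrow(object@rows), "rows,",
      nrow(object@averages), "condition averages\n")
  disp <- object@averages
  for (m in c("acc", "auroc", "ap")) disp[[m]] <- round(disp[[m]], 3)
  print(disp, row.names = FALSE)
})

setMethod("show", "TissueFixture", function(object) {
  cat("TissueFixture:", nrow(object@coords), "cells,",
      ncol(object@expression), "genes,",
      length(unique(object@communities)), "communities\n")
  cat("  edges:", sum(object@adjacency) / 2, " (kNN, n =",
      object@config$nNeighbors, ")\n")
})

#' @rdname accessors
#' @export
setGeneric("tissueCoords", function(object) standardGeneric("tissueCoords"))

#' @rdname accessors
#' @export
setGeneric("tissueExpression",
           function(object) standardGeneric("tissueExpression"))

#' @rdname accessors
#' @export
setGeneric("tissueAdjacency",
           function(object) standardGeneric("tissueAdjacency"))

#' @rdname accessors
#' @export
setGeneric("tissueCommunities",
           function(object) standardGeneric("tissueCommunities"))

#' @rdname accessors
#' @export
setMethod("tissueCoords", "TissueFixture", function(object) object@coords)

#' @rdname accessors
#' @export
setMethod("tissueExpression", "TissueFixture",
          function(object) object@expression)

#' @rdname accessors
#' @export
setMethod("tissueAdjacency", "TissueFixture",
          function(object) object@adjacency)

#' @rdname accessors
#' @export
setMethod("tissueCommunities", "TissueFixture",
          function(object) object@communities)
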