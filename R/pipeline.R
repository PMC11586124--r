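# Pipeline orchestration: a single entry point wiring
# preprocess -> graph -> train -> reconstruct -> align -> 3D network ->
# evaluate from a configuration list or YAML file, writing a
# deterministic artifact set plus a manifest.

.defaultConfig <- function() {
  list(
    seed = 1,
    outDir = "spatialCCI_run",
    nNeighbors = 6,
    layerSpacing = 10,
    train = list(epochs = 30, lr = 0.01, hiddenDims = c(64, 64, 32),
                 latentDim = 32, beta = 1, advWeight = 1,
                 discHidden = 64),
    fixture = NULL,       # list(nCells, nGenes, ...) -> simulateTissue
    expressionFile = NULL,
    coordsFile = NULL,
    slices = NULL,        # list of coordinate CSV paths for 3D mode
    evaluate = list(maskFraction = 0.1)
  )
}

.mergeConfig <- function(base, user) {
  known <- names(base)
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- utils::modifyList(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Read a pipeline configuration
#'
#' @param path YAML file with any subset of the configuration keys;
#'   unknown keys are rejected.
#' @return validated configuration list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  .mergeConfig(.defaultConfig(), yaml::read_yaml(path))
}

#' Run the reconstruction pipeline
#'
#' Loads (or simulates) expression and coordinates, filters and
#' standardizes the expression, builds the symmetrized kNN graph, trains
#' the variational graph autoencoder, scores held-out edges, and — when
#' several slices are configured — aligns them, stacks 3D coordinates and
#' exports the inter-layer edge list. All outputs are deterministic for a
#' fixed configuration and seed.
#'
#' @param config configuration list (see [readRunConfig()]) or a path to
#'   a YAML file.
#' @return invisibly, a list with the artifact paths (`manifest` included)
#'   and the in-memory results (`fit`, `report`, `stacked`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  else config <- .mergeConfig(.defaultConfig(), config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$fixture)) {
    fx <- do.call(simulateTissue,
                  c(config$fixture,
                    list(nNeighbors = config$nNeighbors,
                         seed = config$seed)))
    X <- tissueExpression(fx)
    coords <- tissueCoords(fx)
  } else {
    if (is.null(config$expressionFile) || is.null(config$coordsFile))
      stop("config error: need 'fixture' or both 'expressionFile' and ",
           "'coordsFile'")
    if (!file.exists(config$expressionFile))
      stop("config error: expression file not found: ",
           config$expressionFile)
    if (!file.exists(config$coordsFile))
      stop("config error: coordinates file not found: ", config$coordsFile)
    X <- readExpression(config$expressionFile)
    ctab <- utils::read.csv(config$coordsFile, stringsAsFactors = FALSE)
    coords <- as.matrix(ctab[, c("x", "y")])
    rownames(coords) <- ctab$cell_id
    X <- X[rownames(coords), , drop = FALSE]
  }

  # --- preprocess + graph --------------------------------------------
  X <- standardizeExpression(filterAllZero(X))
  A <- knnAdjacency(euclideanDistances(coords), config$nNeighbors)

  # --- train + evaluate ----------------------------------------------
  res <- .maskedRecoveryRun(X, A, config$evaluate$maskFraction,
                            config$seed, trainConfig = config$train)
  fit <- res$fit
  report <- seedReport(
    data.frame(condition = sprintf("mask=%g", config$evaluate$maskFraction),
               seed = config$seed, acc = res$acc, auroc = res$auroc,
               ap = res$ap, stringsAsFactors = FALSE),
    metadata = list(config = config))

  utils::write.csv(data.frame(cell_id = fit@nodeIds, latentMeans(fit)),
                   out("latent_means.csv"), row.names = FALSE)
  write.table(rankedEdges(fit), out("reconstructed_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(lossHistory(fit), out("loss_history.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeReport(report, out("report.tsv"))

  # --- optional 3D mode ----------------------------------------------
  stacked <- NULL
  if (!is.null(config$slices)) {
    slices <- lapply(config$slices, function(p) {
      tab <- utils::read.csv(p, stringsAsFactors = FALSE)
      m <- as.matrix(tab[, c("x", "y")])
      rownames(m) <- tab$cell_id
      m
    })
    transforms <- vector("list", length(slices))
    transforms[[1]] <- methods::new("RigidTransform", rotation = diag(2),
                                    translation = c(0, 0), scale = 1)
    for (s in seq_along(slices)[-1]) {
      al <- alignSlices(coordsX = slices[[s]], coordsY = slices[[s - 1]])
      rel <- procrustesTransform(slices[[s]], slices[[s - 1]],
                                 transportPlan(al))
      rel <- refineTransform(slices[[s]], slices[[s - 1]], rel)
      transforms[[s]] <- composeTransforms(transforms[[s - 1]], rel)
    }
    stacked <- stackSlices(slices, transforms, config$layerSpacing)
    utils::write.csv(
      data.frame(cell_id = rownames(stacked$coords), stacked$coords,
                 layer = stacked$layer),
      out("stacked_coords.csv"), row.names = FALSE)
    g3 <- crossLayerGraph(stacked$coords, stacked$layer,
                          config$nNeighbors)
    write.table(interLayerEdges(g3), out("inter_layer_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- manifest -------------------------------------------------------
  files <- setdiff(list.files(config$outDir), "manifest.json")
  manifest <- list(
    package = "spatialCCI",
    version = as.character(utils::packageVersion("spatialCCI")),
    seed = config$seed,
    files = as.list(tools::md5sum(file.path(config$outDir,
                                            sort(files)))))
  names(manifest$files) <- sort(files)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             out("manifest.json"))

  invisible(list(outDir = config$outDir, manifest = out("manifest.json"),
                 fit = fit, report = report, stacked = stacked))
}
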