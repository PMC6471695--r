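#' Generate a resolution-labelled synthetic corpus
#'
#' Simulates \code{nPerClass} distinct seeded synthetic structures, renders
#' every structure at every training resolution (the published corpus
#' construction: each selected structure is simulated at 2.5, 7.5 and
#' 12.5 A, tripling the structure count), min-max normalizes the maps and
#' stacks them with their three-class labels.
#'
#' @param nPerClass maps per resolution class.
#' @param resolutions training resolutions in Angstrom.
#' @param box cubic box edge in voxels.
#' @param voxelSize Angstrom/voxel.
#' @param nAtoms atoms per synthetic structure.
#' @param seed base seed; each map's structure uses its own derived seed.
#' @return list: \code{X} rank-4 array (N, box, box, box) of normalized
#'   maps, \code{y} integer three-class labels, \code{resolution} per map,
#'   \code{id} per map.
#' @export
makeResolutionCorpus <- function(nPerClass, resolutions = c(2.5, 7.5, 12.5),
                                 box = 32, voxelSize = 1, nAtoms = 250,
                                 seed = 1) {
  n <- nPerClass * length(resolutions)
  X <- array(0, c(n, box, box, box))
  y <- integer(n)
  res <- numeric(n)
  id <- character(n)
  j <- 0L
  for (i in seq_len(nPerClass)) {
    struct <- makeSyntheticModel(nAtoms, extent = 0.6 * box * voxelSize,
                                 seed = seed + i)
    for (k in seq_along(resolutions)) {
      j <- j + 1L
      m <- suppressWarnings(
        simulateMap(struct, resolutions[k], box = box,
                    voxelSize = voxelSize))
      X[j, , , ] <- mapData(minMaxNormalize(m))
      y[j] <- threeClassLabel(resolutions[k])
      res[j] <- resolutions[k]
      id[j] <- sprintf("sim_%03d_R%.1f", i, resolutions[k])
    }
  }
  list(X = X, y = y, resolution = res, id = id)
}

#' Build a patch repository from local-resolution phantoms
#'
#' Generates seeded phantoms, min-max normalizes each map, partitions map
#' and label volume into 16^3 cubes with empty-cube removal, and pools the
#' retained cubes — the feed for voxel-wise training.
#'
#' @param nPhantoms number of phantoms.
#' @param resolutions region resolutions passed to
#'   [makeLocalResPhantom()].
#' @param layout region layout ("slabs" or "spheres").
#' @param box phantom box edge (default 32).
#' @param cube patch edge (default 16).
#' @param seed base seed.
#' @param background label sentinel.
#' @return list: \code{inputs} and \code{labels} rank-4 arrays,
#'   \code{phantom} index per cube.
#' @export
makePhantomPatchSet <- function(nPhantoms, resolutions = c(2.5, 12.5),
                                layout = "slabs", box = 32, cube = 16,
                                seed = 1, background = -1) {
  inputs <- list(); labels <- list(); from <- integer(0)
  for (p in seq_len(nPhantoms)) {
    ph <- makeLocalResPhantom(resolutions, layout = layout, box = box,
                              seed = seed + p, background = background)
    nm <- minMaxNormalize(ph@map)
    batch <- partitionPatches(nm, ph@voxelLabels, cube = cube,
                              background = background)
    if (dim(patchInputs(batch))[1] == 0L) next
    inputs[[length(inputs) + 1L]] <- patchInputs(batch)
    labels[[length(labels) + 1L]] <- patchLabels(batch)
    from <- c(from, rep(p, dim(patchInputs(batch))[1]))
  }
  list(inputs = do.call(abind4, inputs), labels = do.call(abind4, labels),
       phantom = from)
}

# bind rank-4 arrays along the first axis
abind4 <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) length(p) > 0, TRUE)]
  if (length(parts) == 1L) return(parts[[1L]])
  d <- dim(parts[[1L]])[2:4]
  n <- sum(vapply(parts, function(p) dim(p)[1], 0))
  out <- array(0, c(n, d))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    out[at + seq_len(np), , , ] <- p
    at <- at + np
  }
  out
}

validatePipelineConfig <- function(config) {
  need <- c("outDir", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0)
    stop("pipeline config is missing field(s): ", paste(miss, collapse = ", "))
  for (f in c("pdbFile", "mapFile"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("configured input path does not exist: ", config[[f]])
  invisible(TRUE)
}

#' Default demo pipeline configuration
#'
#' A no-download end-to-end configuration: synthetic three-class corpus
#' (30 maps per class, 32^3 box at 1 A/voxel, 2.5/7.5/12.5 A), 60/20/20
#' split, a desk-scale dense classifier, and full metric reports. Runs in
#' minutes on one CPU.
#'
#' @param outDir run directory.
#' @param seed integer seed for every stage.
#' @return config list for [runPipeline()].
#' @export
demoRunConfig <- function(outDir = tempfile("cryores_run_"), seed = 1) {
  list(outDir = outDir, seed = seed, nPerClass = 30, box = 32,
       resolutions = c(2.5, 7.5, 12.5), architecture = "dnn",
       hidden = c(256, 64), ratios = c(0.6, 0.2, 0.2),
       learningRate = 0.01, batchSize = 32, maxEpochs = 12, patience = 12)
}

#' Run the full pipeline: simulate, preprocess, split, train, evaluate
#'
#' Executes the linear workflow on a synthetic corpus and writes a
#' deterministic artifact tree under \code{config$outDir}: the corpus and
#' split (\code{corpus.rds}, \code{split.rds}), the trained model and its
#' trace (\code{model.rds}, \code{trace.csv}), per-map test predictions
#' (\code{predictions.csv}) and the metric report (\code{metrics.json},
#' \code{confusion.csv}). Completed stages are detected by their artifacts
#' and reused, so interrupted runs resume; two runs with the same config
#' and seed produce identical reports.
#'
#' @param config list as produced by [demoRunConfig()].
#' @param verbose print stage progress.
#' @return (invisibly) list with the confusion matrix, metrics and paths.
#' @export
runPipeline <- function(config = demoRunConfig(), verbose = TRUE) {
  validatePipelineConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[cryores] ", ...)
  art <- function(f) file.path(config$outDir, f)
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), art("config.json"))

  # stage 1+2: simulate + normalize
  if (file.exists(art("corpus.rds"))) {
    say("corpus.rds present; reusing")
    corpus <- readRDS(art("corpus.rds"))
  } else {
    say("simulating ", config$nPerClass, " maps/class at ",
        paste(config$resolutions, collapse = "/"), " A")
    corpus <- makeResolutionCorpus(config$nPerClass, config$resolutions,
                                   box = config$box, seed = config$seed)
    saveRDS(corpus, art("corpus.rds"))
  }

  # stage 3: split
  if (file.exists(art("split.rds"))) {
    split <- readRDS(art("split.rds"))
  } else {
    split <- splitDataset(seq_along(corpus$y), config$ratios,
                          seed = config$seed)
    saveRDS(split, art("split.rds"))
  }

  # stage 4: train
  `%||%` <- function(a, b) if (is.null(a)) b else a
  spec <- switch(config$architecture,
    dnn = buildDNN(config$box, hidden = config$hidden %||% c(256, 64)),
    cnn3d = buildCNN3D(config$box,
                       filters = config$filters %||% c(8, 16, 32),
                       denseUnits = config$denseUnits %||% 256),
    stop("pipeline supports the global classifiers (dnn, cnn3d)"))
  if (file.exists(art("model.rds"))) {
    say("model.rds present; reusing")
    model <- readRDS(art("model.rds"))
  } else {
    say("training ", config$architecture, " for up to ",
        config$maxEpochs, " epochs")
    model <- trainNetwork(spec,
      corpus$X[split$train, , , , drop = FALSE], corpus$y[split$train],
      corpus$X[split$validation, , , , drop = FALSE],
      corpus$y[split$validation],
      TrainConfig(learningRate = config$learningRate,
                  batchSize = config$batchSize,
                  maxEpochs = config$maxEpochs, patience = config$patience,
                  seed = config$seed))
    saveRDS(model, art("model.rds"))
    utils::write.csv(model@trace, art("trace.csv"), row.names = FALSE)
  }

  # stage 5: predict + evaluate on the held-out test set
  pred <- predictNetwork(model, corpus$X[split$test, , , , drop = FALSE])
  utils::write.csv(
    data.frame(id = corpus$id[split$test], truth = corpus$y[split$test],
               predicted = pred),
    art("predictions.csv"), row.names = FALSE)
  cm <- confusionMatrix3(corpus$y[split$test], pred)
  utils::write.csv(cmCounts(cm), art("confusion.csv"))
  metrics <- list(
    combined_agreement_pct = combinedAgreement(cm),
    test_accuracy = mean(pred == corpus$y[split$test]),
    class_metrics = classMetrics(cm),
    best_epoch = model@bestEpoch,
    n_test = length(split$test))
  writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, pretty = TRUE,
                              digits = 10, dataframe = "columns"),
             art("metrics.json"))
  say("combined agreement ", metrics$combined_agreement_pct, "% on ",
      metrics$n_test, " test maps")
  invisible(list(confusion = cm, metrics = metrics, dir = config$outDir))
}
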