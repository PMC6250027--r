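# End-to-end orchestration: generate/load scenes, preprocess, segment,
# refine, resolve overlaps, extract features, select, classify, evaluate.

#' Default pipeline configuration
#'
#' A nested list mirroring each stage's parameters; see the YAML written
#' by [writePipelineConfig()] for the file form. Unknown keys in a config
#' file are rejected by [readPipelineConfig()].
#'
#' @return named list of stage sections.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    scenes = list(nImages = 4, width = 512, height = 512, nNuclei = 18,
                  overlapFraction = 0.2, malignantFraction = 0.25),
    preprocess = list(width = NULL, height = NULL, lowPct = 1,
                      highPct = 99, kernel = 3),
    segment = list(nSuperpixels = 500, compactness = 10, k = 2),
    postprocess = list(openingRadii = 7:15, minArea = 50),
    overlap = list(gate = TRUE),
    features = list(minArea = 15),
    select = list(enabled = FALSE, nf = 20, maxIt = 50, temp0 = 10,
                  alpha = 0.99, hiddenUnits = 10, nRepeats = 3),
    classify = list(nTrees = 100, nFolds = 5, trainFraction = 0.8)
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML is merged over [defaultPipelineConfig()]; unknown sections or keys
#' raise an error naming the offender.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  usr <- yaml::read_yaml(path)
  def <- defaultPipelineConfig()
  bad <- setdiff(names(usr), names(def))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(usr)) {
    if (!is.list(def[[sec]])) {
      def[[sec]] <- usr[[sec]]
      next
    }
    badKey <- setdiff(names(usr[[sec]]), names(def[[sec]]))
    if (length(badKey)) stop("unknown key(s) in section '", sec, "': ",
                             paste(badKey, collapse = ", "))
    def[[sec]][names(usr[[sec]])] <- usr[[sec]]
  }
  def
}

#' @rdname readPipelineConfig
#' @param config configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Segment one image into labelled nuclei
#'
#' Convenience stage runner: preprocess (optional resize), hybrid
#' SLIC/K-Means segmentation, multiscale morphological refinement, and
#' SVM-gated overlap resolution.
#'
#' @param img RGB array in `[0, 255]`.
#' @param config pipeline configuration (see [defaultPipelineConfig()]).
#' @param model overlap gate; `NULL` trains the default surrogate.
#' @param seed RNG seed for the clustering stage.
#' @return integer instance mask with the `nuclei` attribute of
#'   [resolveOverlaps()].
#' @export
segmentImage <- function(img, config = defaultPipelineConfig(),
                         model = NULL, seed = config$seed) {
  pp <- config$preprocess
  w <- pp$width %||% dim(img)[1]
  h <- pp$height %||% dim(img)[2]
  img <- preprocessImage(img, w, h, pp$lowPct, pp$highPct, pp$kernel)
  sg <- config$segment
  mask <- segmentNuclei(img, sg$nSuperpixels, sg$compactness, sg$k, seed)
  mask <- refineMultiscale(mask, config$postprocess$openingRadii,
                           config$postprocess$minArea)
  resolveOverlaps(mask, model = model, gate = isTRUE(config$overlap$gate))
}

# majority-overlap match of predicted nuclei to ground-truth classes
matchLabels <- function(predMask, truthMask, truthClasses) {
  ids <- sort(unique(as.integer(predMask[predMask > 0])))
  out <- character(max(c(ids, 0)))
  for (id in ids) {
    t <- truthMask[predMask == id]
    t <- t[t > 0]
    out[id] <- if (!length(t)) "benign" else
      as.character(truthClasses[as.integer(names(which.max(table(t))))])
  }
  out
}

#' Run the full pipeline on synthetic scenes
#'
#' Generates `nImages` scenes, segments each one, extracts per-nucleus
#' features (labelled by majority overlap with the ground truth), splits
#' the images 80/20 into disjoint train/test sets (no image contributes to
#' both), optionally runs annealing feature selection on the training
#' rows, trains the bagged ensemble with cross-validation, predicts the
#' held-out images and reports confusion metrics. All artefacts (scenes,
#' masks, feature tables, predictions, metrics, manifest) are written to
#' `outDir`.
#'
#' @param config configuration list from [defaultPipelineConfig()] /
#'   [readPipelineConfig()].
#' @param outDir run directory to create.
#' @return invisibly, a list with the feature table, model, test metrics
#'   and the run directory.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outDir = tempfile("pleuracad_run_")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  sc <- config$scenes
  gateModel <- defaultOverlapModel(seed)

  tabs <- list()
  for (i in seq_len(sc$nImages)) {
    spec <- SceneSpec(width = sc$width, height = sc$height,
                      nNuclei = sc$nNuclei,
                      overlapFraction = sc$overlapFraction,
                      malignantFraction = sc$malignantFraction,
                      seed = seed + i)
    scene <- generateScene(spec)
    writeScene(scene, file.path(outDir, "scenes"), sprintf("scene_%03d", i))
    pred <- segmentImage(scene@image, config, model = gateModel,
                         seed = seed + i)
    writeMask(pred, file.path(outDir, "scenes",
                              sprintf("scene_%03d_pred.tiff", i)))
    truthClasses <- stats::setNames(scene@nuclei$class, scene@nuclei$id)
    lab <- matchLabels(pred, scene@mask,
                       scene@nuclei$class[order(scene@nuclei$id)])
    tab <- extractFeatures(scene@image, pred, labels = lab,
                           minArea = config$features$minArea)
    if (nrow(tab)) tab$image <- i
    tabs[[i]] <- tab
  }
  feat <- do.call(rbind, tabs)
  utils::write.csv(feat, file.path(outDir, "features.csv"),
                   row.names = FALSE)

  # image-level 80/20 split, disjoint
  nImg <- sc$nImages
  nTrain <- max(1, round(config$classify$trainFraction * nImg))
  trainImgs <- withr::with_seed(seed, sample.int(nImg, nTrain))
  trainTab <- feat[feat$image %in% trainImgs, ]
  testTab <- feat[!feat$image %in% trainImgs, ]

  codes <- grep("^F[0-9]+$", names(feat), value = TRUE)
  if (isTRUE(config$select$enabled) &&
      nlevels(droplevels(trainTab$label)) == 2) {
    ss <- config$select
    sub <- annealFeatures(trainTab, nf = ss$nf, maxIt = ss$maxIt,
                          temp0 = ss$temp0, alpha = ss$alpha,
                          hiddenUnits = ss$hiddenUnits,
                          nRepeats = ss$nRepeats, seed = seed)
    codes <- selectedFeatures(sub)
    utils::write.csv(data.frame(code = codes),
                     file.path(outDir, "selected_features.csv"),
                     row.names = FALSE)
  }

  model <- trainECBDT(trainTab, selected = codes,
                      nTrees = config$classify$nTrees,
                      nFolds = config$classify$nFolds, seed = seed)
  result <- list(features = feat, model = model, runDir = outDir)
  if (nrow(testTab)) {
    pred <- predict(model, testTab)
    counts <- confusionCounts(testTab$label, pred)
    metrics <- suppressWarnings(computeMetrics(counts))
    utils::write.csv(cbind(testTab[c("image", "id", "label")],
                           predicted = pred),
                     file.path(outDir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(counts = as.list(counts),
                              metrics = as.list(metrics)),
                         file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    result$metrics <- metrics
    result$counts <- counts
  }
  cfgPath <- file.path(outDir, "config.yaml")
  writePipelineConfig(config, cfgPath)
  manifest <- list(configHash = unname(tools::md5sum(cfgPath)),
                   seed = seed, nImages = nImg,
                   trainImages = sort(trainImgs),
                   nNucleiDetected = nrow(feat))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(result)
}
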