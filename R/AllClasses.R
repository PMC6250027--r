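#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib PleuraCAD, .registration = TRUE
NULL

#' Parameters of a synthetic CPE scene
#'
#' A `SceneSpec` holds everything needed to render a synthetic cytological
#' pleural effusion (CPE) scene: canvas size, nucleus counts, the fraction of
#' nuclei placed in touching pairs, the benign/malignant mix, and the optical
#' contrasts (size, darkness, chromatin texture) that separate the two
#' classes. Identical specs (including `seed`) render byte-identical scenes.
#'
#' @slot width,height canvas size in pixels.
#' @slot nNuclei number of nuclei to place.
#' @slot overlapFraction fraction of nuclei placed in touching pairs, in
#'   `[0, 1]`.
#' @slot malignantFraction fraction of malignant nuclei, in `[0, 1]`.
#' @slot radiusRangeBenign,radiusRangeMalignant mean-radius intervals
#'   (pixels) for the two classes.
#' @slot darknessContrast difference in mean intensity (8-bit units) between
#'   benign and malignant nuclei; malignant nuclei are darker.
#' @slot chromatinNoiseSigma length-2 numeric, per-class chromatin noise
#'   scale (benign, malignant) in 8-bit units.
#' @slot impulseNoiseDensity salt-and-pepper density in `[0, 1]`.
#' @slot gaussianNoiseSigma additive Gaussian noise sigma, 8-bit units.
#' @slot seed integer RNG seed.
#' @seealso [SceneSpec()], [generateScene()]
#' @export
setClass("SceneSpec", representation(
  width = "numeric", height = "numeric",
  nNuclei = "numeric", overlapFraction = "numeric",
  malignantFraction = "numeric",
  radiusRangeBenign = "numeric", radiusRangeMalignant = "numeric",
  darknessContrast = "numeric", chromatinNoiseSigma = "numeric",
  impulseNoiseDensity = "numeric", gaussianNoiseSigma = "numeric",
  seed = "numeric"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  frac <- c(overlapFraction = object@overlapFraction,
            malignantFraction = object@malignantFraction,
            impulseNoiseDensity = object@impulseNoiseDensity)
  bad <- frac < 0 | frac > 1
  if (any(bad))
    msg <- c(msg, paste0(names(frac)[bad], " must lie in [0, 1]"))
  if (object@width < 8 || object@height < 8)
    msg <- c(msg, "canvas must be at least 8x8 pixels")
  for (nm in c("radiusRangeBenign", "radiusRangeMalignant")) {
    r <- slot(object, nm)
    if (length(r) != 2 || r[1] <= 0 || r[2] <= r[1])
      msg <- c(msg, paste0(nm, " must be a positive non-degenerate interval"))
  }
  if (length(object@chromatinNoiseSigma) != 2 ||
      any(object@chromatinNoiseSigma < 0))
    msg <- c(msg, "chromatinNoiseSigma must be two non-negative values")
  if (object@gaussianNoiseSigma < 0)
    msg <- c(msg, "gaussianNoiseSigma must be non-negative")
  if (object@nNuclei < 0) msg <- c(msg, "nNuclei must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A rendered synthetic scene with ground truth
#'
#' Container returned by [generateScene()]: the noisy 8-bit RGB raster, the
#' noise-free render, the instance label mask, and the per-nucleus ground
#' truth table. Rasters use the EBImage axis convention, `[x, y(, channel)]`
#' with `dim1 = width`.
#'
#' @slot image numeric array `width x height x 3`, intensities in `[0, 255]`.
#' @slot clean same geometry, before impulse/Gaussian noise.
#' @slot mask integer matrix: 0 background, positive nucleus ids.
#' @slot nuclei `data.frame` with one row per nucleus: `id`, `class`
#'   (benign/malignant), `overlap` (single/overlapped), `cx`, `cy`, `a`, `b`
#'   (semi-axes, pixels), `angle` (radians).
#' @slot spec the generating [SceneSpec-class].
#' @export
setClass("CytoScene", representation(
  image = "array", clean = "array", mask = "matrix",
  nuclei = "data.frame", spec = "SceneSpec"
))

setValidity("CytoScene", function(object) {
  msg <- character()
  if (!identical(dim(object@image)[1:2], dim(object@mask)))
    msg <- c(msg, "image and mask dimensions differ")
  ids <- sort(unique(as.integer(object@mask[object@mask > 0])))
  if (!identical(ids, sort(as.integer(object@nuclei$id))))
    msg <- c(msg, "mask labels and nuclei table ids differ")
  if (length(msg)) msg else TRUE
})

#' A fixed-cardinality feature subset found by simulated annealing
#'
#' @slot selected character vector of selected feature codes (e.g. `"F37"`),
#'   of length `nf`.
#' @slot cost held-out misclassification rate of the subset, in `[0, 1]`.
#' @slot trace per-iteration `data.frame`: `iteration`, `temperature`,
#'   `currentCost`, `bestCost`.
#' @slot seed integer seed the search was run under.
#' @seealso [annealFeatures()]
#' @export
setClass("FeatureSubset", representation(
  selected = "character", cost = "numeric",
  trace = "data.frame", seed = "numeric"
))

#' Ensemble classifier of bagged decision trees
#'
#' One hundred (by default) unpruned decision trees, each grown on an
#' n-out-of-n bootstrap resample of the training rows; prediction is by
#' majority vote with exact ties resolved toward the malignant class.
#'
#' @slot trees list of fitted `rpart` trees.
#' @slot featureCodes character, the feature columns the model consumes.
#' @slot nTrees number of trees.
#' @slot cvMetrics named numeric, stratified cross-validation metrics (in
#'   percent) computed on the training data.
#' @slot cvCounts named numeric, pooled cross-validation confusion counts
#'   (TP, FP, TN, FN).
#' @slot seed integer training seed.
#' @seealso [trainECBDT()]
#' @export
setClass("EnsembleModel", representation(
  trees = "list", featureCodes = "character", nTrees = "numeric",
  cvMetrics = "numeric", cvCounts = "numeric", seed = "numeric"
))

setValidity("EnsembleModel", function(object) {
  if (length(object@trees) != object@nTrees)
    "number of trees differs from nTrees" else TRUE
})
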