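#' Accessors for scene, subset and model objects
#'
#' `sceneImage`, `cleanImage`, `instanceMask` and `nucleiTable` read the
#' slots of a [CytoScene-class]; `selectedFeatures`, `subsetCost` and
#' `costTrace` those of a [FeatureSubset-class]; `cvMetrics` and `nTrees`
#' those of an [EnsembleModel-class].
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases sceneImage cleanImage instanceMask nucleiTable selectedFeatures
#'   subsetCost costTrace cvMetrics nTrees
NULL

#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname accessors
#' @export
setGeneric("cleanImage", function(x) standardGeneric("cleanImage"))
#' @rdname accessors
#' @export
setGeneric("instanceMask", function(x) standardGeneric("instanceMask"))
#' @rdname accessors
#' @export
setGeneric("nucleiTable", function(x) standardGeneric("nucleiTable"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("subsetCost", function(x) standardGeneric("subsetCost"))
#' @rdname accessors
#' @export
setGeneric("costTrace", function(x) standardGeneric("costTrace"))
#' @rdname accessors
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))
#' @rdname accessors
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))

#' @rdname accessors
setMethod("sceneImage", "CytoScene", function(x) x@image)
#' @rdname accessors
setMethod("cleanImage", "CytoScene", function(x) x@clean)
#' @rdname accessors
setMethod("instanceMask", "CytoScene", function(x) x@mask)
#' @rdname accessors
setMethod("nucleiTable", "CytoScene", function(x) x@nuclei)
#' @rdname accessors
setMethod("selectedFeatures", "FeatureSubset", function(x) x@selected)
#' @rdname accessors
setMethod("subsetCost", "FeatureSubset", function(x) x@cost)
#' @rdname accessors
setMethod("costTrace", "FeatureSubset", function(x) x@trace)
#' @rdname accessors
setMethod("cvMetrics", "EnsembleModel", function(x) x@cvMetrics)
#' @rdname accessors
setMethod("nTrees", "EnsembleModel", function(x) x@nTrees)

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", object@width, "x", object@height, "px,",
      object@nNuclei, "nuclei\n")
  cat("  overlap fraction:", object@overlapFraction,
      " malignant fraction:", object@malignantFraction, "\n")
  cat("  radii benign [", paste(object@radiusRangeBenign, collapse = ", "),
      "] malignant [", paste(object@radiusRangeMalignant, collapse = ", "),
      "] px\n", sep = "")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "CytoScene", function(object) {
  tab <- table(object@nuclei$class)
  cat("CytoScene:", paste(dim(object@image)[1:2], collapse = " x "),
      "px,", nrow(object@nuclei), "nuclei (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n")
})

setMethod("show", "FeatureSubset", function(object) {
  cat("FeatureSubset:", length(object@selected), "features, cost",
      round(object@cost, 4), "\n")
  cat(" ", paste(object@selected, collapse = " "), "\n")
})

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel:", object@nTrees, "bagged trees on",
      length(object@featureCodes), "features\n")
  if (length(object@cvMetrics)) {
    cat("  CV metrics (%):",
        paste(names(object@cvMetrics),
              round(object@cvMetrics, 2), sep = "=", collapse = " "), "\n")
  }
})
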