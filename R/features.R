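# The 201-dimensional per-nucleus feature vector, laid out as codes
# F1-F201:
#   F1-F14    morphometrics
#   F15-F20   colorimetric means (R, G, B, H, S, V)
#   F21-F69   CCFOS: 7 first-order statistics x 7 colour components,
#             component-major in the order R, G, B, H, S, V, Gray
#   F70-F157  GLCM: 22 statistics x 4 orientations, orientation-major
#             (0, 45, 90, 135), statistics in canonical row order
#   F158-F201 GLRLM: 11 statistics x 4 orientations, orientation-major
# All channels live on the [0, 255] scale (H, S, V scaled up from [0, 1];
# gray is ITU-R 601 luma).

FOS_STATS <- c("mean", "std", "smoothness", "variance", "skewness",
               "kurtosis", "energy")
CCFOS_COMPONENTS <- c("R", "G", "B", "H", "S", "V", "Gray")
GLCM_STATS <- c("autocorrelation", "contrast", "correlation1",
                "correlation2", "cluster_prominence", "cluster_shade",
                "dissimilarity", "energy", "entropy", "homogeneity1",
                "homogeneity2", "maximum_probability", "sum_of_square",
                "sum_average", "sum_entropy", "sum_variance",
                "difference_variance", "difference_entropy", "imc1",
                "imc2", "idn", "idmn")
GLRLM_STATS <- c("sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge",
                 "lrhge", "gln", "rln", "rp")

#' Feature code table
#'
#' The fixed layout of the 201 feature codes: code (`F1`..`F201`),
#' human-readable name, and block (`morphometric`, `colorimetric`,
#' `ccfos`, `glcm`, `glrlm`).
#'
#' @return `data.frame` with columns `code`, `name`, `block` (201 rows).
#' @examples
#' fc <- featureCodes()
#' fc[fc$code %in% c("F19", "F37", "F70"), ]
#' @export
featureCodes <- function() {
  morpho <- c("area", "perimeter", "roundness", "solidity",
              "equivalent_diameter", "compactness", "eccentricity",
              "diameter", "major_axis", "minor_axis", "elongation",
              "max_intensity", "min_intensity", "mean_intensity")
  color <- paste0("mean_", c("R", "G", "B", "H", "S", "V"))
  ccfos <- as.vector(t(outer(CCFOS_COMPONENTS, FOS_STATS,
                             function(c, s) paste0("fos_", c, "_", s))))
  glcm <- as.vector(vapply(GLCM_ANGLES, function(a)
    paste0("glcm_", GLCM_STATS, "_", a), character(22)))
  glrlm <- as.vector(vapply(GLCM_ANGLES, function(a)
    paste0("glrlm_", GLRLM_STATS, "_", a), character(11)))
  nm <- c(morpho, color, ccfos, glcm, glrlm)
  data.frame(code = paste0("F", seq_along(nm)), name = nm,
             block = rep(c("morphometric", "colorimetric", "ccfos",
                           "glcm", "glrlm"),
                         c(14, 6, 49, 88, 44)))
}

#' Morphometric features of a region (F1-F14)
#'
#' Area; chain-code perimeter (axial steps weigh 1, diagonal steps
#' `sqrt(2)`); roundness `4 pi A / P^2`; solidity; equivalent circular
#' diameter `sqrt(4 A / pi)`; compactness `A / P^2` (identically
#' roundness over `4 pi`); eccentricity; diameter `P / pi`; major/minor
#' axis lengths of the image-moments ellipse; elongation (major axis over
#' perimeter); max/min/mean gray intensity.
#'
#' @param mask logical matrix with one connected region.
#' @param gray gray plane in `[0, 255]`, same size.
#' @return named numeric of length 14.
#' @export
morphometricFeatures <- function(mask, gray) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("empty region")
  area <- nrow(pts)
  ct <- traceContour(mask)
  P <- if (nrow(ct) < 2) 4 else {
    d <- rbind(diff(ct), ct[1, ] - ct[nrow(ct), ])
    steps <- abs(d[, 1]) + abs(d[, 2])
    sum(ifelse(steps == 1, 1, sqrt(2))[steps > 0])
  }
  P <- max(P, 1)
  ax <- momentsEllipse(pts)
  g <- gray[mask]
  c(area = area,
    perimeter = P,
    roundness = 4 * pi * area / P^2,
    solidity = area / convexArea(pts, dim(mask)),
    equivalent_diameter = sqrt(4 * area / pi),
    compactness = area / P^2,
    eccentricity = ax[["eccentricity"]],
    diameter = P / pi,
    major_axis = ax[["major"]],
    minor_axis = ax[["minor"]],
    elongation = ax[["major"]] / P,
    max_intensity = max(g),
    min_intensity = min(g),
    mean_intensity = mean(g))
}

#' Colorimetric features of a region (F15-F20)
#'
#' Componentwise means over the mask, in the order R, G, B, H, S, V, all
#' on the `[0, 255]` scale.
#'
#' @param channels channel planes from [channelPlanes()].
#' @param mask logical matrix.
#' @return named numeric of length 6.
#' @export
colorimetricFeatures <- function(channels, mask) {
  out <- vapply(c("R", "G", "B", "H", "S", "V"),
                function(c) mean(channels[[c]][mask]), 0)
  names(out) <- paste0("mean_", names(out))
  out
}

#' Colour-component first-order statistics (F21-F69)
#'
#' The seven [fosStats()] statistics for each of the seven components
#' R, G, B, H, S, V, Gray (component-major layout).
#'
#' @inheritParams colorimetricFeatures
#' @return named numeric of length 49.
#' @export
ccfosFeatures <- function(channels, mask) {
  out <- lapply(CCFOS_COMPONENTS, function(c) {
    s <- fosStats(channels[[c]][mask])
    names(s) <- paste0("fos_", c, "_", names(s))
    s
  })
  unlist(out)
}

#' GLCM texture features (F70-F157)
#'
#' The 22 cooccurrence statistics at offset 1 for the four orientations,
#' orientation-major.
#'
#' @param gray gray plane in `[0, 255]`.
#' @param mask logical matrix.
#' @return named numeric of length 88.
#' @export
glcmFeatures <- function(gray, mask) {
  q <- quantizeGray(gray)
  out <- lapply(GLCM_ANGLES, function(a) {
    s <- glcmStats(glcmMatrix(q, mask, a))
    names(s) <- paste0("glcm_", names(s), "_", a)
    s
  })
  unlist(out)
}

#' GLRLM texture features (F158-F201)
#'
#' The 11 run-length statistics for the four orientations,
#' orientation-major.
#'
#' @inheritParams glcmFeatures
#' @return named numeric of length 44.
#' @export
glrlmFeatures <- function(gray, mask) {
  q <- quantizeGray(gray)
  out <- lapply(GLCM_ANGLES, function(a) {
    s <- glrlmStats(glrlmMatrix(q, mask, a))
    names(s) <- paste0("glrlm_", names(s), "_", a)
    s
  })
  unlist(out)
}

#' Assemble the full 201-value feature vector of one nucleus
#'
#' Concatenates the five blocks in code order F1-F201. Values are named by
#' code with the descriptive name attached as `attr(, "featureNames")`.
#'
#' @param img RGB array `W x H x 3` in `[0, 255]`.
#' @param mask logical matrix with one connected region.
#' @return named numeric of length 201, all finite.
#' @export
assembleFeatureVector <- function(img, mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("empty region")
  # crop to the bounding box; all features are crop-invariant
  x0 <- min(pts[, 1]); x1 <- max(pts[, 1])
  y0 <- min(pts[, 2]); y1 <- max(pts[, 2])
  sub <- img[x0:x1, y0:y1, , drop = FALSE]
  msk <- mask[x0:x1, y0:y1, drop = FALSE]
  ch <- channelPlanes(sub)
  v <- c(morphometricFeatures(msk, ch$Gray),
         colorimetricFeatures(ch, msk),
         ccfosFeatures(ch, msk),
         glcmFeatures(ch$Gray, msk),
         glrlmFeatures(ch$Gray, msk))
  stopifnot(length(v) == 201)
  if (any(!is.finite(v))) stop("non-finite feature value")
  out <- stats::setNames(v, paste0("F", 1:201))
  attr(out, "featureNames") <- names(v)
  out
}

#' Per-nucleus feature table of a labelled image
#'
#' Runs [assembleFeatureVector()] for every label of an instance mask.
#' Regions smaller than `minArea` pixels are skipped (they carry no stable
#' texture).
#'
#' @param img RGB array `W x H x 3` in `[0, 255]`.
#' @param labelMask integer instance mask (0 = background).
#' @param labels optional named/ordered class labels per nucleus id
#'   (character or factor), attached as a `label` column.
#' @param minArea minimum region area in pixels.
#' @return `data.frame` with columns `id`, `F1`..`F201` and optionally
#'   `label`.
#' @export
extractFeatures <- function(img, labelMask, labels = NULL, minArea = 15) {
  ids <- sort(unique(as.integer(labelMask[labelMask > 0])))
  rows <- list()
  for (id in ids) {
    m <- labelMask == id
    if (sum(m) < minArea) next
    rows[[as.character(id)]] <- assembleFeatureVector(img, m)
  }
  if (!length(rows)) {
    tab <- as.data.frame(matrix(numeric(), 0, 202))
    names(tab) <- c("id", paste0("F", 1:201))
    return(tab)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(id = as.integer(names(rows)), tab)
  rownames(tab) <- NULL
  if (!is.null(labels))
    tab$label <- factor(as.character(labels)[tab$id],
                        levels = c("benign", "malignant"))
  tab
}
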