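#' SLIC superpixels of an RGB image
#'
#' Clusters pixels in the joint `[l a b x y]` space (k-means style local
#' search over a 2S x 2S window, S the grid interval), then enforces
#' 4-connectivity. The colour planes are converted to L*a*b* with the D65
#' standard observer.
#'
#' @param img numeric array `W x H x 3` in `[0, 255]`.
#' @param nSuperpixels requested superpixel count (the delivered count is
#'   within about 20 percent of this); the pipeline default is 500.
#' @param compactness colour-vs-space weighting; 10 is the conventional
#'   scale for L*a*b* inputs.
#' @param maxIter local k-means sweeps.
#' @param lab optional precomputed L*a*b* array (saves the conversion when
#'   several stages share it).
#' @return integer matrix `W x H` of superpixel ids `1..n`, with attributes
#'   `nSuperpixels` (delivered) and `requested`.
#' @export
slicSuperpixels <- function(img, nSuperpixels = 500, compactness = 10,
                            maxIter = 10, lab = NULL) {
  d <- dim(img)
  if (nSuperpixels < 2) stop("nSuperpixels must be at least 2")
  if (prod(d[1:2]) < nSuperpixels)
    stop("image smaller than one superpixel cell")
  if (is.null(lab)) lab <- rgbToLab(img)
  labels <- slic_cpp(lab[, , 1], lab[, , 2], lab[, , 3],
                     as.integer(nSuperpixels), compactness,
                     as.integer(maxIter))
  structure(labels, nSuperpixels = max(labels), requested = nSuperpixels)
}

#' Median L*a*b* colour of each superpixel
#'
#' @param img numeric array `W x H x 3` in `[0, 255]`.
#' @param sp superpixel label matrix from [slicSuperpixels()].
#' @param lab optional precomputed L*a*b* array.
#' @return numeric matrix `n x 3` (columns L, a, b), one row per superpixel
#'   id, componentwise medians over the superpixel's own pixels.
#' @export
superpixelMedianLab <- function(img, sp, lab = NULL) {
  stopifnot(identical(dim(img)[1:2], dim(sp)))
  if (is.null(lab)) lab <- rgbToLab(img)
  pL <- lab[, , 1]; pa <- lab[, , 2]; pb <- lab[, , 3]
  idx <- split(seq_along(sp), as.vector(sp))
  out <- t(vapply(idx, function(i) {
    c(stats::median(pL[i]), stats::median(pa[i]), stats::median(pb[i]))
  }, numeric(3)))
  colnames(out) <- c("L", "a", "b")
  out
}

#' Label superpixels nuclei/background by K-Means on their median colour
#'
#' K-Means (k-means++-style multiple restarts, seeded) on the median
#' L*a*b* features; the cluster with the lower mean L* is taken as nuclei
#' (Pap-stained nuclei are darker than background), and the mask is painted
#' by superpixel membership, so mask boundaries are unions of superpixel
#' boundaries.
#'
#' @param medLab `n x 3` matrix from [superpixelMedianLab()].
#' @param sp the matching label matrix.
#' @param k number of clusters; the pipeline uses 2.
#' @param seed RNG seed for the restarts.
#' @return logical `W x H` nucleus mask.
#' @export
clusterSuperpixels <- function(medLab, sp, k = 2, seed = 1) {
  if (nrow(unique(medLab)) < k)
    stop("fewer than k distinct superpixel features")
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(medLab, centers = k, nstart = 10,
                                       iter.max = 50))
  nuc <- which.min(km$centers[, "L"])
  nucIds <- as.integer(rownames(medLab) %||% seq_len(nrow(medLab)))[
    km$cluster == nuc]
  matrix(as.vector(sp) %in% nucIds, nrow(sp), ncol(sp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hybrid SLIC/K-Means nucleus segmentation
#'
#' Convenience wrapper: superpixels, median L*a*b* features, K-Means with
#' `k = 2`, darker cluster painted as nuclei.
#'
#' @inheritParams slicSuperpixels
#' @inheritParams clusterSuperpixels
#' @return logical `W x H` nucleus mask.
#' @export
segmentNuclei <- function(img, nSuperpixels = 500, compactness = 10,
                          k = 2, seed = 1) {
  lab <- rgbToLab(img)
  sp <- slicSuperpixels(img, nSuperpixels, compactness, lab = lab)
  med <- superpixelMedianLab(img, sp, lab = lab)
  clusterSuperpixels(med, sp, k = k, seed = seed)
}
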