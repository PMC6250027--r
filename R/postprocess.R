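#' Disk structuring element
#'
#' Discrete Euclidean disk of the given radius (odd-sided
#' [EBImage::makeBrush()] `"disc"`).
#'
#' @param radius disk radius in pixels, `>= 1`.
#' @return binary matrix of side `2 * radius + 1`.
#' @export
diskElement <- function(radius) {
  if (radius < 1) stop("radius must be >= 1")
  EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
}

#' Morphological opening followed by paired closing
#'
#' Opening (erosion then dilation) with a disk of radius `radius` removes
#' objects smaller than the element; the subsequent closing (dilation then
#' erosion) with a disk of half that radius (rounded up) smooths the
#' boundary left by the opening.
#'
#' @param mask logical matrix.
#' @param radius opening disk radius.
#' @return logical matrix.
#' @export
openClose <- function(mask, radius) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- EBImage::opening(m, diskElement(radius))
  m <- EBImage::closing(m, diskElement(max(1, ceiling(radius / 2))))
  m > 0.5
}

#' Multiscale morphological refinement of a segmentation mask
#'
#' Each connected component is processed at its own scale: the opening
#' radius applied is the element of `openingRadii` closest to half the
#' component's equivalent radius (clamped to the range). Components that do
#' not survive their assigned opening are deleted; survivors are
#' boundary-smoothed by the paired closing of [openClose()]; finally
#' components smaller than `minArea` pixels are dropped. With the default
#' radii `{7..15}` a component of equivalent radius 16 is assigned radius 8.
#'
#' @param mask logical matrix.
#' @param openingRadii strictly increasing opening radii; default `7:15`.
#' @param minArea minimum surviving component area in pixels (default 50 at
#'   the 1024 x 1024 working scale).
#' @return logical matrix.
#' @export
refineMultiscale <- function(mask, openingRadii = 7:15, minArea = 50) {
  if (any(diff(openingRadii) <= 0))
    stop("openingRadii must be strictly increasing")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  n <- max(lab)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (n == 0) return(out)
  W <- nrow(mask); H <- ncol(mask)
  for (id in seq_len(n)) {
    px <- which(lab == id)
    eqR <- sqrt(length(px) / pi)
    radius <- openingRadii[which.min(abs(openingRadii - eqR / 2))]
    xs <- (px - 1L) %% W + 1L
    ys <- (px - 1L) %/% W + 1L
    pad <- radius + ceiling(radius / 2) + 1L
    x0 <- max(1L, min(xs) - pad); x1 <- min(W, max(xs) + pad)
    y0 <- max(1L, min(ys) - pad); y1 <- min(H, max(ys) + pad)
    crop <- matrix(FALSE, x1 - x0 + 1L, y1 - y0 + 1L)
    crop[cbind(xs - x0 + 1L, ys - y0 + 1L)] <- TRUE
    ref <- openClose(crop, radius)
    if (!any(ref)) next
    out[x0:x1, y0:y1] <- out[x0:x1, y0:y1] | ref
  }
  # final area filter
  lab2 <- EBImage::bwlabel(matrix(as.numeric(out), nrow(out), ncol(out)))
  if (max(lab2) > 0) {
    areas <- tabulate(lab2[lab2 > 0], nbins = max(lab2))
    drop <- which(areas < minArea)
    if (length(drop)) out[lab2 %in% drop] <- FALSE
  }
  out
}
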