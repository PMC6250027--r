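#' Read an image as an 8-bit RGB array
#'
#' Wraps [EBImage::readImage()]; grayscale inputs are replicated to three
#' channels, alpha channels dropped. Returned arrays are `width x height x 3`
#' with intensities in `[0, 255]`.
#'
#' @param path PNG/TIFF/JPEG file.
#' @return numeric array `W x H x 3`.
#' @export
readImageRGB <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Write an 8-bit RGB array as PNG
#'
#' @param img numeric array `W x H x 3`, `[0, 255]`.
#' @param path output file.
#' @export
writeImageRGB <- function(img, path) {
  a <- aperm(clip255(img) / 255, c(2, 1, 3))  # writePNG wants [row=y, col=x]
  png::writePNG(a, path)
  invisible(path)
}

#' Write an instance label mask as a 16-bit TIFF
#'
#' Labels are stored as `value / 65535` so up to 65535 nuclei round-trip
#' exactly; [readMask()] reverses the scaling.
#'
#' @param mask integer matrix (`0` = background).
#' @param path output file.
#' @export
writeMask <- function(mask, path) {
  if (max(mask) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(t(mask / 65535), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(t(m) * 65535)), nrow = ncol(m))
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Dice coefficient between two binary masks
#'
#' @param a,b logical matrices of equal size.
#' @return `2|a & b| / (|a| + |b|)`; 1 when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Convert an 8-bit RGB array to L*a*b*
#'
#' Uses [grDevices::convertColor()] (sRGB, D65 standard observer).
#'
#' @param img numeric array `W x H x 3` in `[0, 255]`.
#' @return numeric array `W x H x 3` of L*, a*, b*.
#' @export
rgbToLab <- function(img) {
  d <- dim(img)
  m <- matrix(img, ncol = 3) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, d)
}

# channel planes of a region, all on the [0, 255] scale, order used by the
# colorimetric/CCFOS extractors: R, G, B, H, S, V, gray (ITU-R 601 luma)
channelPlanes <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  hsv <- grDevices::rgb2hsv(as.vector(r), as.vector(g), as.vector(b),
                            maxColorValue = 255)
  shp <- dim(r)
  list(R = r, G = g, B = b,
       H = matrix(hsv[1, ] * 255, shp[1], shp[2]),
       S = matrix(hsv[2, ] * 255, shp[1], shp[2]),
       V = matrix(hsv[3, ] * 255, shp[1], shp[2]),
       Gray = 0.299 * r + 0.587 * g + 0.114 * b)
}
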