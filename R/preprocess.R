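#' Resize an RGB image to the working resolution
#'
#' Bilinear resampling (via [EBImage::resize()]); on downscales the image
#' is first Gaussian pre-smoothed (replicated borders) at the scale of the
#' decimation factor, which suppresses aliasing that would otherwise
#' perturb the texture features. The target is a fixed square by default,
#' so aspect ratio is not preserved. The working resolution for the whole
#' pipeline is 1024 x 1024.
#'
#' @param img numeric array `W x H x 3` in `[0, 255]`.
#' @param width,height target size in pixels.
#' @return resized array, `[0, 255]`.
#' @export
resizeImage <- function(img, width = 1024, height = 1024) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || any(d[1:2] < 1))
    stop("img must be a non-empty W x H x 3 array")
  if (d[1] == width && d[2] == height) return(img)
  x <- EBImage::Image(img / 255, colormode = "Color")
  f <- max(d[1] / width, d[2] / height)
  if (f > 1.2) {
    sigma <- 0.5 * sqrt(f^2 - 1)
    x <- EBImage::gblur(x, sigma = sigma, boundary = "replicate")
  }
  out <- EBImage::resize(x, w = width, h = height, antialias = FALSE)
  clip255(EBImage::imageData(out) * 255)
}

#' Per-channel linear contrast stretch
#'
#' Maps the `lowPct`/`highPct` percentile of each channel to 0/255 and clips
#' outside; a degenerate channel (all pixels equal at the chosen
#' percentiles) is returned unchanged. The default saturates the bottom and
#' top 1 percent of each channel.
#'
#' @param img numeric array `W x H x 3` in `[0, 255]`.
#' @param lowPct,highPct percentiles in `[0, 100]`, `lowPct < highPct`.
#' @return stretched array, `[0, 255]`.
#' @export
adjustIntensity <- function(img, lowPct = 1, highPct = 99) {
  if (!(lowPct >= 0 && lowPct < highPct && highPct <= 100))
    stop("need 0 <= lowPct < highPct <= 100")
  for (c in seq_len(dim(img)[3])) {
    ch <- img[, , c]
    q <- stats::quantile(ch, c(lowPct, highPct) / 100, names = FALSE)
    if (q[2] > q[1])
      img[, , c] <- clip255((ch - q[1]) / (q[2] - q[1]) * 255)
  }
  img
}

#' Median-filter each colour channel independently
#'
#' @param img numeric array `W x H x 3` in `[0, 255]`.
#' @param kernel odd window side in pixels; the default 3 is the smallest
#'   window, chosen to suppress impulse noise without blurring nucleus
#'   edges.
#' @return filtered array with channels never mixed.
#' @export
medianFilterRGB <- function(img, kernel = 3) {
  if (kernel %% 2 != 1 || kernel < 1) stop("kernel must be odd and >= 1")
  if (kernel == 1) return(img)
  if (kernel == 3) {
    for (c in seq_len(dim(img)[3])) img[, , c] <- median3(img[, , c])
    return(img)
  }
  r <- (kernel - 1) / 2
  for (c in seq_len(dim(img)[3])) {
    f <- EBImage::medianFilter(EBImage::Image(img[, , c] / 255), r)
    img[, , c] <- clip255(round(EBImage::imageData(f) * 255))
  }
  img
}

# 3x3 median via a 19-exchange sorting network over edge-reflected shifts
median3 <- function(m) {
  W <- nrow(m); H <- ncol(m)
  ix <- function(d) pmin(pmax(seq_len(W) + d, 1L), W)
  iy <- function(d) pmin(pmax(seq_len(H) + d, 1L), H)
  p <- vector("list", 9)
  k <- 0
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1
    p[[k]] <- m[ix(dx), iy(dy)]
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

#' Run the full preprocessing chain
#'
#' Resize to the working resolution, stretch contrast per channel, then
#' median-filter per channel -- in that order.
#'
#' @inheritParams resizeImage
#' @inheritParams adjustIntensity
#' @inheritParams medianFilterRGB
#' @return preprocessed array `width x height x 3`.
#' @export
preprocessImage <- function(img, width = 1024, height = 1024,
                            lowPct = 1, highPct = 99, kernel = 3) {
  img <- resizeImage(img, width, height)
  img <- adjustIntensity(img, lowPct, highPct)
  medianFilterRGB(img, kernel)
}
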