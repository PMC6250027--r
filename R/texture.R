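# Texture machinery: first-order statistics, gray-level cooccurrence
# matrices (GLCM) and gray-level run-length matrices (GLRLM).
#
# Conventions shared by both matrix families:
#  * gray values are quantised to NG = 8 uniform bins over the fixed range
#    [0, 255] (comparability across nuclei; per-nucleus min-max would
#    decouple darkness from texture);
#  * four orientations, expressed as (dx, dy) steps in the [x, y] raster:
#    0 = (1,0), 45 = (1,1), 90 = (0,1), 135 = (-1,1);
#  * only pixels inside the region mask participate; pairs/runs never cross
#    the mask boundary.

GLCM_ANGLES <- c("0", "45", "90", "135")
glcmOffset <- function(angle) {
  switch(angle, "0" = c(1L, 0L), "45" = c(1L, 1L),
         "90" = c(0L, 1L), "135" = c(-1L, 1L))
}

#' Quantise a gray plane to 8 levels
#'
#' Uniform bins over the fixed `[0, 255]` range.
#'
#' @param gray numeric matrix in `[0, 255]`.
#' @param nLevels number of levels.
#' @return integer matrix of levels `1..nLevels`.
#' @export
quantizeGray <- function(gray, nLevels = 8) {
  matrix(pmin(floor(gray / (256 / nLevels)) + 1L, nLevels),
         nrow(gray), ncol(gray))
}

#' First-order statistics of an intensity sample
#'
#' The seven histogram statistics, computed from a 256-bin normalised
#' histogram of the (rounded) sample: mean, standard deviation, smoothness
#' `1 - 1/(1 + sigma^2)`, variance, skewness, excess kurtosis (with the
#' `-3` term), and energy `sum p(i)^2`. A constant sample yields
#' `sd = smoothness = skewness = kurtosis = 0` and `energy = 1`.
#'
#' @param v numeric vector of intensities in `[0, 255]`.
#' @return named numeric of length 7 (`mean`, `std`, `smoothness`,
#'   `variance`, `skewness`, `kurtosis`, `energy`).
#' @export
fosStats <- function(v) {
  h <- tabulate(pmin(pmax(as.integer(round(v)), 0L), 255L) + 1L,
                nbins = 256)
  p <- h / length(v)
  i <- 0:255
  mu <- sum(i * p)
  s2 <- sum((i - mu)^2 * p)
  s <- sqrt(s2)
  c(mean = mu,
    std = s,
    smoothness = 1 - 1 / (1 + s2),
    variance = s2,
    skewness = if (s > 0) sum((i - mu)^3 * p) / s^3 else 0,
    kurtosis = if (s > 0) sum((i - mu)^4 * p) / s^4 - 3 else 0,
    energy = sum(p^2))
}

#' Gray-level cooccurrence matrix of a masked region
#'
#' Pairs at offset `d = 1` in the given orientation are counted only when
#' both pixels lie inside the mask, accumulated symmetrically and
#' normalised to sum to one.
#'
#' @param q quantised level matrix from [quantizeGray()].
#' @param mask logical matrix of the same size.
#' @param angle one of `"0"`, `"45"`, `"90"`, `"135"`.
#' @param nLevels number of gray levels.
#' @return `nLevels x nLevels` symmetric probability matrix.
#' @export
glcmMatrix <- function(q, mask, angle = "0", nLevels = 8) {
  off <- glcmOffset(as.character(angle))
  W <- nrow(q); H <- ncol(q)
  x0 <- max(1L, 1L - off[1]); x1 <- min(W, W - off[1])
  y0 <- max(1L, 1L - off[2]); y1 <- min(H, H - off[2])
  if (x0 > x1 || y0 > y1) stop("region too small for offset")
  xs <- x0:x1; ys <- y0:y1
  A <- mask[xs, ys, drop = FALSE] & mask[xs + off[1], ys + off[2],
                                         drop = FALSE]
  i <- q[xs, ys, drop = FALSE][A]
  j <- q[xs + off[1], ys + off[2], drop = FALSE][A]
  if (!length(i))
    stop("no valid pixel pair for orientation ", angle)
  C <- matrix(tabulate((i - 1L) * nLevels + j, nLevels * nLevels),
              nLevels, nLevels, byrow = TRUE)
  P <- C + t(C)
  P / sum(P)
}

#' The 22 cooccurrence statistics of a GLCM
#'
#' Computed with natural logarithms and the convention `0 log 0 = 0`;
#' correlation-type statistics are defined as 0 when a marginal standard
#' deviation vanishes. The sum-variance statistic is centred on the
#' sum-entropy value, and the difference variance is the uncentred second
#' moment of the difference distribution.
#'
#' @param P GLCM probability matrix from [glcmMatrix()].
#' @return named numeric of length 22, in the canonical row order
#'   (autocorrelation .. idmn).
#' @export
glcmStats <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  lv <- seq_len(L)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sdx <- sqrt(sum((lv - mux)^2 * px)); sdy <- sqrt(sum((lv - muy)^2 * py))
  xlog <- function(p) ifelse(p > 0, p * log(p), 0)
  # sum and difference marginals
  ks <- 2:(2 * L)
  psum <- vapply(ks, function(k) sum(P[i + j == k]), 0)
  kd <- 0:(L - 1)
  pdif <- vapply(kd, function(k) sum(P[abs(i - j) == k]), 0)
  sumEnt <- -sum(xlog(psum))
  HXY <- -sum(xlog(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(ifelse(pxy > 0, P * log(pxy), 0))
  HXY2 <- -sum(xlog(pxy))
  HX <- -sum(xlog(px)); HY <- -sum(xlog(py))
  corrNum <- sum((i - mux) * (j - muy) * P)
  c(autocorrelation = sum(i * j * P),
    contrast = sum((i - j)^2 * P),
    correlation1 = if (sdx > 0 && sdy > 0) corrNum / (sdx * sdy) else 0,
    correlation2 = if (sdx > 0 && sdy > 0)
      (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0,
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = -sum(xlog(P)),
    homogeneity1 = sum(P / (1 + abs(i - j))),
    homogeneity2 = sum(P / (1 + (i - j)^2)),
    maximum_probability = max(P),
    sum_of_square = sum((i - mux)^2 * P),
    sum_average = sum(ks * psum),
    sum_entropy = sumEnt,
    sum_variance = sum((ks - sumEnt)^2 * psum),
    difference_variance = sum(kd^2 * pdif),
    difference_entropy = -sum(xlog(pdif)),
    imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY)))),
    idn = sum(P / (1 + abs(i - j) / L)),
    idmn = sum(P / (1 + (i - j)^2 / L^2)))
}

#' Gray-level run-length matrix of a masked region
#'
#' Runs are maximal same-level pixel sequences along the orientation,
#' truncated at the mask boundary (an out-of-mask pixel breaks a run).
#'
#' @inheritParams glcmMatrix
#' @return count matrix `nLevels x Rmax` with attribute `np` (mask pixel
#'   count); `sum(g)` is the total number of runs and
#'   `sum(j * g[, j])` equals `np`.
#' @export
glrlmMatrix <- function(q, mask, angle = "0", nLevels = 8) {
  off <- glcmOffset(as.character(angle))
  q0 <- ifelse(mask, q, 0L)
  xv <- as.vector(row(q0)); yv <- as.vector(col(q0)); vv <- as.vector(q0)
  key <- if (off[1] == 1 && off[2] == 0) yv
  else if (off[1] == 0 && off[2] == 1) xv
  else if (off[1] == 1 && off[2] == 1) xv - yv
  else xv + yv
  ord <- order(key, xv, yv)
  lines <- split(vv[ord], key[ord])
  levs <- integer(); lens <- integer()
  for (ln in lines) {
    r <- rle(ln)
    keep <- r$values > 0
    levs <- c(levs, r$values[keep])
    lens <- c(lens, r$lengths[keep])
  }
  if (!length(levs)) {
    g <- matrix(0, nLevels, 1)
  } else {
    R <- max(lens)
    g <- matrix(tabulate((levs - 1L) * R + lens, nLevels * R),
                nLevels, R, byrow = TRUE)
  }
  attr(g, "np") <- sum(mask)
  g
}

#' The 11 run-length statistics of a GLRLM
#'
#' @param g run-length count matrix from [glrlmMatrix()] (attribute `np`
#'   holds the pixel count used by run percentage).
#' @param np region pixel count; defaults to the matrix attribute.
#' @return named numeric of length 11, canonical order (sre .. rp).
#' @export
glrlmStats <- function(g, np = attr(g, "np")) {
  nr <- sum(g)
  if (nr == 0) stop("no runs in region")
  i <- row(g); j <- col(g)
  c(sre = sum(g / j^2) / nr,
    lre = sum(g * j^2) / nr,
    lgre = sum(g / i^2) / nr,
    hgre = sum(g * i^2) / nr,
    srlge = sum(g / (i^2 * j^2)) / nr,
    srhge = sum(g * i^2 / j^2) / nr,
    lrlge = sum(g * j^2 / i^2) / nr,
    lrhge = sum(g * i^2 * j^2) / nr,
    gln = sum(rowSums(g)^2) / nr,
    rln = sum(colSums(g)^2) / nr,
    rp = nr / np)
}
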