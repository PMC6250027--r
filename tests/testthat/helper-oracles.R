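# independent brute-force oracles for the texture features: explicit
# pair/run enumeration with scalar loops, sharing no code with the
# package's vectorised implementations

oracleOffset <- function(angle) {
  switch(as.character(angle), "0" = c(1L, 0L), "45" = c(1L, 1L),
         "90" = c(0L, 1L), "135" = c(-1L, 1L))
}

# symmetric normalised cooccurrence matrix by scalar pair enumeration
oracleGLCM <- function(q, mask, angle, nLevels = 8) {
  off <- oracleOffset(angle)
  P <- matrix(0, nLevels, nLevels)
  W <- nrow(q); H <- ncol(q)
  for (x in seq_len(W)) for (y in seq_len(H)) {
    x2 <- x + off[1]; y2 <- y + off[2]
    if (x2 < 1 || x2 > W || y2 < 1 || y2 > H) next
    if (!mask[x, y] || !mask[x2, y2]) next
    i <- q[x, y]; j <- q[x2, y2]
    P[i, j] <- P[i, j] + 1
    P[j, i] <- P[j, i] + 1
  }
  if (sum(P) == 0) stop("oracle: no pair")
  P / sum(P)
}

# run-length counts by walking each line pixel by pixel
oracleGLRLM <- function(q, mask, angle, nLevels = 8) {
  off <- oracleOffset(angle)
  W <- nrow(q); H <- ncol(q)
  # starting points: pixels with no predecessor along the direction
  runs <- list()
  for (x in seq_len(W)) for (y in seq_len(H)) {
    px <- x - off[1]; py <- y - off[2]
    hasPrev <- px >= 1 && px <= W && py >= 1 && py <= H
    if (hasPrev) next
    # walk this line
    cx <- x; cy <- y
    lev <- 0L; len <- 0L
    while (cx >= 1 && cx <= W && cy >= 1 && cy <= H) {
      v <- if (mask[cx, cy]) q[cx, cy] else 0L
      if (v == lev && v > 0) {
        len <- len + 1L
      } else {
        if (lev > 0) runs[[length(runs) + 1]] <- c(lev, len)
        lev <- v; len <- if (v > 0) 1L else 0L
      }
      cx <- cx + off[1]; cy <- cy + off[2]
    }
    if (lev > 0) runs[[length(runs) + 1]] <- c(lev, len)
  }
  R <- max(1, vapply(runs, `[`, 0, 2))
  g <- matrix(0, nLevels, R)
  for (r in runs) g[r[1], r[2]] <- g[r[1], r[2]] + 1
  attr(g, "np") <- sum(mask)
  g
}

# first-order statistics directly from the value list (no histogram)
oracleFOS <- function(v) {
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  s <- sqrt(s2)
  c(mean = mu, std = s, smoothness = 1 - 1 / (1 + s2), variance = s2,
    skewness = if (s > 0) mean((v - mu)^3) / s^3 else 0,
    kurtosis = if (s > 0) mean((v - mu)^4) / s^4 - 3 else 0,
    energy = sum((tabulate(v + 1L, 256) / length(v))^2))
}

# random masked 8-bit gray image for oracle comparisons
randomMaskedImage <- function(side = 8, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:255, side * side, replace = TRUE), side, side)
    m <- matrix(stats::runif(side * side) < 0.8, side, side)
    if (!any(m)) m[1:2, 1:2] <- TRUE
    list(gray = g, mask = m)
  })
}

# split/merge error of a resolved mask against scene ground truth:
# per ground-truth clump, | #predicted labels - #true nuclei |
splitError <- function(resolved, scene) {
  gt <- instanceMask(scene)
  clumps <- EBImage::bwlabel(matrix(as.numeric(gt > 0), nrow(gt), ncol(gt)))
  err <- 0
  for (cl in seq_len(max(clumps))) {
    inC <- clumps == cl
    trueN <- length(unique(gt[inC & gt > 0]))
    predN <- length(unique(resolved[inC & resolved > 0]))
    err <- err + abs(predN - trueN)
  }
  err
}
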