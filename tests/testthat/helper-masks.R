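# mask construction helpers shared across tests

# filled-ellipse mask; ells is a list of c(cx, cy, a, b, angle)
maskFromEllipses <- function(side, ells) {
  m <- matrix(FALSE, side, side)
  for (e in ells) {
    xs <- pmax(1, floor(e[1] - max(e[3], e[4]))):
      pmin(side, ceiling(e[1] + max(e[3], e[4])))
    ys <- pmax(1, floor(e[2] - max(e[3], e[4]))):
      pmin(side, ceiling(e[2] + max(e[3], e[4])))
    for (y in ys) {
      dx <- xs - e[1]; dy <- y - e[2]
      u <- (dx * cos(e[5]) + dy * sin(e[5])) / e[3]
      v <- (-dx * sin(e[5]) + dy * cos(e[5])) / e[4]
      m[xs[u^2 + v^2 <= 1], y] <- TRUE
    }
  }
  m
}

diskMask <- function(side, cx, cy, r) {
  maskFromEllipses(side, list(c(cx, cy, r, r, 0)))
}

# fused pair of disks with centre distance frac * 2r
fusedDisks <- function(r, frac = 1.5 / 2) {
  side <- ceiling(4 * r + 2 * frac * 2 * r) + 8
  c1 <- side / 2 - frac * r; c2 <- side / 2 + frac * r
  list(mask = maskFromEllipses(side, list(c(c1, side / 2, r, r, 0),
                                          c(c2, side / 2, r, r, 0))),
       centers = rbind(c(c1, side / 2), c(c2, side / 2)))
}

# rotate a matrix / W x H x 3 array by 90 degrees
rot90mat <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot90img <- function(img) {
  out <- array(0, c(dim(img)[2], dim(img)[1], dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- rot90mat(img[, , c])
  out
}

# a small flat-background image with one textured elliptical nucleus
smallNucleusScene <- function(seed = 1, side = 64) {
  withr::with_seed(seed, {
    img <- array(rep(c(230, 220, 225), each = side * side),
                 c(side, side, 3))
    mask <- maskFromEllipses(side, list(c(side / 2, side / 2,
                                          side * 0.3, side * 0.22, 0.5)))
    for (c in 1:3) {
      ch <- img[, , c]
      ch[mask] <- 110 + stats::rnorm(sum(mask), 0, 18)
      img[, , c] <- pmin(pmax(round(ch), 0), 255)
    }
    list(img = img, mask = mask)
  })
}
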