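#' Shape descriptor of a connected region
#'
#' The five shape cues used to discriminate single from overlapped nuclei:
#' solidity (area over convex area), eccentricity, equivalent circular
#' diameter, and major/minor axis lengths of the image-moments ellipse.
#'
#' @param mask logical matrix containing one connected region.
#' @return named numeric: `solidity`, `eccentricity`,
#'   `equivalentDiameter`, `majorAxis`, `minorAxis`.
#' @export
shapeDescriptor <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("empty region")
  area <- nrow(pts)
  ax <- momentsEllipse(pts)
  c(solidity = area / convexArea(pts, dim(mask)),
    eccentricity = ax["eccentricity"][[1]],
    equivalentDiameter = sqrt(4 * area / pi),
    majorAxis = ax["major"][[1]], minorAxis = ax["minor"][[1]])
}

# convex area as the pixel count of the rasterised convex hull
convexArea <- function(pts, dims) {
  if (nrow(pts) < 3) return(nrow(pts))
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  xs <- min(pts[, 1]):max(pts[, 1])
  ys <- min(pts[, 2]):max(pts[, 2])
  gx <- rep(xs, length(ys)); gy <- rep(ys, each = length(xs))
  inside <- rep(TRUE, length(gx))
  n <- length(h)
  # chull returns vertices clockwise; a point is inside iff it is on the
  # clockwise side (or on the edge) of every directed hull edge
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (gy - hy[i]) - (hy[j] - hy[i]) * (gx - hx[i])
    inside <- inside & (cross <= 1e-9)
    if (!any(inside)) break
  }
  max(sum(inside), nrow(pts))
}

# best-fit ellipse from image moments (pixel-extent corrected covariance)
momentsEllipse <- function(pts) {
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  cxx <- mean((pts[, 1] - mx)^2) + 1 / 12
  cyy <- mean((pts[, 2] - my)^2) + 1 / 12
  cxy <- mean((pts[, 1] - mx) * (pts[, 2] - my))
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  major <- 4 * sqrt(e$values[1])
  minor <- 4 * sqrt(max(e$values[2], 0))
  c(cx = mx, cy = my, major = major, minor = minor,
    angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
    eccentricity = sqrt(max(0, 1 - (minor / major)^2)))
}

#' Train the single-vs-overlapped gate
#'
#' An RBF support-vector machine on the standardised five-feature shape
#' descriptors. The training set shipped with the pipeline is synthetic
#' (see [makeOverlapShapeSet()]): clinical shape annotations are not
#' distributed, so the gate is a documented, reproducible surrogate trained
#' on rendered single ellipses and fused pairs.
#'
#' @param shapes numeric matrix/data.frame, one [shapeDescriptor()] row per
#'   region.
#' @param labels factor or character, `"single"`/`"overlapped"`.
#' @param seed RNG seed.
#' @return fitted [e1071::svm] model.
#' @export
trainOverlapSVM <- function(shapes, labels, seed = 1) {
  labels <- factor(as.character(labels), levels = c("single", "overlapped"))
  if (nlevels(droplevels(labels)) < 2)
    stop("both single and overlapped examples are required")
  withr::with_seed(as.integer(seed),
                   e1071::svm(x = as.matrix(shapes), y = labels,
                              kernel = "radial", scale = TRUE))
}

#' Synthetic shape-training set for the overlap gate
#'
#' Renders `n` single ellipses and `n` fused pairs (centre distance uniform
#' in `[0.7, 1.1]` times the sum of mean radii) and returns their shape
#' descriptors.
#'
#' @param n examples per class.
#' @param radiusRange mean-radius interval in pixels.
#' @param seed RNG seed.
#' @return list with `shapes` (matrix) and `labels` (factor).
#' @export
makeOverlapShapeSet <- function(n = 100, radiusRange = c(8, 26), seed = 1) {
  withr::with_seed(as.integer(seed), {
    shapes <- NULL
    labels <- character()
    for (i in seq_len(2 * n)) {
      overl <- i > n
      r1 <- stats::runif(1, radiusRange[1], radiusRange[2])
      u <- stats::runif(1, 1, 1.3)
      side <- ceiling(4 * radiusRange[2]) + 8L
      m <- matrix(FALSE, side, side)
      cx <- side / 2; cy <- side / 2
      px <- ellipsePixels(side, side, cx, cy, r1 * u, r1 / u,
                          stats::runif(1, 0, pi))
      m[px] <- TRUE
      if (overl) {
        r2 <- stats::runif(1, radiusRange[1], radiusRange[2])
        u2 <- stats::runif(1, 1, 1.3)
        d <- stats::runif(1, 0.7, 1.1) * (r1 + r2)
        th <- stats::runif(1, 0, 2 * pi)
        px2 <- ellipsePixels(side, side, cx + d * cos(th), cy + d * sin(th),
                             r2 * u2, r2 / u2, stats::runif(1, 0, pi))
        m[px2] <- TRUE
      }
      shapes <- rbind(shapes, shapeDescriptor(m))
      labels <- c(labels, if (overl) "overlapped" else "single")
    }
    list(shapes = shapes,
         labels = factor(labels, levels = c("single", "overlapped")))
  })
}

#' Default overlap gate trained on synthetic shapes
#'
#' @inheritParams makeOverlapShapeSet
#' @return fitted [e1071::svm] model.
#' @export
defaultOverlapModel <- function(seed = 1) {
  s <- makeOverlapShapeSet(seed = seed)
  trainOverlapSVM(s$shapes, s$labels, seed = seed)
}

#' Trace the outer contour of a connected region
#'
#' Ordered 8-connected boundary points via [EBImage::ocontour()], returned
#' 1-based in the `[x, y]` raster frame.
#'
#' @param mask logical matrix.
#' @return integer matrix `n x 2` of contour points.
#' @export
traceContour <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  if (!length(oc)) stop("empty region")
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]]
  pts + 1L
}

# circular Gaussian smoothing of a closed signal
smoothCircular <- function(v, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  n <- length(v)
  ext <- c(v[(n - h + 1):n], v, v[1:h])
  stats::convolve(ext, rev(k), type = "filter")
}

#' Concave points of a region contour
#'
#' The closed contour is Gaussian-smoothed (curvature-scale-space style),
#' curvature is computed from circular finite differences, and points are
#' kept when they are (i) local curvature-magnitude maxima above the
#' `curvatureQuantile` of the contour, and (ii) concave -- the chord
#' midpoint between the points `chordHalf` samples away falls outside the
#' region, i.e. the contour turns away from it. Convex shapes yield an
#' empty set.
#'
#' @param mask logical matrix with one connected region.
#' @param sigma contour smoothing scale in samples.
#' @param curvatureQuantile curvature-magnitude threshold quantile.
#' @param chordHalf half-chord length in samples for the concavity test.
#' @param minSep minimal separation (samples) between reported points.
#' @return numeric matrix `k x 2` of concave-point coordinates with
#'   attribute `index` (positions along the contour) and `contour` (the
#'   full traced contour).
#' @export
detectConcavePoints <- function(mask, sigma = 3, curvatureQuantile = 0.9,
                                chordHalf = 5, minSep = 5) {
  ct <- traceContour(mask)
  n <- nrow(ct)
  empty <- function() {
    out <- matrix(numeric(), 0, 2)
    attr(out, "index") <- integer()
    attr(out, "contour") <- ct
    out
  }
  if (n < 4 * chordHalf) return(empty())
  xs <- smoothCircular(ct[, 1], sigma)
  ys <- smoothCircular(ct[, 2], sigma)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  x1 <- (xs[ip] - xs[im]) / 2; y1 <- (ys[ip] - ys[im]) / 2
  x2 <- xs[ip] - 2 * xs + xs[im]; y2 <- ys[ip] - 2 * ys + ys[im]
  sp <- (x1^2 + y1^2)^1.5
  kap <- ifelse(sp > 1e-9, (x1 * y2 - y1 * x2) / sp, 0)
  ak <- abs(kap)
  thr <- stats::quantile(ak, curvatureQuantile, names = FALSE)

  # concavity: chord midpoint outside the region
  W <- nrow(mask); H <- ncol(mask)
  qi <- (seq_len(n) + chordHalf - 1L) %% n + 1L
  qj <- (seq_len(n) - chordHalf - 1L) %% n + 1L
  mx <- pmin(pmax(round((ct[qi, 1] + ct[qj, 1]) / 2), 1L), W)
  my <- pmin(pmax(round((ct[qi, 2] + ct[qj, 2]) / 2), 1L), H)
  outside <- !mask[cbind(mx, my)]

  cand <- which(ak >= thr & outside)
  # local maxima within +-minSep samples (circular)
  isMax <- vapply(cand, function(i) {
    w <- ((i - minSep):(i + minSep) - 1L) %% n + 1L
    ak[i] >= max(ak[w])
  }, logical(1))
  cand <- cand[isMax]
  if (!length(cand)) return(empty())
  # merge runs of nearby candidates, keep the sharpest of each run
  o <- order(cand)
  cand <- cand[o]
  groups <- cumsum(c(1, diff(cand) > minSep))
  # wrap-around: first and last group may be one
  if (length(unique(groups)) > 1 &&
      (n - cand[length(cand)]) + cand[1] <= minSep)
    groups[groups == max(groups)] <- 1
  keep <- vapply(split(cand, groups),
                 function(g) g[which.max(ak[g])], numeric(1))
  keep <- sort(as.integer(keep))
  out <- ct[keep, , drop = FALSE]
  attr(out, "index") <- keep
  attr(out, "contour") <- ct
  out
}

#' Direct least-squares ellipse fit
#'
#' Numerically stable direct fit of an ellipse-constrained conic to a point
#' set (reduced scatter-matrix formulation). Points are centred and scaled
#' before solving.
#'
#' @param pts numeric matrix `n x 2`, `n >= 5`.
#' @return named numeric `cx, cy, a, b, angle` with `a >= b > 0`, or `NULL`
#'   when no ellipse solution exists.
#' @export
fitEllipseDirect <- function(pts) {
  if (nrow(pts) < 5) return(NULL)
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  s <- mean(sqrt((pts[, 1] - mx)^2 + (pts[, 2] - my)^2))
  if (s < 1e-9) return(NULL)
  x <- (pts[, 1] - mx) / s; y <- (pts[, 2] - my) / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- V[, ok[1]]
  conic <- c(a1, as.vector(T1 %*% a1))  # A B C D E F in scaled frame
  ellipseFromConic(conic, mx, my, s)
}

ellipseFromConic <- function(co, mx, my, s) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Vc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  M <- matrix(c(A, B / 2, B / 2, C), 2)
  e <- eigen(M, symmetric = TRUE)
  ax2 <- -Vc / e$values
  if (any(ax2 <= 0) || any(!is.finite(ax2))) return(NULL)
  ax <- sqrt(ax2)
  major <- which.max(ax)
  ang <- atan2(e$vectors[2, major], e$vectors[1, major])
  c(cx = cx * s + mx, cy = cy * s + my,
    a = max(ax) * s, b = min(ax) * s, angle = ang %% pi)
}

#' Mean normalised radial residual of points to an ellipse
#'
#' For each point the residual is `|r - 1|` with `r` the radial coordinate
#' in the ellipse's normalised frame; the mean over points is a
#' scale-free goodness-of-fit (0.05 means points deviate by about 5 percent
#' of the local radius).
#'
#' @param pts numeric matrix `n x 2`.
#' @param el ellipse as returned by [fitEllipseDirect()].
#' @return non-negative scalar (Inf for a `NULL` ellipse).
#' @export
ellipseResidual <- function(pts, el) {
  if (is.null(el)) return(Inf)
  dx <- pts[, 1] - el[["cx"]]; dy <- pts[, 2] - el[["cy"]]
  co <- cos(el[["angle"]]); si <- sin(el[["angle"]])
  u <- (dx * co + dy * si) / el[["a"]]
  v <- (-dx * si + dy * co) / el[["b"]]
  mean(abs(sqrt(u^2 + v^2) - 1))
}

# fallback ellipse from image moments of the region
momentsEllipseParams <- function(mask) {
  m <- momentsEllipse(which(mask, arr.ind = TRUE))
  c(cx = m[["cx"]], cy = m[["cy"]], a = m[["major"]] / 2,
    b = max(m[["minor"]] / 2, 0.5), angle = m[["angle"]] %% pi)
}

#' Split an overlapped clump into constituent ellipses
#'
#' The contour is cut at concave points into segments; segments are
#' greedily merged while the joint direct least-squares fit keeps a mean
#' normalised radial residual below `residThreshold`, an axis ratio below
#' `maxAxisRatio`, and a plausible size; each final group contributes one
#' ellipse. When fewer than two concave points exist, or no valid grouping
#' is found, the whole contour is fitted as a single ellipse (fail-safe: no
#' split).
#'
#' @param mask logical matrix with one connected clump.
#' @param residThreshold grouping acceptance residual (nuclei are
#'   near-elliptical, so 0.05 is strict but attainable).
#' @param maxAxisRatio maximal `a/b` of an accepted ellipse.
#' @param minSegLen segments shorter than this are folded into their
#'   predecessor.
#' @param ... passed to [detectConcavePoints()].
#' @return list of named ellipse vectors (`cx, cy, a, b, angle`).
#' @export
splitOverlapped <- function(mask, residThreshold = 0.05, maxAxisRatio = 4,
                            minSegLen = 5, ...) {
  if (!any(mask)) stop("empty component")
  cp <- detectConcavePoints(mask, ...)
  ct <- attr(cp, "contour")
  idx <- attr(cp, "index")
  wholeFit <- function() {
    el <- fitEllipseDirect(ct)
    if (is.null(el) || el[["a"]] / el[["b"]] > maxAxisRatio)
      el <- momentsEllipseParams(mask)
    list(el)
  }
  if (length(idx) < 2) return(wholeFit())

  n <- nrow(ct)
  k <- length(idx)
  segs <- vector("list", k)
  for (j in seq_len(k)) {
    from <- idx[j]
    to <- idx[if (j == k) 1 else j + 1]
    rng <- if (to > from) from:to else c(from:n, 1:to)
    segs[[j]] <- ct[rng, , drop = FALSE]
  }
  # fold short segments into their predecessor
  lens <- vapply(segs, nrow, 0L)
  while (any(lens < minSegLen) && length(segs) > 1) {
    j <- which.min(lens)
    prev <- if (j == 1) length(segs) else j - 1
    segs[[prev]] <- rbind(segs[[prev]], segs[[j]])
    segs[[j]] <- NULL
    lens <- vapply(segs, nrow, 0L)
  }
  if (length(segs) < 2) return(wholeFit())

  maxA <- max(momentsEllipse(which(mask, arr.ind = TRUE))[["major"]], 4)
  validEl <- function(el) {
    !is.null(el) && el[["a"]] / el[["b"]] <= maxAxisRatio &&
      el[["a"]] <= maxA && el[["b"]] >= 1
  }
  groups <- segs
  jointResid <- function(g1, g2) {
    pts <- rbind(g1, g2)
    el <- fitEllipseDirect(pts)
    if (!validEl(el)) return(Inf)
    ellipseResidual(pts, el)
  }
  repeat {
    ng <- length(groups)
    if (ng < 2) break
    best <- c(Inf, 0, 0)
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
      r <- jointResid(groups[[i]], groups[[j]])
      if (r < best[1]) best <- c(r, i, j)
    }
    if (best[1] > residThreshold) break
    groups[[best[2]]] <- rbind(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }

  fits <- lapply(groups, fitEllipseDirect)
  bad <- which(!vapply(fits, validEl, logical(1)))
  # absorb unfittable groups into their best partner
  while (length(bad) && length(groups) > 1) {
    j <- bad[1]
    rs <- vapply(seq_along(groups), function(i) {
      if (i == j) return(Inf)
      pts <- rbind(groups[[i]], groups[[j]])
      el <- fitEllipseDirect(pts)
      if (is.null(el)) Inf else ellipseResidual(pts, el)
    }, numeric(1))
    tgt <- which.min(rs)
    if (!is.finite(rs[tgt])) break
    groups[[tgt]] <- rbind(groups[[tgt]], groups[[j]])
    groups[[j]] <- NULL
    fits <- lapply(groups, fitEllipseDirect)
    bad <- which(!vapply(fits, validEl, logical(1)))
  }
  if (length(groups) < 2 || length(bad)) return(wholeFit())
  fits
}

#' Classify clumps and split only the overlapped ones
#'
#' Every connected component of the mask is classified single/overlapped by
#' the shape gate; single components keep their pixels under one label,
#' overlapped components are split with [splitOverlapped()] and their
#' pixels reassigned to the nearest fitted ellipse (smallest normalised
#' radial distance). Splitting conserves pixels and output ids are
#' contiguous.
#'
#' @param mask logical matrix (postprocessed segmentation).
#' @param model overlap gate from [trainOverlapSVM()] /
#'   [defaultOverlapModel()]; `NULL` trains the default surrogate.
#' @param gate if `FALSE`, the splitter is applied to every component
#'   unconditionally (the ungated baseline).
#' @param ... passed to [splitOverlapped()].
#' @return integer label matrix with attribute `nuclei`, a `data.frame`
#'   `id, cx, cy, a, b, angle, wasSplit`.
#' @export
resolveOverlaps <- function(mask, model = NULL, gate = TRUE, ...) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  n <- max(lab)
  out <- matrix(0L, nrow(mask), ncol(mask))
  info <- NULL
  if (n == 0) {
    attr(out, "nuclei") <- data.frame(id = integer(), cx = numeric(),
                                      cy = numeric(), a = numeric(),
                                      b = numeric(), angle = numeric(),
                                      wasSplit = logical())
    return(out)
  }
  if (is.null(model) && gate) model <- defaultOverlapModel()
  nextId <- 0L
  W <- nrow(mask)
  for (id in seq_len(n)) {
    px <- which(lab == id)
    comp <- matrix(FALSE, nrow(mask), ncol(mask))
    comp[px] <- TRUE
    overlapped <- if (!gate) TRUE else {
      sd <- shapeDescriptor(comp)
      as.character(stats::predict(model, t(as.matrix(sd)))) == "overlapped"
    }
    ells <- if (overlapped) splitOverlapped(comp, ...) else
      list(momentsEllipseParams(comp))
    xs <- (px - 1L) %% W + 1L
    ys <- (px - 1L) %/% W + 1L
    if (length(ells) == 1) {
      nextId <- nextId + 1L
      out[px] <- nextId
      e <- ells[[1]]
      info <- rbind(info, data.frame(id = nextId, cx = e[["cx"]],
                                     cy = e[["cy"]], a = e[["a"]],
                                     b = e[["b"]], angle = e[["angle"]],
                                     wasSplit = FALSE))
    } else {
      dmat <- vapply(ells, function(e) {
        dx <- xs - e[["cx"]]; dy <- ys - e[["cy"]]
        co <- cos(e[["angle"]]); si <- sin(e[["angle"]])
        u <- (dx * co + dy * si) / e[["a"]]
        v <- (-dx * si + dy * co) / e[["b"]]
        sqrt(u^2 + v^2)
      }, numeric(length(px)))
      dmat <- matrix(dmat, nrow = length(px))
      assign <- max.col(-dmat)
      for (j in seq_along(ells)) {
        nextId <- nextId + 1L
        out[px[assign == j]] <- nextId
        e <- ells[[j]]
        info <- rbind(info, data.frame(id = nextId, cx = e[["cx"]],
                                       cy = e[["cy"]], a = e[["a"]],
                                       b = e[["b"]], angle = e[["angle"]],
                                       wasSplit = TRUE))
      }
    }
  }
  attr(out, "nuclei") <- info
  out
}
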