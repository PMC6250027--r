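#' Construct a synthetic-scene specification
#'
#' Defaults describe the study conditions the rest of the package is
#' exercised under: a 1024 x 1024 working canvas, a few dozen Pap-stain-like
#' dark nuclei on a pale pink-grey background with a mild illumination
#' gradient, a minority of malignant nuclei that are larger, darker and more
#' coarsely textured than benign ones, a controllable fraction of touching
#' pairs, and impulse plus Gaussian acquisition noise.
#'
#' @param width,height canvas in pixels.
#' @param nNuclei nuclei to place.
#' @param overlapFraction fraction of nuclei placed in touching pairs.
#' @param malignantFraction fraction of malignant nuclei.
#' @param radiusRangeBenign,radiusRangeMalignant mean-radius intervals (px).
#' @param darknessContrast malignant-vs-benign mean intensity gap (8-bit).
#' @param chromatinNoiseSigma per-class chromatin texture sigma
#'   `c(benign, malignant)`.
#' @param impulseNoiseDensity salt-and-pepper pixel fraction.
#' @param gaussianNoiseSigma additive Gaussian sigma (8-bit units).
#' @param seed RNG seed.
#' @return a [SceneSpec-class].
#' @examples
#' spec <- SceneSpec(width = 256, height = 256, nNuclei = 8, seed = 1)
#' scene <- generateScene(spec)
#' nucleiTable(scene)
#' @export
SceneSpec <- function(width = 1024, height = 1024, nNuclei = 50,
                      overlapFraction = 0.2, malignantFraction = 0.1,
                      radiusRangeBenign = c(10, 16),
                      radiusRangeMalignant = c(16, 26),
                      darknessContrast = 40,
                      chromatinNoiseSigma = c(5, 12),
                      impulseNoiseDensity = 0.02,
                      gaussianNoiseSigma = 3,
                      seed = 1) {
  new("SceneSpec", width = width, height = height, nNuclei = nNuclei,
      overlapFraction = overlapFraction,
      malignantFraction = malignantFraction,
      radiusRangeBenign = radiusRangeBenign,
      radiusRangeMalignant = radiusRangeMalignant,
      darknessContrast = darknessContrast,
      chromatinNoiseSigma = chromatinNoiseSigma,
      impulseNoiseDensity = impulseNoiseDensity,
      gaussianNoiseSigma = gaussianNoiseSigma, seed = seed)
}

# pixel linear indices of a filled ellipse, clipped to the canvas
ellipsePixels <- function(W, H, cx, cy, a, b, angle) {
  r <- max(a, b)
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(integer())
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / b
  inside <- which(u * u + v * v <= 1)
  (rep(ys, each = length(xs))[inside] - 1L) * W + rep(xs, length(ys))[inside]
}

#' Render a synthetic CPE scene with ground truth
#'
#' Nuclei are filled ellipses, darker than the background, carrying a
#' multiplicative low-frequency chromatin texture and per-pixel Gaussian
#' chromatin noise whose scale differs by class. Touching pairs are placed
#' with centre distance uniform in `[0.7, 1.1]` times the sum of mean radii,
#' which guarantees concave necks for the splitter. Placement is by rejection
#' sampling; an error is raised when the canvas cannot host the requested
#' count.
#'
#' @param spec a [SceneSpec-class].
#' @return a [CytoScene-class]; the noisy image is in `sceneImage()`, the
#'   noise-free render in `cleanImage()`.
#' @export
generateScene <- function(spec) {
  validObject(spec)
  withr::with_seed(as.integer(spec@seed), .renderScene(spec))
}

.renderScene <- function(spec) {
  W <- as.integer(spec@width); H <- as.integer(spec@height)
  n <- as.integer(spec@nNuclei)
  nOver <- 2L * as.integer(round(spec@overlapFraction * n / 2))
  nMal <- as.integer(round(spec@malignantFraction * n))
  classes <- rep("benign", n)
  if (nMal > 0) classes[sample.int(n, nMal)] <- "malignant"

  margin <- max(spec@radiusRangeMalignant[2], spec@radiusRangeBenign[2]) + 2
  if (2 * margin >= min(W, H))
    stop("canvas too small for the requested nucleus radii")

  drawOne <- function(class) {
    rng <- if (class == "malignant") spec@radiusRangeMalignant else
      spec@radiusRangeBenign
    r <- stats::runif(1, rng[1], rng[2])
    u <- stats::runif(1, 1, 1.3)
    list(a = r * u, b = r / u, angle = stats::runif(1, 0, pi), r = r)
  }
  collides <- function(cx, cy, a, others) {
    if (!nrow(others)) return(FALSE)
    d <- sqrt((others$cx - cx)^2 + (others$cy - cy)^2)
    any(d < 1.15 * (others$a + a))
  }

  placed <- data.frame(id = integer(), class = character(),
                       overlap = character(), cx = numeric(), cy = numeric(),
                       a = numeric(), b = numeric(), angle = numeric())
  addRow <- function(class, overlap, cx, cy, g) {
    rbind(placed, data.frame(id = nrow(placed) + 1L, class = class,
                             overlap = overlap, cx = cx, cy = cy,
                             a = g$a, b = g$b, angle = g$angle))
  }

  i <- 1L
  while (i <= n) {
    pair <- i <= nOver          # pair members come first, two at a time
    ok <- FALSE
    for (try in seq_len(400)) {
      g1 <- drawOne(classes[i])
      cx1 <- stats::runif(1, margin, W - margin)
      cy1 <- stats::runif(1, margin, H - margin)
      if (collides(cx1, cy1, g1$a, placed)) next
      if (!pair) {
        placed <- addRow(classes[i], "single", cx1, cy1, g1)
        ok <- TRUE; break
      }
      g2 <- drawOne(classes[i + 1L])
      d <- stats::runif(1, 0.7, 1.1) *
        ((g1$a + g1$b) / 2 + (g2$a + g2$b) / 2)
      th <- stats::runif(1, 0, 2 * pi)
      cx2 <- cx1 + d * cos(th); cy2 <- cy1 + d * sin(th)
      if (cx2 < margin || cx2 > W - margin ||
          cy2 < margin || cy2 > H - margin) next
      if (collides(cx2, cy2, g2$a, placed)) next
      placed <- addRow(classes[i], "overlapped", cx1, cy1, g1)
      placed <- addRow(classes[i + 1L], "overlapped", cx2, cy2, g2)
      ok <- TRUE; break
    }
    if (!ok) stop("could not place nucleus ", i,
                  ": canvas too crowded for the requested geometry")
    i <- i + if (pair) 2L else 1L
  }

  # background: pale pink-grey with a mild diagonal illumination gradient
  base <- c(235, 222, 228)
  grad <- outer(seq_len(W) / W, seq_len(H) / H, "+") - 1
  img <- array(0, c(W, H, 3))
  for (c in 1:3) img[, , c] <- base[c] + 12 * grad

  mask <- matrix(0L, W, H)
  benignBase <- c(118, 92, 148)
  for (k in seq_len(nrow(placed))) {
    p <- placed[k, ]
    px <- ellipsePixels(W, H, p$cx, p$cy, p$a, p$b, p$angle)
    if (!length(px)) next
    mask[px] <- p$id
    dark <- if (p$class == "malignant") spec@darknessContrast else 0
    sig <- spec@chromatinNoiseSigma[if (p$class == "malignant") 2 else 1]
    jit <- stats::rnorm(3, 0, 4)
    lam <- max(4, 0.7 * (p$a + p$b) / 2)
    ph <- stats::runif(2, 0, 2 * pi)
    xs <- (px - 1L) %% W + 1L
    ys <- (px - 1L) %/% W + 1L
    tex <- 1 + 0.12 * sin(2 * pi * xs / lam + ph[1]) *
      sin(2 * pi * ys / lam + ph[2])
    chroma <- stats::rnorm(length(px), 0, sig)
    for (c in 1:3) {
      val <- (benignBase[c] - dark + jit[c]) * tex + chroma
      img[, , c][px] <- val
    }
  }
  clean <- clip255(img)

  noisy <- clean
  if (spec@gaussianNoiseSigma > 0)
    noisy <- noisy + array(stats::rnorm(length(noisy), 0,
                                        spec@gaussianNoiseSigma), dim(noisy))
  if (spec@impulseNoiseDensity > 0) {
    nImp <- round(spec@impulseNoiseDensity * W * H)
    if (nImp > 0) {
      at <- sample.int(W * H, nImp)
      val <- sample(c(0, 255), nImp, replace = TRUE)
      for (c in 1:3) noisy[, , c][at] <- val
    }
  }
  noisy <- round(clip255(noisy))

  keep <- placed$id %in% unique(as.integer(mask[mask > 0]))
  new("CytoScene", image = noisy, clean = clean, mask = mask,
      nuclei = placed[keep, ], spec = spec)
}

#' Write a scene to disk
#'
#' Writes the noisy image as PNG, the instance mask as 16-bit TIFF and the
#' per-nucleus ground truth as CSV (`id,class,overlap,cx,cy,a,b,angle`).
#'
#' @param scene a [CytoScene-class].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the three file paths.
#' @export
writeScene <- function(scene, dir, name = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image = file.path(dir, paste0(name, ".png")),
             mask = file.path(dir, paste0(name, "_mask.tiff")),
             nuclei = file.path(dir, paste0(name, "_nuclei.csv")))
  writeImageRGB(scene@image, paths["image"])
  writeMask(scene@mask, paths["mask"])
  utils::write.csv(scene@nuclei, paths["nuclei"], row.names = FALSE)
  invisible(paths)
}

#' Generate a synthetic 201-column feature table
#'
#' Produces a labelled table shaped like the output of [extractFeatures()]:
#' 201 columns coded `F1`..`F201`, plus a `label` factor
#' (benign/malignant). Exactly `nInformative` columns (drawn at random,
#' returned in `attr(, "informative")`) carry class signal; the rest are
#' independent standard-normal noise.
#'
#' Two signal shapes are available. `"shift"` adds `delta` to every
#' informative column of every malignant row. `"subtypes"` assigns each
#' malignant row to one informative column (its "subtype") and shifts only
#' that column, so positives form a mixture of subpopulations and every
#' informative column contributes a roughly constant share of the attainable
#' accuracy -- a caricature of tumour heterogeneity that makes the
#' informative set uniquely identifiable.
#'
#' @param nSamples number of rows.
#' @param nInformative number of signal-carrying columns (at most 201).
#' @param imbalance positive-class (malignant) prevalence in `(0, 1)`.
#' @param seed RNG seed.
#' @param delta mean shift carried by an informative column.
#' @param signal `"shift"` or `"subtypes"`.
#' @return `data.frame` with columns `F1..F201` and `label`;
#'   `attr(, "informative")` names the signal columns.
#' @export
generateFeatureTable <- function(nSamples, nInformative = 5,
                                 imbalance = 0.5, seed = 1, delta = 2,
                                 signal = c("shift", "subtypes")) {
  signal <- match.arg(signal)
  if (nInformative > 201) stop("nInformative must be at most 201")
  nPos <- round(imbalance * nSamples)
  if (nPos < 1 || nPos > nSamples - 1)
    stop("imbalance leaves a class empty (", nPos, " positives of ",
         nSamples, ")")
  withr::with_seed(as.integer(seed), {
    x <- matrix(stats::rnorm(nSamples * 201), nSamples, 201)
    colnames(x) <- paste0("F", 1:201)
    lab <- rep("benign", nSamples)
    lab[sample.int(nSamples, nPos)] <- "malignant"
    inf <- sort(sample.int(201, nInformative))
    pos <- which(lab == "malignant")
    if (nInformative > 0) {
      if (signal == "shift") {
        x[pos, inf] <- x[pos, inf] + delta
      } else {
        sub <- sample(seq_len(nInformative), length(pos), replace = TRUE)
        x[cbind(pos, inf[sub])] <- x[cbind(pos, inf[sub])] + delta
      }
    }
    tab <- as.data.frame(x)
    tab$label <- factor(lab, levels = c("benign", "malignant"))
    attr(tab, "informative") <- paste0("F", inf)
    tab
  })
}
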