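test_that("shape descriptors behave like their geometry", {
  d <- diskMask(60, 30, 30, 20)
  sd1 <- shapeDescriptor(d)
  expect_gte(sd1[["solidity"]], 0.95)
  expect_lte(sd1[["eccentricity"]], 0.2)
  expect_equal(sd1[["equivalentDiameter"]], sqrt(4 * sum(d) / pi))

  e <- maskFromEllipses(120, list(c(60, 60, 40, 20, 0.4)))
  sd2 <- shapeDescriptor(e)
  expect_equal(sd2[["eccentricity"]], sqrt(1 - 1 / 4), tolerance = 0.03)
  expect_equal(sd2[["majorAxis"]], 80, tolerance = 2)
  expect_equal(sd2[["minorAxis"]], 40, tolerance = 2)

  fd <- fusedDisks(20, frac = 0.6)
  expect_lt(shapeDescriptor(fd$mask)[["solidity"]], sd1[["solidity"]])
  expect_error(shapeDescriptor(matrix(FALSE, 5, 5)), "empty")
})

test_that("the shape gate separates singles from fused pairs", {
  s <- makeOverlapShapeSet(n = 100, seed = 1)
  tr <- c(1:70, 101:170); te <- c(71:100, 171:200)
  mod <- trainOverlapSVM(s$shapes[tr, ], s$labels[tr], seed = 1)
  acc <- mean(predict(mod, s$shapes[te, ]) == s$labels[te])
  expect_gte(acc, 0.9)

  expect_error(trainOverlapSVM(s$shapes[1:50, ], s$labels[1:50]), "both")
  dup <- rbind(s$shapes[c(1, 1, 101, 101), ])
  expect_s3_class(trainOverlapSVM(dup, s$labels[c(1, 1, 101, 101)]), "svm")
})

test_that("concave points sit at the necks of fused disks", {
  expect_equal(nrow(detectConcavePoints(diskMask(60, 30, 30, 20))), 0)

  fd <- fusedDisks(20, frac = 0.75)  # centres 1.5 r apart
  cp <- detectConcavePoints(fd$mask)
  expect_equal(nrow(cp), 2)
  # analytic circle intersections: midway in x, +-sqrt(r^2 - (d/2)^2) in y
  mid <- colMeans(fd$centers)
  half <- sqrt(20^2 - (0.75 * 20)^2)
  want <- rbind(c(mid[1], mid[2] - half), c(mid[1], mid[2] + half))
  err <- vapply(1:2, function(i)
    min(sqrt(colSums((t(want) - cp[i, ])^2))), 0)
  expect_lt(max(err), 3)

  # three collinear fused disks: two necks, four concave points
  side <- 220
  chain <- maskFromEllipses(side, list(c(80, 110, 20, 20, 0),
                                       c(110, 110, 20, 20, 0),
                                       c(140, 110, 20, 20, 0)))
  expect_equal(nrow(detectConcavePoints(chain)), 4)
})

test_that("direct ellipse fit recovers exact ellipse points", {
  t <- seq(0, 2 * pi, length.out = 40)[-40]
  for (par in list(c(50, 60, 30, 18, 0.7), c(10, -5, 12, 11, 2.1))) {
    x <- par[1] + par[3] * cos(t) * cos(par[5]) -
      par[4] * sin(t) * sin(par[5])
    y <- par[2] + par[3] * cos(t) * sin(par[5]) +
      par[4] * sin(t) * cos(par[5])
    el <- fitEllipseDirect(cbind(x, y))
    expect_equal(el[["cx"]], par[1], tolerance = 1e-6)
    expect_equal(el[["cy"]], par[2], tolerance = 1e-6)
    expect_equal(el[["a"]], par[3], tolerance = 1e-6)
    expect_equal(el[["b"]], par[4], tolerance = 1e-6)
    expect_lt(ellipseResidual(cbind(x, y), el), 1e-9)
  }
  expect_null(fitEllipseDirect(cbind(1:10, 2 * (1:10))))  # collinear
})

test_that("splitting resolves clumps and fails safe on ellipses", {
  fd <- fusedDisks(20, frac = 0.75)
  ells <- splitOverlapped(fd$mask)
  expect_length(ells, 2)
  got <- t(vapply(ells, function(e) c(e[["cx"]], e[["cy"]]), numeric(2)))
  err <- vapply(1:2, function(i)
    min(sqrt(colSums((t(got) - fd$centers[i, ])^2))), 0)
  expect_lt(max(err), 3)

  # a single ellipse routed here returns itself
  e <- maskFromEllipses(100, list(c(50, 50, 30, 20, 0.3)))
  fit <- splitOverlapped(e)
  expect_length(fit, 1)
  expect_lt(sqrt((fit[[1]][["cx"]] - 50)^2 + (fit[[1]][["cy"]] - 50)^2), 2)

  side <- 220
  chain <- maskFromEllipses(side, list(c(80, 110, 20, 20, 0),
                                       c(110, 110, 20, 20, 0),
                                       c(140, 110, 20, 20, 0)))
  expect_length(splitOverlapped(chain), 3)
  expect_error(splitOverlapped(matrix(FALSE, 10, 10)), "empty")
})

test_that("overlap resolution conserves pixels and counts", {
  sc <- generateScene(SceneSpec(width = 320, height = 320, nNuclei = 7,
                                overlapFraction = 0, seed = 11))
  m <- instanceMask(sc) > 0
  model <- defaultOverlapModel(1)
  res <- resolveOverlaps(m, model)
  expect_equal(max(res),
               max(EBImage::bwlabel(matrix(as.numeric(m), 320, 320))))
  expect_identical(res > 0, m)          # pixel conservation
  ids <- unique(as.integer(res[res > 0]))
  expect_setequal(ids, seq_len(max(res)))

  empty <- resolveOverlaps(matrix(FALSE, 20, 20), model)
  expect_equal(max(empty), 0)
  expect_equal(nrow(attr(empty, "nuclei")), 0)
})

test_that("five singles plus two fused pairs resolve to nine nuclei", {
  side <- 420
  singles <- list(c(60, 60, 16, 12, 0.2), c(180, 70, 14, 14, 0),
                  c(320, 60, 18, 13, 1.2), c(70, 200, 15, 11, 2.0),
                  c(350, 350, 16, 16, 0))
  pairA <- list(c(180, 200, 16, 16, 0), c(204, 200, 16, 16, 0))
  pairB <- list(c(100, 330, 15, 15, 0), c(100, 353, 15, 15, 0))
  m <- maskFromEllipses(side, c(singles, pairA, pairB))
  res <- resolveOverlaps(m, defaultOverlapModel(1))
  expect_equal(max(res), 9)
  info <- attr(res, "nuclei")
  expect_equal(sum(info$wasSplit), 4)
})

test_that("gating produces no more split errors than splitting everything", {
  errsGated <- 0; errsUngated <- 0
  model <- defaultOverlapModel(1)
  for (s in 1:4) {
    sc <- generateScene(SceneSpec(width = 400, height = 400, nNuclei = 12,
                                  overlapFraction = 0.3, seed = 100 + s))
    m <- instanceMask(sc) > 0
    errsGated <- errsGated + splitError(resolveOverlaps(m, model), sc)
    errsUngated <- errsUngated +
      splitError(resolveOverlaps(m, gate = FALSE), sc)
  }
  expect_lte(errsGated, errsUngated)
})
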