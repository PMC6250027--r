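test_that("scene generation honours counts, flags and determinism", {
  spec <- SceneSpec(width = 256, height = 256, nNuclei = 10,
                    overlapFraction = 0, malignantFraction = 0.3, seed = 5)
  sc <- generateScene(spec)
  ids <- sort(unique(as.integer(instanceMask(sc)[instanceMask(sc) > 0])))
  expect_length(ids, 10)
  expect_true(all(nucleiTable(sc)$overlap == "single"))
  expect_equal(sum(nucleiTable(sc)$class == "malignant"), 3)

  sc2 <- generateScene(spec)
  expect_identical(sceneImage(sc), sceneImage(sc2))
  expect_identical(instanceMask(sc), instanceMask(sc2))

  # every positive label has exactly one ground-truth record
  expect_setequal(ids, nucleiTable(sc)$id)
})

test_that("overlap pairs share a connected clump and hit the rate", {
  fracs <- vapply(1:12, function(s) {
    sc <- generateScene(SceneSpec(width = 420, height = 420, nNuclei = 20,
                                  overlapFraction = 0.4, seed = s))
    mean(nucleiTable(sc)$overlap == "overlapped")
  }, 0)
  expect_lt(abs(mean(fracs) - 0.4), 0.1)

  sc <- generateScene(SceneSpec(width = 420, height = 420, nNuclei = 12,
                                overlapFraction = 0.5, seed = 3))
  gt <- instanceMask(sc)
  clumps <- EBImage::bwlabel(matrix(as.numeric(gt > 0), nrow(gt), ncol(gt)))
  nuc <- nucleiTable(sc)
  for (i in which(nuc$overlap == "overlapped")) {
    partnerRow <- if (i %% 2 == 1) i + 1 else i - 1
    ci <- clumps[round(nuc$cx[i]), round(nuc$cy[i])]
    cj <- clumps[round(nuc$cx[partnerRow]), round(nuc$cy[partnerRow])]
    expect_equal(ci, cj)
  }
})

test_that("rendered dark regions match the instance mask before noise", {
  sc <- generateScene(SceneSpec(width = 360, height = 360, nNuclei = 14,
                                overlapFraction = 0.3, seed = 9))
  dark <- cleanImage(sc)[, , 1] < 200
  expect_gte(diceCoefficient(dark, instanceMask(sc) > 0), 0.99)
})

test_that("class contrasts point the requested way over many nuclei", {
  nucs <- do.call(rbind, lapply(1:6, function(s) {
    sc <- generateScene(SceneSpec(width = 512, height = 512, nNuclei = 16,
                                  malignantFraction = 0.5,
                                  overlapFraction = 0, seed = s))
    gt <- instanceMask(sc)
    img <- cleanImage(sc)
    data.frame(class = nucleiTable(sc)$class,
               area = as.vector(table(gt[gt > 0])),
               dark = vapply(nucleiTable(sc)$id, function(id)
                 mean(img[, , 1][gt == id]), 0))
  }))
  expect_gte(min(table(nucs$class)), 30)
  expect_gt(mean(nucs$area[nucs$class == "malignant"]),
            mean(nucs$area[nucs$class == "benign"]))
  expect_lt(mean(nucs$dark[nucs$class == "malignant"]),
            mean(nucs$dark[nucs$class == "benign"]))
})

test_that("impossible geometry errors out instead of spinning", {
  expect_error(generateScene(SceneSpec(width = 64, height = 64,
                                       nNuclei = 200, seed = 1)),
               "crowded|too small")
})

test_that("scene io round-trips image, mask and truth table", {
  sc <- generateScene(SceneSpec(width = 128, height = 128, nNuclei = 4,
                                seed = 2))
  d <- withr::local_tempdir()
  p <- writeScene(sc, d, "s1")
  expect_true(all(file.exists(p)))
  img <- readImageRGB(p["image"])
  expect_equal(dim(img), c(128, 128, 3))
  expect_equal(max(abs(img - sceneImage(sc))), 0)
  expect_identical(readMask(p["mask"]), instanceMask(sc))
  tab <- read.csv(p["nuclei"])
  expect_equal(tab$id, nucleiTable(sc)$id)
})

test_that("synthetic feature tables carry the requested signal", {
  tab <- generateFeatureTable(1000, nInformative = 5, imbalance = 0.1,
                              seed = 1)
  expect_equal(sum(tab$label == "malignant"), 100)
  expect_equal(ncol(tab), 202)
  inf <- attr(tab, "informative")
  expect_length(inf, 5)
  shift <- colMeans(tab[tab$label == "malignant", inf]) -
    colMeans(tab[tab$label == "benign", inf])
  expect_true(all(shift > 1.5))
  noise <- setdiff(paste0("F", 1:201), inf)[1:20]
  shiftN <- colMeans(tab[tab$label == "malignant", noise]) -
    colMeans(tab[tab$label == "benign", noise])
  expect_true(all(abs(shiftN) < 0.5))

  expect_identical(generateFeatureTable(100, seed = 7),
                   generateFeatureTable(100, seed = 7))
  expect_error(generateFeatureTable(50, imbalance = 0), "class")
})

test_that("tables with no informative columns are chance-level", {
  accs <- vapply(1:5, function(s) {
    tab <- generateFeatureTable(300, nInformative = 0, imbalance = 0.5,
                                seed = s)
    n <- nrow(tab)
    tr <- seq_len(200); te <- 201:n
    fit <- rpart::rpart(label ~ ., tab[tr, c(paste0("F", 1:20), "label")],
                        method = "class")
    mean(predict(fit, tab[te, ], type = "class") == tab$label[te])
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})
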