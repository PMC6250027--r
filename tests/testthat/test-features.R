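test_that("the feature layout is 201 codes in five blocks", {
  fc <- featureCodes()
  expect_equal(nrow(fc), 201)
  expect_equal(as.integer(table(fc$block)[c("morphometric", "colorimetric",
                                            "ccfos", "glcm", "glrlm")]),
               c(14L, 6L, 49L, 88L, 44L))
  # spot checks of the derived code layout
  lay <- stats::setNames(fc$name, fc$code)
  expect_equal(lay[["F19"]], "mean_S")
  expect_equal(lay[["F25"]], "fos_R_skewness")
  expect_equal(lay[["F28"]], "fos_G_mean")
  expect_equal(lay[["F37"]], "fos_B_smoothness")
  expect_equal(lay[["F51"]], "fos_S_smoothness")
  expect_equal(lay[["F55"]], "fos_S_energy")
  expect_equal(lay[["F70"]], "glcm_autocorrelation_0")
  expect_equal(lay[["F82"]], "glcm_sum_of_square_0")
  expect_equal(lay[["F88"]], "glcm_imc1_0")
  expect_equal(lay[["F96"]], "glcm_cluster_prominence_45")
  expect_equal(lay[["F146"]], "glcm_homogeneity2_135")
  expect_equal(lay[["F163"]], "glrlm_srhge_0")
  expect_equal(lay[["F168"]], "glrlm_rp_0")
  expect_equal(lay[["F183"]], "glrlm_hgre_90")
  expect_equal(lay[["F187"]], "glrlm_lrhge_90")
})

test_that("morphometrics match geometry on a discrete disk", {
  d <- diskMask(80, 40, 40, 30)
  g <- matrix(100, 80, 80)
  f <- morphometricFeatures(d, g)
  expect_equal(f[["area"]], sum(d))
  expect_gt(f[["roundness"]], 0.85)
  expect_lt(f[["roundness"]], 1.1)
  expect_equal(f[["compactness"]], f[["roundness"]] / (4 * pi))
  expect_equal(f[["equivalent_diameter"]], sqrt(4 * sum(d) / pi))
  expect_equal(f[["diameter"]], f[["perimeter"]] / pi)
  expect_equal(f[["major_axis"]], 60, tolerance = 1.5)
  expect_equal(f[["max_intensity"]], 100)
  expect_equal(f[["min_intensity"]], 100)
  expect_equal(f[["mean_intensity"]], 100)

  e <- maskFromEllipses(120, list(c(60, 60, 40, 20, 0.3)))
  fe <- morphometricFeatures(e, matrix(0, 120, 120))
  expect_equal(fe[["eccentricity"]], sqrt(1 - 1 / 4), tolerance = 0.03)
  expect_error(morphometricFeatures(matrix(FALSE, 4, 4), matrix(0, 4, 4)),
               "empty")
})

test_that("colorimetric means land on the [0,255] component scales", {
  img <- array(0, c(10, 10, 3))
  img[, , 1] <- 255                      # pure red
  mask <- matrix(TRUE, 10, 10)
  ch <- PleuraCAD:::channelPlanes(img)
  f <- colorimetricFeatures(ch, mask)
  expect_equal(f[["mean_R"]], 255)
  expect_equal(f[["mean_G"]], 0)
  expect_equal(f[["mean_B"]], 0)
  expect_equal(f[["mean_S"]], 255)       # fully saturated

  grayimg <- array(rep(matrix(77, 10, 10), 3), c(10, 10, 3))
  fg <- colorimetricFeatures(PleuraCAD:::channelPlanes(grayimg), mask)
  expect_equal(fg[["mean_S"]], 0)        # grayscale has zero saturation
})

test_that("FOS statistics agree with direct moments on integer samples", {
  expect_equal(unname(fosStats(rep(100, 64))),
               c(100, 0, 0, 0, 0, 0, 1))
  h <- fosStats(c(rep(0, 50), rep(255, 50)))
  expect_equal(h[["mean"]], 127.5)
  expect_equal(h[["skewness"]], 0)
  expect_equal(h[["energy"]], 0.5)

  for (s in 1:10) {
    v <- withr::with_seed(s, sample(0:255, 400, replace = TRUE))
    expect_equal(unname(fosStats(v)), unname(oracleFOS(v)),
                 tolerance = 1e-6)
  }
})

test_that("GLCM matrices equal brute-force pair enumeration", {
  for (s in 1:12) {
    im <- randomMaskedImage(8, s)
    q <- quantizeGray(im$gray)
    for (a in c("0", "45", "90", "135")) {
      expect_equal(glcmMatrix(q, im$mask, a), oracleGLCM(q, im$mask, a),
                   tolerance = 1e-9)
    }
  }
})

test_that("GLCM statistics behave at the degenerate and known points", {
  q <- matrix(5L, 6, 6)
  P <- glcmMatrix(q, matrix(TRUE, 6, 6), "0")
  st <- glcmStats(P)
  expect_equal(st[["contrast"]], 0)
  expect_equal(st[["energy"]], 1)
  expect_equal(st[["entropy"]], 0)

  # alternating extremes along dim1: every 0-degree pair spans 7 levels
  g <- matrix(c(0, 255), 4, 4)
  st2 <- glcmStats(glcmMatrix(quantizeGray(g), matrix(TRUE, 4, 4), "0"))
  expect_equal(st2[["contrast"]], 49)
  # but along dim2 rows are constant
  st3 <- glcmStats(glcmMatrix(quantizeGray(g), matrix(TRUE, 4, 4), "90"))
  expect_equal(st3[["contrast"]], 0)

  expect_error(glcmMatrix(quantizeGray(matrix(1, 1, 1)),
                          matrix(TRUE, 1, 1), "0"), "too small|pair")
})

test_that("GLRLM matrices equal brute-force run enumeration", {
  for (s in 1:12) {
    im <- randomMaskedImage(8, s + 100)
    # coarser texture so runs longer than 1 appear
    q <- quantizeGray(im$gray %/% 2 + 96)
    for (a in c("0", "45", "90", "135")) {
      g1 <- glrlmMatrix(q, im$mask, a)
      g2 <- oracleGLRLM(q, im$mask, a)
      # pad to common width
      R <- max(ncol(g1), ncol(g2))
      pad <- function(g) cbind(g, matrix(0, nrow(g), R - ncol(g)))
      expect_equal(pad(unclass(g1))[, ], pad(unclass(g2))[, ],
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(sum(vapply(seq_len(ncol(g1)),
                              function(j) j * sum(g1[, j]), 0)),
                   sum(im$mask))
    }
  }
})

test_that("GLRLM statistics match hand-enumerated runs", {
  # single line g,g,x along dim1: two runs, SRE = (1/2)(1/4 + 1)
  q <- matrix(c(3L, 3L, 7L), 3, 1)
  g <- glrlmMatrix(q, matrix(TRUE, 3, 1), "0")
  st <- glrlmStats(g)
  expect_equal(sum(g), 2)
  expect_equal(st[["sre"]], 0.625)

  # constant n-pixel line: one run, RP = 1/n
  qc <- matrix(4L, 9, 1)
  stc <- glrlmStats(glrlmMatrix(qc, matrix(TRUE, 9, 1), "0"))
  expect_equal(stc[["rp"]], 1 / 9)
})

test_that("the assembled vector is 201 finite values in code order", {
  sn <- smallNucleusScene(3)
  v <- assembleFeatureVector(sn$img, sn$mask)
  expect_length(v, 201)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), paste0("F", 1:201))
  expect_length(attr(v, "featureNames"), 201)
  # textural slice F21-F201 has length 181
  expect_length(v[21:201], 181)
  # determinism
  expect_identical(v, assembleFeatureVector(sn$img, sn$mask))
})

test_that("rotating a region by 90 degrees permutes orientation blocks", {
  sn <- smallNucleusScene(5)
  v1 <- assembleFeatureVector(sn$img, sn$mask)
  v2 <- assembleFeatureVector(rot90img(sn$img), rot90mat(sn$mask))
  fc <- featureCodes()
  nm <- stats::setNames(fc$code, fc$name)
  swap <- function(name) {
    if (grepl("_0$", name)) sub("_0$", "_90", name)
    else if (grepl("_90$", name)) sub("_90$", "_0", name)
    else if (grepl("_45$", name)) sub("_45$", "_135", name)
    else sub("_135$", "_45", name)
  }
  for (name in fc$name[fc$block %in% c("glcm", "glrlm")]) {
    expect_equal(v2[[nm[[name]]]], v1[[nm[[swap(name)]]]],
                 tolerance = 1e-9)
  }
  for (code in c("F1", "F3", "F4")) {  # area, roundness, solidity
    expect_equal(v2[[code]], v1[[code]], tolerance = 1e-9)
  }
  # colour blocks are rotation-invariant outright
  expect_equal(v2[15:69], v1[15:69], tolerance = 1e-9)
})

test_that("extractFeatures tables every sufficiently large nucleus", {
  sc <- generateScene(SceneSpec(width = 220, height = 220, nNuclei = 5,
                                overlapFraction = 0, seed = 6))
  lab <- stats::setNames(nucleiTable(sc)$class, nucleiTable(sc)$id)
  tab <- extractFeatures(sceneImage(sc), instanceMask(sc),
                         labels = lab[as.character(sort(nucleiTable(sc)$id))])
  expect_equal(nrow(tab), 5)
  expect_equal(ncol(tab), 203)
  expect_true(all(is.finite(as.matrix(tab[, paste0("F", 1:201)]))))
  expect_s3_class(tab$label, "factor")
})
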