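test_that("the ensemble honours its size and is reproducible", {
  tab <- generateFeatureTable(250, nInformative = 4, imbalance = 0.3,
                              seed = 1, delta = 3)
  m <- trainECBDT(tab, nTrees = 100, seed = 7)
  expect_equal(nTrees(m), 100)
  expect_length(m@trees, 100)
  m2 <- trainECBDT(tab, nTrees = 100, seed = 7)
  expect_equal(cvMetrics(m), cvMetrics(m2))
  expect_identical(predict(m, tab), predict(m2, tab))
  expect_error(trainECBDT(tab[tab$label == "benign", ]), "both classes")
  expect_error(trainECBDT(tab, selected = c("F1", "nope")), "missing")
})

test_that("a separable table cross-validates above 95 percent", {
  tab <- generateFeatureTable(300, nInformative = 5, imbalance = 0.5,
                              seed = 4, delta = 6)
  m <- trainECBDT(tab, selected = attr(tab, "informative"), nTrees = 50,
                  seed = 1)
  expect_gte(cvMetrics(m)[["accuracy"]], 95)
})

test_that("majority voting follows the votes and breaks ties malignant", {
  vote <- PleuraCAD:::voteBag
  # stub voters with a fixed, known vote
  assign("predict.fixedvote",
         function(object, newdata, ...)
           factor(rep(object$lab, nrow(newdata)),
                  levels = c("benign", "malignant")),
         envir = globalenv())
  withr::defer(rm("predict.fixedvote", envir = globalenv()))
  mkTree <- function(lab) structure(list(lab = lab), class = "fixedvote")
  newd <- data.frame(F1 = 0.5)
  allMal <- replicate(100, mkTree("malignant"), simplify = FALSE)
  expect_equal(as.character(vote(allMal, newd)), "malignant")
  split5149 <- c(replicate(51, mkTree("benign"), simplify = FALSE),
                 replicate(49, mkTree("malignant"), simplify = FALSE))
  expect_equal(as.character(vote(split5149, newd)), "benign")
  tie <- c(replicate(50, mkTree("benign"), simplify = FALSE),
           replicate(50, mkTree("malignant"), simplify = FALSE))
  expect_equal(as.character(vote(tie, newd)), "malignant")
})

test_that("metrics implement the confusion-matrix arithmetic", {
  m <- suppressWarnings(computeMetrics(c(TP = 50, FP = 0, TN = 0, FN = 10)))
  expect_equal(m[["sensitivity"]], 100 * 50 / 60, tolerance = 1e-12)
  expect_equal(m[["recall"]], m[["sensitivity"]])

  perfect <- computeMetrics(c(TP = 5, FP = 0, TN = 20, FN = 0))
  expect_equal(as.numeric(perfect), rep(100, 6))

  # F-score is the harmonic fixed point: precision = recall = 80 -> 80
  mm <- computeMetrics(c(TP = 80, FP = 20, TN = 0, FN = 20))
  expect_equal(mm[["precision"]], 80)
  expect_equal(mm[["recall"]], 80)
  expect_equal(mm[["f_score"]], 80)

  # enumerated grid against independently coded formulas
  for (tp in c(0, 3, 17)) for (fp in c(0, 5)) for (tn in c(0, 11))
    for (fn in c(0, 7)) {
      cnt <- c(TP = tp, FP = fp, TN = tn, FN = fn)
      if (sum(cnt) == 0) next
      got <- suppressWarnings(computeMetrics(cnt))
      sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
      spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else 0
      prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
      f <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
      acc <- 100 * (tp + tn) / sum(cnt)
      expect_equal(as.numeric(got),
                   c(sens, spec, prec, sens, f, acc), tolerance = 1e-12)
    }
  expect_warning(computeMetrics(c(TP = 0, FP = 0, TN = 5, FN = 0)),
                 "zero-denominator")
  expect_error(computeMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("accuracy equals the vote-error complement on any set", {
  tab <- generateFeatureTable(200, nInformative = 3, imbalance = 0.3,
                              seed = 6, delta = 2)
  te <- seq(1, 200, by = 5)
  m <- trainECBDT(tab[-te, ], nTrees = 30, seed = 2)
  pred <- predict(m, tab[te, ])
  counts <- confusionCounts(tab$label[te], pred)
  metrics <- suppressWarnings(computeMetrics(counts))
  expect_equal(metrics[["accuracy"]],
               100 * mean(pred == tab$label[te]), tolerance = 1e-12)
})

test_that("bagging does not trail a single tree on rare positives", {
  fEns <- numeric(); fOne <- numeric()
  for (s in 1:10) {
    tab <- generateFeatureTable(600, nInformative = 5, imbalance = 0.05,
                                seed = 300 + s, delta = 3)
    te <- seq(1, 600, by = 3)
    tr <- setdiff(seq_len(600), te)
    if (nlevels(droplevels(tab$label[tr])) < 2) next
    ens <- trainECBDT(tab[tr, ], selected = attr(tab, "informative"),
                      nTrees = 60, seed = s)
    one <- trainECBDT(tab[tr, ], selected = attr(tab, "informative"),
                      nTrees = 1, seed = s)
    fm <- function(model) suppressWarnings(computeMetrics(
      confusionCounts(tab$label[te], predict(model, tab[te, ]))))[["f_score"]]
    fEns <- c(fEns, fm(ens)); fOne <- c(fOne, fm(one))
  }
  expect_gte(mean(fEns), mean(fOne))
})
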