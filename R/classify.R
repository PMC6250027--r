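# Bagged decision-tree ensemble (ECBDT) and confusion-matrix metrics.

fitBag <- function(data, nTrees) {
  n <- nrow(data)
  lapply(seq_len(nTrees), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    for (try in seq_len(20)) {
      if (nlevels(droplevels(data$label[idx])) == 2) break
      idx <- sample.int(n, n, replace = TRUE)
    }
    rpart::rpart(label ~ ., data = data[idx, , drop = FALSE],
                 method = "class",
                 control = rpart::rpart.control(cp = 0, minsplit = 5,
                                                xval = 0))
  })
}

voteBag <- function(trees, newdata, nTrees = length(trees)) {
  votes <- vapply(trees, function(tr)
    as.character(stats::predict(tr, newdata, type = "class")),
    character(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  mal <- rowSums(votes == "malignant")
  # exact 50/50 ties go to malignant: screening favours sensitivity
  factor(ifelse(2 * mal >= nTrees, "malignant", "benign"),
         levels = c("benign", "malignant"))
}

#' Train the bagged decision-tree ensemble
#'
#' Grows `nTrees` unpruned classification trees, each on an n-out-of-n
#' bootstrap resample of the training rows restricted to the selected
#' feature columns; prediction is by majority vote (exact ties toward
#' malignant). A stratified `nFolds`-fold cross-validation report on the
#' training rows is produced alongside the final model, which is trained
#' on all rows.
#'
#' @param table `data.frame` with feature columns and a two-level `label`
#'   factor (`benign`/`malignant`).
#' @param selected feature columns the model consumes (default: all `F*`
#'   columns).
#' @param nTrees ensemble size (default 100).
#' @param nFolds cross-validation folds (default 5).
#' @param seed RNG seed governing bootstraps and fold assignment.
#' @return an [EnsembleModel-class] with `cvMetrics()` in percent.
#' @export
trainECBDT <- function(table, selected = NULL, nTrees = 100, nFolds = 5,
                       seed = 1) {
  if (is.null(selected))
    selected <- grep("^F[0-9]+$", names(table), value = TRUE)
  if (!all(selected %in% names(table)))
    stop("selected features missing from table: ",
         paste(setdiff(selected, names(table)), collapse = ", "))
  y <- factor(as.character(table$label), levels = c("benign", "malignant"))
  if (nlevels(droplevels(y)) < 2) stop("both classes are required")
  data <- cbind(table[, selected, drop = FALSE], label = y)
  withr::with_seed(as.integer(seed), {
    # stratified fold assignment
    fold <- integer(nrow(data))
    for (cl in levels(y)) {
      i <- which(y == cl)
      fold[i] <- sample(rep_len(seq_len(nFolds), length(i)))
    }
    pred <- factor(rep("benign", nrow(data)),
                   levels = c("benign", "malignant"))
    for (f in seq_len(nFolds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (!length(te)) next
      trees <- fitBag(data[tr, , drop = FALSE], nTrees)
      pred[te] <- voteBag(trees, data[te, , drop = FALSE], nTrees)
    }
    counts <- confusionCounts(y, pred)
    metrics <- computeMetrics(counts)
    finalTrees <- fitBag(data, nTrees)
    new("EnsembleModel", trees = finalTrees, featureCodes = selected,
        nTrees = nTrees, cvMetrics = metrics, cvCounts = counts,
        seed = seed)
  })
}

#' Predict with a bagged ensemble
#'
#' Majority vote over the trees; an exact 50/50 tie is resolved toward
#' malignant.
#'
#' @param object an [EnsembleModel-class].
#' @param newdata `data.frame` carrying the model's feature columns.
#' @return factor of `benign`/`malignant` labels.
#' @export
setMethod("predict", "EnsembleModel", function(object, newdata) {
  miss <- setdiff(object@featureCodes, names(newdata))
  if (length(miss))
    stop("newdata lacks model columns: ", paste(miss, collapse = ", "))
  voteBag(object@trees,
          newdata[, object@featureCodes, drop = FALSE], object@nTrees)
})

#' Confusion counts with malignant as the positive class
#'
#' @param truth,pred factors/characters of `benign`/`malignant`.
#' @return named numeric `TP, FP, TN, FN`.
#' @export
confusionCounts <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  c(TP = sum(truth == "malignant" & pred == "malignant"),
    FP = sum(truth == "benign" & pred == "malignant"),
    TN = sum(truth == "benign" & pred == "benign"),
    FN = sum(truth == "malignant" & pred == "benign"))
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, recall (= sensitivity), F-score
#' `2 * precision * recall / (precision + recall)` and accuracy
#' `(TP+TN)/total`, all in percent. A ratio with zero denominator is
#' reported as 0 and flagged with a warning.
#'
#' @param counts named numeric `TP, FP, TN, FN`.
#' @return named numeric of the six metrics (percent), with attribute
#'   `undefined` naming any zero-denominator metrics.
#' @export
computeMetrics <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  if (any(is.na(counts)) || any(counts < 0)) stop("invalid counts")
  if (sum(counts) == 0) stop("all counts are zero")
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else 100 * num / den
  }
  sens <- ratio(counts["TP"], counts["TP"] + counts["FN"], "sensitivity")
  spec <- ratio(counts["TN"], counts["TN"] + counts["FP"], "specificity")
  prec <- ratio(counts["TP"], counts["TP"] + counts["FP"], "precision")
  rec <- sens
  f <- if (prec + rec == 0) {
    undefined <- c(undefined, "f_score")
    0
  } else 2 * prec * rec / (prec + rec)
  acc <- 100 * (counts["TP"] + counts["TN"]) / sum(counts)
  if (length(undefined))
    warning("zero-denominator metrics reported as 0: ",
            paste(unique(undefined), collapse = ", "))
  out <- c(sensitivity = sens, specificity = spec, precision = prec,
           recall = rec, f_score = f, accuracy = unname(acc))
  out <- stats::setNames(as.numeric(out),
                         c("sensitivity", "specificity", "precision",
                           "recall", "f_score", "accuracy"))
  attr(out, "undefined") <- unique(undefined)
  out
}
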