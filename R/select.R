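# Simulated-annealing wrapper feature selection scored by a small
# feedforward network.

#' Held-out misclassification cost of a feature subset
#'
#' Trains a 3-layer feedforward network (subset inputs, one hidden layer,
#' one logistic output; quasi-Newton BFGS optimiser via [nnet::nnet()]) on
#' a stratified split of the table restricted to the subset's columns, and
#' returns the held-out misclassification rate averaged over
#' `nRepeats` weight-initialisation restarts. The split and the restarts
#' are both functions of `seed` only, so the same subset always yields the
#' same cost.
#'
#' @param table `data.frame` with feature columns and a two-level `label`
#'   factor.
#' @param selected character vector of feature column names.
#' @param seed RNG seed.
#' @param hiddenUnits hidden-layer size (default 10).
#' @param nRepeats restarts averaged into the cost (default 3, damping
#'   initialisation variance).
#' @param holdout held-out fraction of rows.
#' @param maxit optimiser iteration cap.
#' @return misclassification rate in `[0, 1]`.
#' @export
annCost <- function(table, selected, seed = 1, hiddenUnits = 10,
                    nRepeats = 3, holdout = 0.3, maxit = 100) {
  y <- table$label
  if (nlevels(droplevels(factor(y))) < 2)
    stop("both classes are required to score a subset")
  x <- as.matrix(table[, selected, drop = FALSE])
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  sg[sg == 0] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sg, "/")
  pos <- as.integer(y == levels(factor(y))[2])
  te <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_along(pos), pos), function(i)
      i[sample.int(length(i), max(1, round(holdout * length(i))))]))
  })
  tr <- setdiff(seq_along(pos), te)
  errs <- vapply(seq_len(nRepeats), function(r) {
    fit <- withr::with_seed(as.integer(seed) + r,
      nnet::nnet(x[tr, , drop = FALSE], pos[tr], size = hiddenUnits,
                 entropy = TRUE, decay = 1e-3, maxit = maxit,
                 trace = FALSE))
    pred <- as.integer(stats::predict(fit, x[te, , drop = FALSE]) > 0.5)
    mean(pred != pos[te])
  }, 0)
  mean(errs)
}

#' Neighbouring subset: swap one selected for one unselected feature
#'
#' Uses the current RNG stream; both the dropped and the added code are
#' chosen uniformly. Cardinality is preserved.
#'
#' @param selected character vector, the current subset.
#' @param pool character vector of all candidate codes.
#' @return character vector of the same length as `selected`.
#' @export
neighborSubset <- function(selected, pool) {
  unsel <- setdiff(pool, selected)
  if (!length(unsel))
    stop("no unselected feature to swap in (subset covers the pool)")
  drop <- selected[sample.int(length(selected), 1)]
  add <- unsel[sample.int(length(unsel), 1)]
  c(setdiff(selected, drop), add)
}

#' Simulated-annealing feature selection
#'
#' Classic annealing over fixed-cardinality subsets: start from a random
#' subset of size `nf`, propose a one-swap neighbour each iteration,
#' accept downhill moves always and uphill moves with probability
#' `exp(-delta / T)`; the temperature cools geometrically,
#' `T_k = temp0 * alpha^k` after `k` iterations. The best subset ever
#' visited is returned. Defaults follow the pipeline's operating point:
#' `maxIt = 50`, `temp0 = 10`, `alpha = 0.99`, `nf = 20`.
#'
#' @inheritParams annCost
#' @param nf subset cardinality.
#' @param maxIt number of iterations.
#' @param temp0 initial temperature.
#' @param alpha geometric cooling rate in `(0, 1)`; `alpha = 0` degenerates
#'   to greedy descent after the first iteration.
#' @param pool candidate feature codes (default: all `F*` columns of
#'   `table`).
#' @return a [FeatureSubset-class]; `costTrace()` holds the per-iteration
#'   temperature and current/best cost.
#' @export
annealFeatures <- function(table, nf = 20, maxIt = 50, temp0 = 10,
                           alpha = 0.99, hiddenUnits = 10, nRepeats = 3,
                           holdout = 0.3, maxit = 100, seed = 1,
                           pool = NULL) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (is.null(pool)) pool <- grep("^F[0-9]+$", names(table), value = TRUE)
  if (nf < 1 || nf > length(pool))
    stop("nf must lie between 1 and the pool size")
  cost <- function(s) annCost(table, s, seed = seed,
                              hiddenUnits = hiddenUnits,
                              nRepeats = nRepeats, holdout = holdout,
                              maxit = maxit)
  withr::with_seed(as.integer(seed), {
    cur <- sample(pool, nf)
    curCost <- cost(cur)
    best <- cur; bestCost <- curCost
    Temp <- temp0
    trace <- data.frame(iteration = 0, temperature = Temp,
                        currentCost = curCost, bestCost = bestCost)
    for (it in seq_len(maxIt)) {
      cand <- neighborSubset(cur, pool)
      candCost <- cost(cand)
      delta <- candCost - curCost
      accept <- delta <= 0 ||
        (Temp > 0 && stats::runif(1) < exp(-delta / Temp))
      if (accept) {
        cur <- cand; curCost <- candCost
      }
      if (curCost < bestCost) {
        best <- cur; bestCost <- curCost
      }
      Temp <- alpha * Temp
      trace <- rbind(trace, data.frame(iteration = it, temperature = Temp,
                                       currentCost = curCost,
                                       bestCost = bestCost))
    }
    new("FeatureSubset", selected = sort(best), cost = bestCost,
        trace = trace, seed = seed)
  })
}
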