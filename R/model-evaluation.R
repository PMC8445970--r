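#' Cross-validation configuration
#'
#' Replicated stratified k-fold CV: replication r derives its fold-shuffle
#' and learner seed as \code{baseSeed + r}, so every run is reproducible
#' and candidate evaluations can share paired seeds.
#'
#' @param k number of folds (10 throughout the pipeline).
#' @param reps number of replications.
#' @param baseSeed integer base seed.
#' @param stratified stratify folds by class (recommended: with 27
#'   positives among 90 molecules, unstratified 10-fold CV can produce
#'   positive-free folds).
#' @return an object of class \code{CVConfig}.
#' @export
cvConfig <- function(k = 10L, reps = 100L, baseSeed = 1L, stratified = TRUE) {
  stopifnot(k >= 2L, reps >= 1L)
  structure(list(k = as.integer(k), reps = as.integer(reps),
                 baseSeed = as.integer(baseSeed),
                 stratified = isTRUE(stratified)),
            class = "CVConfig")
}

# Fold assignment: within each class, fold labels 1..k are dealt as evenly
# as possible (counts differ by at most one) and shuffled, so per-fold
# class proportions deviate from the global ones by at most one molecule.
.makeFolds <- function(y, k, seed, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  rng <- .withSeed(seed, {
    if (stratified) {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
  rng
}

# evaluate expr with a local RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# One k-fold pass: returns pooled test accuracy in percent. Training folds
# must contain both classes; if one is absent (possible unstratified) the
# caller re-draws.
.cvOnePass <- function(X, y, w, spec, folds, k) {
  correct <- 0L
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test)) next
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L) return(NA_real_)  # flag for re-draw
    model <- .fitModel(spec, X[!test, , drop = FALSE], ytr, w[!test])
    pred <- .predictModel(model, X[test, , drop = FALSE])
    correct <- correct + sum(pred == y[test])
  }
  100 * correct / length(y)
}

#' Replicated stratified k-fold cross-validation
#'
#' Runs \code{cv$reps} replications of k-fold CV for one estimator on one
#' feature set. Each replication reshuffles the (stratified) fold
#' assignment and reseeds the learner with \code{baseSeed + r}. Training
#' applies the inverse-class-size sample weights; the reported accuracy is
#' the plain unweighted fraction of correct test predictions, in percent,
#' pooled over the k folds. Replications whose training folds lose a class
#' are flagged and re-drawn with a shifted seed.
#'
#' @param x a labeled, cleaned \linkS4class{DescriptorSet}.
#' @param features character vector of descriptor names to use.
#' @param estimator an \code{\link{estimatorSpec}} (tuned or default).
#' @param cv a \code{\link{cvConfig}}.
#' @return an object of class \code{CVResult}: list with
#'   \code{perRepAccuracy} (percent, length \code{reps}), \code{mean},
#'   \code{max} and \code{std} (sample standard deviation).
#' @export
repeatedCV <- function(x, features, estimator, cv = cvConfig()) {
  stopifnot(inherits(cv, "CVConfig"))
  .assertBothClasses(x)
  missing <- setdiff(features, descriptorNames(x))
  if (length(missing))
    stop("features absent from dataset: ", paste(missing, collapse = ", "))
  X <- descriptorMatrix(x)[, features, drop = FALSE]
  y <- classLabels(x)
  w <- sampleWeights(x)
  acc <- numeric(cv$reps)
  for (r in seq_len(cv$reps)) {
    s <- cv$baseSeed + r
    repeat {
      folds <- .makeFolds(y, cv$k, s, cv$stratified)
      spec <- estimatorSpec(estimator$family, estimator$params, seed = s)
      a <- .cvOnePass(X, y, w, spec, folds, cv$k)
      if (!is.na(a)) break
      s <- s + 104729L   # re-draw on a class-free training fold
    }
    acc[r] <- a
  }
  .cvResult(acc)
}

.cvResult <- function(acc) {
  structure(list(perRepAccuracy = acc,
                 mean = mean(acc),
                 max = max(acc),
                 std = if (length(acc) > 1L) stats::sd(acc) else 0),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult: %d replications, mean %.2f%%, max %.2f%%, sd %.2f\n",
              length(x$perRepAccuracy), x$mean, x$max, x$std))
  invisible(x)
}

#' Exhaustive grid-search hyperparameter tuning
#'
#' Evaluates every combination in the Cartesian product of the grid by
#' replicated k-fold CV and returns the combination maximizing mean
#' accuracy. Ties prefer the smaller model: lower \code{max_depth}
#' (unlimited counts as largest), then fewer \code{n_estimators}, then
#' grid order.
#'
#' @param x a labeled, cleaned \linkS4class{DescriptorSet}.
#' @param features feature set (character vector).
#' @param family estimator family.
#' @param grid named list of parameter values, e.g. from
#'   \code{\link{defaultGrid}}.
#' @param cv a \code{\link{cvConfig}} used for every combination (shared
#'   seeds make the comparison paired).
#' @param seed learner seed recorded in the returned spec.
#' @return list with \code{best} (an \code{EstimatorSpec}), \code{mean}
#'   (its mean CV accuracy) and \code{results} (data.frame of all
#'   combinations with their mean/max/std accuracy).
#' @export
gridSearchTune <- function(x, features, family, grid, cv = cvConfig(reps = 10L),
                           seed = 1L) {
  if (!length(grid)) stop("empty grid")
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- data.frame(combos, mean = NA_real_, max = NA_real_, std = NA_real_,
                    check.names = FALSE)
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, , drop = FALSE])
    cvr <- repeatedCV(x, features, estimatorSpec(family, params, seed), cv)
    res$mean[i] <- cvr$mean; res$max[i] <- cvr$max; res$std[i] <- cvr$std
  }
  depth <- if ("max_depth" %in% names(res))
    ifelse(is.na(res$max_depth), Inf, res$max_depth) else rep(0, nrow(res))
  ntree <- if ("n_estimators" %in% names(res)) res$n_estimators else rep(0, nrow(res))
  best <- order(-res$mean, depth, ntree, seq_len(nrow(res)))[1L]
  list(best = estimatorSpec(family, as.list(combos[best, , drop = FALSE]), seed),
       mean = res$mean[best],
       results = res)
}

#' High-replication final validation with a normal fit
#'
#' Runs \code{reps} CV replications (10,000 in the full-scale protocol) on
#' the final feature set and estimator, then summarizes the accuracy
#' distribution by its moment-fitted normal (mu = sample mean,
#' sigma = sample standard deviation) and a histogram.
#'
#' @param x a labeled, cleaned \linkS4class{DescriptorSet}.
#' @param features final feature set.
#' @param estimator tuned \code{\link{estimatorSpec}}.
#' @param reps replication count.
#' @param k folds.
#' @param baseSeed base seed.
#' @return list with \code{cv} (a \code{CVResult}) and \code{distribution}
#'   (list: \code{mu}, \code{sigma}, \code{breaks}, \code{counts}).
#' @export
finalValidation <- function(x, features, estimator, reps = 10000L, k = 10L,
                            baseSeed = 1L) {
  cvr <- repeatedCV(x, features, estimator,
                    cvConfig(k = k, reps = reps, baseSeed = baseSeed))
  h <- graphics::hist(cvr$perRepAccuracy, plot = FALSE)
  list(cv = cvr,
       distribution = list(mu = cvr$mean, sigma = cvr$std,
                           breaks = h$breaks, counts = h$counts))
}
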