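#' Recursive feature elimination
#'
#' Importance-ranked backward elimination: the estimator is trained on the
#' current feature set with the class-weighted samples, features are ranked
#' by the learner's internal split-gain (impurity-decrease) importance, and
#' the least important \code{step} features are discarded; this repeats
#' until every feature has been assigned a position in the elimination
#' order. Ties in importance are broken deterministically by eliminating
#' the lexicographically last of the tied names. The full ordering (first
#' eliminated to last surviving) supports nested-set slicing at any
#' cardinality via \code{\link{cardinalitySweep}}.
#'
#' @param x a labeled, cleaned \linkS4class{DescriptorSet} (finite values,
#'   no constant descriptors).
#' @param estimator an \code{\link{estimatorSpec}}; ranking uses its
#'   default-but-seeded parameters (per-set tuning happens afterwards).
#' @param step number of features eliminated per round (default 1, which
#'   yields fully nested sets). Values above 1 speed up the ranking of very
#'   wide tables; within a round, eliminated features are ordered by
#'   ascending importance, so the elimination order stays a total order
#'   and every cardinality slice remains nested.
#' @param fineBelow once the surviving set is at or below this size,
#'   elimination reverts to one feature per round regardless of
#'   \code{step}, so the orderings that matter for a cardinality sweep are
#'   re-evaluated feature by feature. 0 (default) applies \code{step}
#'   throughout.
#' @return an object of class \code{FeatureRanking}: list with
#'   \code{eliminationOrder} (character, first eliminated first) and
#'   \code{estimator}.
#' @export
rankFeaturesRFE <- function(x, estimator, step = 1L, fineBelow = 0L) {
  stopifnot(inherits(estimator, "EstimatorSpec"), step >= 1L)
  .assertBothClasses(x)
  X <- descriptorMatrix(x)
  if (ncol(X) < 2L) stop("need at least 2 features to rank")
  y <- classLabels(x)
  w <- sampleWeights(x)
  current <- colnames(X)
  eliminated <- character(0)
  while (length(current) > 1L) {
    model <- .fitModel(estimator, X[, current, drop = FALSE], y, w)
    imp <- .modelImportance(model)
    s <- if (length(current) > fineBelow) step else 1L
    # eliminate the `s` least important; within importance ties the
    # lexicographically last name goes first
    ord <- order(imp, -rank(names(imp)))   # ascending importance, rev name
    drop <- names(imp)[ord[seq_len(min(s, length(current) - 1L))]]
    eliminated <- c(eliminated, drop)
    current <- setdiff(current, drop)
  }
  structure(list(eliminationOrder = c(eliminated, current),
                 estimator = estimator),
            class = "FeatureRanking")
}

#' @export
print.FeatureRanking <- function(x, ...) {
  p <- length(x$eliminationOrder)
  cat("FeatureRanking over", p, "features (", x$estimator$family, ")\n")
  cat("  last surviving:",
      paste(utils::tail(x$eliminationOrder, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' Nested feature sets over a cardinality range
#'
#' Slices a \code{\link{rankFeaturesRFE}} ordering into one feature set per
#' cardinality k in \code{kMin:kMax}; set k holds the k last-surviving
#' features, so the sets are nested (set(k) is a subset of set(k+1)).
#' The default 2-20 range gives the 19 candidate sets evaluated per
#' estimator family in the accuracy sweep.
#'
#' @param ranking a \code{FeatureRanking}.
#' @param kMin,kMax inclusive cardinality bounds; \code{kMax} must not
#'   exceed the number of ranked features.
#' @return named list of character vectors ("2", "3", ...), each ordered
#'   most-important (last-surviving) first.
#' @export
cardinalitySweep <- function(ranking, kMin = 2L, kMax = 20L) {
  stopifnot(inherits(ranking, "FeatureRanking"))
  p <- length(ranking$eliminationOrder)
  if (kMax > p) stop("kMax (", kMax, ") exceeds number of features (", p, ")")
  if (kMin < 1L || kMin > kMax) stop("need 1 <= kMin <= kMax")
  sets <- lapply(kMin:kMax, function(k)
    rev(utils::tail(ranking$eliminationOrder, k)))
  stats::setNames(sets, kMin:kMax)
}
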