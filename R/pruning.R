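#' Greedy backward feature pruning with per-step retuning
#'
#' Starting from a selected feature set, each step evaluates every
#' single-feature deletion by replicated k-fold CV (all candidates share
#' the same replication seeds, so comparisons are paired) and prunes the
#' deletion with the highest mean accuracy. Ties prune the candidate with
#' the smaller accuracy standard deviation, then the lexicographically
#' first name. Pruning continues until the mean accuracy has declined for
#' \code{extraSteps} consecutive steps (so the decline past the peak is
#' visible in the trace) or the cardinality
#' reaches 2; the returned best set is the argmax of mean accuracy over
#' all evaluated steps. If \code{retune} names hyperparameters, a 1-D
#' grid over each is re-run on the surviving set after every pruning step
#' (e.g. retuning \code{max_depth} once the set shrinks).
#'
#' @param x a labeled, cleaned \linkS4class{DescriptorSet}.
#' @param startSet character vector of feature names (cardinality >= 2),
#'   a subset of the dataset's descriptors.
#' @param estimator tuned \code{\link{estimatorSpec}} for the start set.
#' @param cv a \code{\link{cvConfig}}; its seeds are reused for every
#'   candidate within a step.
#' @param extraSteps consecutive declining steps tolerated before stopping.
#' @param retune character vector of parameter names to retune per step.
#' @param retuneGrid named list of candidate values per retuned parameter;
#'   defaults to the matching axis of \code{\link{defaultGrid}}.
#' @return an object of class \code{PruningTrace}: list with \code{steps}
#'   (data.frame: Features, Removed, Max, Mean, Std.Dev), \code{bestSet},
#'   \code{bestCardinality}, and \code{estimator} (params after the last
#'   retune).
#' @export
backwardPrune <- function(x, startSet, estimator, cv = cvConfig(),
                          extraSteps = 2L, retune = character(0),
                          retuneGrid = NULL) {
  missing <- setdiff(startSet, descriptorNames(x))
  if (length(missing))
    stop("start set features absent from dataset: ",
         paste(missing, collapse = ", "))
  if (length(startSet) < 2L) stop("start set must contain at least 2 features")

  current <- startSet
  spec <- estimator
  base <- repeatedCV(x, current, spec, cv)
  steps <- data.frame(Features = length(current), Removed = NA_character_,
                      Max = base$max, Mean = base$mean, Std.Dev = base$std,
                      stringsAsFactors = FALSE)
  sets <- list(current)
  decline <- 0L
  lastMean <- base$mean

  while (length(current) > 2L && decline < extraSteps) {
    cand <- .evaluateDeletions(x, current, spec, cv)
    pick <- order(-cand$mean, cand$std, cand$feature)[1L]
    removed <- cand$feature[pick]
    current <- setdiff(current, removed)
    if (length(retune))
      spec <- .retune1D(x, current, spec, retune, retuneGrid, cv)
    steps <- rbind(steps, data.frame(
      Features = length(current), Removed = removed,
      Max = cand$max[pick], Mean = cand$mean[pick], Std.Dev = cand$std[pick],
      stringsAsFactors = FALSE))
    sets[[length(sets) + 1L]] <- current
    decline <- if (cand$mean[pick] < lastMean) decline + 1L else 0L
    lastMean <- cand$mean[pick]
  }
  bestIdx <- which.max(steps$Mean)
  structure(list(steps = steps,
                 bestSet = sets[[bestIdx]],
                 bestCardinality = steps$Features[bestIdx],
                 estimator = spec),
            class = "PruningTrace")
}

# mean/max/std of replicated CV for every single-feature deletion,
# all candidates under the identical cv seeds (paired comparison)
.evaluateDeletions <- function(x, current, spec, cv) {
  out <- data.frame(feature = current, mean = NA_real_, max = NA_real_,
                    std = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(current)) {
    cvr <- repeatedCV(x, setdiff(current, current[i]), spec, cv)
    out$mean[i] <- cvr$mean; out$max[i] <- cvr$max; out$std[i] <- cvr$std
  }
  out
}

# 1-D sweep over each named parameter, holding the others fixed
.retune1D <- function(x, features, spec, retune, retuneGrid, cv) {
  for (par in retune) {
    vals <- retuneGrid[[par]]
    if (is.null(vals)) vals <- defaultGrid(spec$family, length(features))[[par]]
    if (is.null(vals)) stop("no retune grid for parameter ", par)
    grid <- list(vals); names(grid) <- par
    fixed <- spec$params[setdiff(names(spec$params), par)]
    best <- NULL; bestMean <- -Inf
    for (v in vals) {
      params <- c(fixed, stats::setNames(list(v), par))
      cvr <- repeatedCV(x, features, estimatorSpec(spec$family, params, spec$seed), cv)
      if (cvr$mean > bestMean) { bestMean <- cvr$mean; best <- params }
    }
    spec <- estimatorSpec(spec$family, best, spec$seed)
  }
  spec
}

#' @export
print.PruningTrace <- function(x, ...) {
  cat("PruningTrace:", nrow(x$steps), "steps; best cardinality",
      x$bestCardinality, sprintf("(mean %.2f%%)\n", max(x$steps$Mean)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}
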