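#' Configuration for a full descriptor-selection run
#'
#' Bundles everything \code{\link{runWorkflow}} needs: the labeled input
#' (a \linkS4class{DescriptorSet} or a \code{\link{syntheticSpec}} to
#' generate one), the estimator families to sweep, the cardinality range,
#' replication counts, the tuning mode, the parsimony tolerance used when
#' choosing the final (family, cardinality), and the base seed from which
#' every stage derives its randomness.
#'
#' @param dataset a labeled \linkS4class{DescriptorSet}; mutually
#'   exclusive with \code{synthetic}.
#' @param synthetic a \code{\link{syntheticSpec}} to generate the input.
#' @param families estimator families to sweep (default: all four).
#' @param kMin,kMax cardinality range for the RFE sweep (default 2-20).
#' @param cvReps CV replications per (cardinality, family) cell and per
#'   pruning candidate (full-scale protocol: 100).
#' @param tune \code{"none"} (default-but-seeded parameters),
#'   \code{"coarse"} (small grid) or \code{"full"}
#'   (\code{\link{defaultGrid}}).
#' @param tuneReps CV replications per grid-search combination.
#' @param finalReps replications of the final validation (full-scale
#'   protocol: 10,000).
#' @param parsimonyTolerance accuracy margin (percentage points) within
#'   which a smaller feature set is preferred over the argmax.
#' @param pruneExtraSteps consecutive declining pruning steps tolerated
#'   before stopping.
#' @param pruneRetune parameter names retuned (1-D) after each pruning
#'   step, e.g. \code{"max_depth"}.
#' @param rfeStep features eliminated per RFE round while the surviving
#'   set is still above twice \code{kMax}; below that, elimination is
#'   always one per round (see \code{\link{rankFeaturesRFE}}). Default 1.
#' @param baseSeed integer master seed.
#' @param quiet suppress progress messages.
#' @return an object of class \code{RunConfig}.
#' @export
runConfig <- function(dataset = NULL, synthetic = NULL,
                      families = c("decision_tree", "random_forest",
                                   "extra_trees", "gradient_boosting"),
                      kMin = 2L, kMax = 20L, cvReps = 100L,
                      tune = c("none", "coarse", "full"), tuneReps = 5L,
                      finalReps = 10000L, parsimonyTolerance = 0.5,
                      pruneExtraSteps = 2L, pruneRetune = character(0),
                      rfeStep = 1L, baseSeed = 1L, quiet = FALSE) {
  tune <- match.arg(tune)
  families <- match.arg(families, .estimatorFamilies, several.ok = TRUE)
  if (is.null(dataset) == is.null(synthetic))
    stop("provide exactly one of `dataset` or `synthetic`")
  structure(list(dataset = dataset, synthetic = synthetic,
                 families = families, kMin = as.integer(kMin),
                 kMax = as.integer(kMax), cvReps = as.integer(cvReps),
                 tune = tune, tuneReps = as.integer(tuneReps),
                 finalReps = as.integer(finalReps),
                 parsimonyTolerance = parsimonyTolerance,
                 pruneExtraSteps = as.integer(pruneExtraSteps),
                 pruneRetune = pruneRetune, rfeStep = as.integer(rfeStep),
                 baseSeed = as.integer(baseSeed),
                 quiet = isTRUE(quiet)),
            class = "RunConfig")
}

#' Run the full descriptor-selection workflow
#'
#' Executes the pipeline end to end: clean the feature space (non-finite
#' then constant descriptors), compute inverse-class-size weights, rank
#' descriptors by RFE per estimator family, evaluate the 2-20 cardinality
#' sweep by replicated stratified 10-fold CV (optionally grid-tuning each
#' cell first), choose the (family, cardinality) by maximum mean accuracy
#' with a parsimony tolerance (within the tolerance, the smallest set
#' wins), greedily backward-prune the chosen set, and validate the pruned
#' set with a high-replication CV and a moment-fitted normal summary.
#'
#' @param config a \code{\link{runConfig}}.
#' @return an object of class \code{RunReport}: list with \code{cleaning},
#'   \code{classWeights}, \code{accuracyMean}/\code{accuracyMax}/
#'   \code{accuracyStd} (cardinality x family data.frames),
#'   \code{sweepSets}, \code{tunedParams}, \code{chosenFamily},
#'   \code{chosenCardinality}, \code{pruning} (a \code{PruningTrace}),
#'   \code{final} (CVResult + distribution), \code{selectedFeatures},
#'   \code{truth} (for synthetic inputs) and \code{config}.
#' @export
runWorkflow <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  note <- function(...) if (!config$quiet) message("[qsarselect] ", ...)

  truth <- NULL
  ds <- config$dataset
  if (is.null(ds)) {
    note("stage synthetic: generating dataset (seed ", config$synthetic$seed, ")")
    gen <- generateDataset(config$synthetic)
    ds <- gen$dataset; truth <- gen$truth
  }
  .assertBothClasses(ds)

  note("stage clean: ", nrow(ds), " descriptors in")
  ds <- dropConstantFeatures(dropNonfiniteFeatures(ds))
  cleaning <- cleaningReport(ds)
  note("stage clean: ", cleaning$nFeaturesAfter, " retained (",
       length(cleaning$removedConstant), " constant, ",
       length(cleaning$removedNonfinite), " non-finite removed)")
  if (config$kMax > nrow(ds))
    stop("kMax (", config$kMax, ") exceeds cleaned feature count (", nrow(ds), ")")

  weights <- computeClassWeights(ds)
  note(sprintf("stage weights: positive %.2f, negative %.2f",
               weights[["positive"]], weights[["negative"]]))

  ks <- config$kMin:config$kMax
  fam <- config$families
  mk <- function() matrix(NA_real_, length(ks), length(fam),
                          dimnames = list(ks, fam))
  accMean <- mk(); accMax <- mk(); accStd <- mk()
  sweepSets <- list(); tunedParams <- list()

  for (fi in seq_along(fam)) {
    family <- fam[fi]
    note("stage rfe [", family, "]: ranking ", nrow(ds), " descriptors")
    ranking <- rankFeaturesRFE(ds, estimatorSpec(family, seed = config$baseSeed),
                               step = config$rfeStep,
                               fineBelow = 2L * config$kMax)
    sets <- cardinalitySweep(ranking, config$kMin, config$kMax)
    sweepSets[[family]] <- sets
    tunedParams[[family]] <- list()
    for (k in ks) {
      seedFK <- config$baseSeed + 1000L * fi + k
      feats <- sets[[as.character(k)]]
      spec <- estimatorSpec(family, seed = seedFK)
      if (config$tune != "none") {
        grid <- if (config$tune == "full") defaultGrid(family, k)
                else coarseGrid(family, k)
        tuned <- gridSearchTune(ds, feats, family, grid,
                                cvConfig(reps = config$tuneReps,
                                         baseSeed = seedFK + 500000L),
                                seed = seedFK)
        spec <- tuned$best
      }
      tunedParams[[family]][[as.character(k)]] <- spec$params
      cvr <- repeatedCV(ds, feats, spec,
                        cvConfig(reps = config$cvReps, baseSeed = seedFK))
      i <- match(k, ks)
      accMean[i, fi] <- cvr$mean; accMax[i, fi] <- cvr$max
      accStd[i, fi] <- cvr$std
    }
    note(sprintf("stage sweep [%s]: best mean %.2f%% at k=%d", family,
                 max(accMean[, fi]), ks[which.max(accMean[, fi])]))
  }

  choice <- .chooseParsimonious(accMean, ks, fam, config$parsimonyTolerance)
  note("stage select: ", choice$family, " with ", choice$k, " features")
  chosenSet <- sweepSets[[choice$family]][[as.character(choice$k)]]
  chosenSpec <- estimatorSpec(choice$family,
                              tunedParams[[choice$family]][[as.character(choice$k)]],
                              seed = config$baseSeed + 77L)

  note("stage prune: backward elimination from ", length(chosenSet), " features")
  trace <- backwardPrune(ds, chosenSet, chosenSpec,
                         cvConfig(reps = config$cvReps,
                                  baseSeed = config$baseSeed + 900000L),
                         extraSteps = config$pruneExtraSteps,
                         retune = config$pruneRetune)
  note("stage prune: best cardinality ", trace$bestCardinality)

  note("stage validate: ", config$finalReps, " replications")
  fin <- finalValidation(ds, trace$bestSet, trace$estimator,
                         reps = config$finalReps,
                         baseSeed = config$baseSeed + 1500000L)

  structure(list(cleaning = cleaning, classWeights = weights,
                 accuracyMean = as.data.frame(accMean),
                 accuracyMax = as.data.frame(accMax),
                 accuracyStd = as.data.frame(accStd),
                 sweepSets = sweepSets, tunedParams = tunedParams,
                 chosenFamily = choice$family, chosenCardinality = choice$k,
                 pruning = trace, final = fin,
                 selectedFeatures = trace$bestSet,
                 dataset = ds, truth = truth, config = config),
            class = "RunReport")
}

# maximum mean accuracy with a parsimony override: among all cells within
# `tol` percentage points of the maximum, take the smallest cardinality;
# ties there resolve to the higher mean, then family order
.chooseParsimonious <- function(accMean, ks, fam, tol) {
  best <- max(accMean)
  cand <- which(accMean >= best - tol, arr.ind = TRUE)
  ord <- order(ks[cand[, 1L]], -accMean[cand], cand[, 2L])
  pick <- cand[ord[1L], ]
  list(family = fam[pick[2L]], k = ks[pick[1L]])
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport\n")
  cat(sprintf("  weights: positive %.2f / negative %.2f\n",
              x$classWeights[["positive"]], x$classWeights[["negative"]]))
  cat("  sweep:", nrow(x$accuracyMean), "cardinalities x",
      ncol(x$accuracyMean), "families\n")
  cat("  chosen:", x$chosenFamily, "with", x$chosenCardinality, "features\n")
  cat(sprintf("  pruned to %d features; final mean accuracy %.2f%% (sd %.2f)\n",
              length(x$selectedFeatures), x$final$cv$mean, x$final$cv$std))
  invisible(x)
}

#' Export a RunReport as CSV/JSON/DOT files
#'
#' Writes the accuracy matrices in the conventional table layout (one row per
#' cardinality, one column per family), the pruning trace with columns
#' Features/Removed/Max/Mean/Std.Dev, the final-validation histogram, the
#' selected descriptor list, cleaning and weight metadata, and — when the
#' chosen family is a single decision tree — the tree refit on the full
#' dataset in Graphviz DOT format. Re-exporting the same report is
#' idempotent.
#'
#' @param report a \code{RunReport}.
#' @param outdir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
exportReports <- function(report, outdir) {
  stopifnot(inherits(report, "RunReport"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name, rn = FALSE) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = rn, quote = FALSE)
    paths <<- c(paths, p)
  }
  addFeatures <- function(m) cbind(Features = rownames(m), as.data.frame(m))
  wcsv(addFeatures(report$accuracyMean), "accuracy_mean.csv")
  wcsv(addFeatures(report$accuracyMax), "accuracy_max.csv")
  wcsv(addFeatures(report$accuracyStd), "accuracy_std.csv")
  wcsv(report$pruning$steps, "pruning_trace.csv")
  d <- report$final$distribution
  wcsv(data.frame(bin_left = utils::head(d$breaks, -1L),
                  bin_right = d$breaks[-1L], count = d$counts),
       "final_histogram.csv")

  wjson <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
  }
  wjson(list(selected = report$selectedFeatures,
             family = report$chosenFamily,
             params = report$pruning$estimator$params,
             finalMean = report$final$cv$mean,
             finalMax = report$final$cv$max,
             finalStd = report$final$cv$std), "selected_features.json")
  wjson(report$cleaning, "cleaning.json")
  wjson(list(positive = report$classWeights[["positive"]],
             negative = report$classWeights[["negative"]]),
        "class_weights.json")
  cfg <- report$config
  wjson(cfg[setdiff(names(cfg), c("dataset", "synthetic"))], "config.json")

  if (report$chosenFamily == "decision_tree") {
    model <- .fitModel(report$pruning$estimator,
                       descriptorMatrix(report$dataset)[, report$selectedFeatures,
                                                        drop = FALSE],
                       classLabels(report$dataset),
                       sampleWeights(report$dataset))
    p <- file.path(outdir, "final_tree.dot")
    exportTreeDot(model, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a fitted decision tree in Graphviz DOT format
#'
#' Internal nodes carry the split condition (descriptor and threshold),
#' leaves the predicted class.
#'
#' @param model a fitted decision-tree model as produced inside the
#'   pipeline (or a bare \code{rpart} fit).
#' @param path output file.
#' @param featureNames optional mapping from internal to original
#'   descriptor names (taken from the model when available).
#' @return \code{path}, invisibly.
#' @export
exportTreeDot <- function(model, path, featureNames = NULL) {
  if (inherits(model, "qsarModel")) {
    featureNames <- stats::setNames(model$features, model$safe)
    fit <- model$fit
  } else fit <- model
  if (!inherits(fit, "rpart")) stop("DOT export supports decision trees only")
  fr <- fit$frame
  nodes <- as.integer(rownames(fr))
  lab <- labels(fit)  # split label per row ("root", "F1< 0.5", ...)
  if (!is.null(featureNames))
    for (s in names(featureNames))
      lab <- sub(paste0("^", s, "\\b"), featureNames[[s]], lab)
  cls <- attr(fit, "ylevels")[fr$yval]
  lines <- c("digraph decision_tree {", "  node [shape=box];")
  for (i in seq_along(nodes)) {
    txt <- if (fr$var[i] == "<leaf>")
      sprintf("%s\\n(n=%d)", cls[i], fr$n[i])
    else {
      v <- as.character(fr$var[i])
      if (!is.null(featureNames) && v %in% names(featureNames))
        v <- featureNames[[v]]
      sprintf("%s\\n(n=%d)", v, fr$n[i])
    }
    lines <- c(lines, sprintf("  n%d [label=\"%s\"%s];", nodes[i], txt,
                              if (fr$var[i] == "<leaf>")
                                ", style=filled, fillcolor=lightgrey" else ""))
  }
  for (i in seq_along(nodes)) {
    for (child in c(2L * nodes[i], 2L * nodes[i] + 1L)) {
      j <- match(child, nodes)
      if (!is.na(j))
        lines <- c(lines, sprintf("  n%d -> n%d [label=\"%s\"];",
                                  nodes[i], child, lab[j]))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
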