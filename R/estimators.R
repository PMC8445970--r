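#' Estimator specification
#'
#' Bundles an estimator family, its hyperparameters and a seed. The four
#' families mirror the tree learners used throughout the pipeline: a single
#' CART decision tree, a random forest, an extremely-randomized-trees
#' forest, and gradient-boosted trees. Hyperparameters use the
#' conventional QSAR/scikit-learn names (\code{max_depth},
#' \code{min_samples_split}, \code{min_samples_leaf}, \code{max_features},
#' \code{n_estimators}, \code{learning_rate}, \code{min_child_weight},
#' \code{subsample}, \code{colsample_bytree}); they are translated to the
#' rpart/ranger/xgboost equivalents internally. \code{max_depth = NA}
#' means unlimited depth ("none").
#'
#' @param family one of \code{"decision_tree"}, \code{"random_forest"},
#'   \code{"extra_trees"}, \code{"gradient_boosting"}.
#' @param params named list of hyperparameters; unspecified ones fall back
#'   to the backend defaults.
#' @param seed integer seed controlling every stochastic element of the
#'   fit (bootstrap, feature subsampling, random splits).
#' @return an object of class \code{EstimatorSpec}.
#' @export
estimatorSpec <- function(family, params = list(), seed = 1L) {
  family <- match.arg(family, .estimatorFamilies)
  stopifnot(is.list(params))
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "EstimatorSpec")
}

.estimatorFamilies <- c("decision_tree", "random_forest", "extra_trees",
                        "gradient_boosting")

#' @export
print.EstimatorSpec <- function(x, ...) {
  cat("EstimatorSpec:", x$family, "(seed", paste0(x$seed, ")"), "\n")
  if (length(x$params)) {
    p <- vapply(x$params, function(v) paste(format(v), collapse = ","),
                character(1))
    cat(" ", paste(names(p), p, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

.param <- function(spec, name, default) {
  v <- spec$params[[name]]
  if (is.null(v)) default else v
}

# depth "none" is encoded NA; rpart caps at 30, ranger uses 0 for unlimited
.depthOr <- function(d, none) if (is.null(d) || is.na(d)) none else as.integer(d)

# Fit one model. X: molecules x features numeric matrix with colnames;
# y: two-level factor (negative level first); w: per-sample weights.
.fitModel <- function(spec, X, y, w = rep(1, length(y))) {
  stopifnot(is.factor(y), nlevels(y) == 2L)
  feats <- colnames(X)
  safe <- paste0("F", seq_along(feats))   # backend-proof column names
  colnames(X) <- safe
  # some backends consume the R RNG (e.g. weighted bootstrap draws), so the
  # whole fit runs under the spec seed for reproducibility
  fit <- .withSeed(spec$seed, switch(spec$family,
    decision_tree = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      ctl <- rpart::rpart.control(
        cp = 0, xval = 0, maxsurrogate = 0, usesurrogate = 0, maxcompete = 0,
        maxdepth = min(.depthOr(.param(spec, "max_depth", NA), 30L), 30L),
        minsplit = .param(spec, "min_samples_split", 2L),
        minbucket = .param(spec, "min_samples_leaf", 1L))
      rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                   control = ctl)
    },
    random_forest = ,
    extra_trees = {
      extra <- spec$family == "extra_trees"
      mtry <- min(.param(spec, "max_features",
                         max(1L, floor(sqrt(ncol(X))))), ncol(X))
      args <- list(
        x = X, y = y, case.weights = w,
        num.trees = .param(spec, "n_estimators", 100L),
        mtry = mtry,
        max.depth = .depthOr(.param(spec, "max_depth", NA), 0L),
        min.node.size = .param(spec, "min_samples_leaf", 1L),
        replace = !extra, sample.fraction = 1,
        importance = "impurity", seed = spec$seed, num.threads = 1L)
      if (extra) {
        args$splitrule <- "extratrees"
        args$num.random.splits <- 1L
      }
      do.call(ranger::ranger, args)
    },
    gradient_boosting = {
      lab <- as.integer(y == levels(y)[2L])
      dtr <- xgboost::xgb.DMatrix(X, label = lab, weight = w, nthread = 1L)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = .param(spec, "learning_rate", 0.3),
                      max_depth = .depthOr(.param(spec, "max_depth", 6L), 6L),
                      min_child_weight = .param(spec, "min_child_weight", 1),
                      subsample = .param(spec, "subsample", 1),
                      colsample_bytree = .param(spec, "colsample_bytree", 1),
                      nthread = 1L, seed = spec$seed),
        data = dtr, nrounds = .param(spec, "n_estimators", 100L),
        verbose = 0)
    }))
  structure(list(family = spec$family, fit = fit, levels = levels(y),
                 features = feats, safe = safe, seed = spec$seed),
            class = "qsarModel")
}

.predictModel <- function(model, X) {
  colnames(X) <- model$safe
  switch(model$family,
    decision_tree = {
      df <- data.frame(X, check.names = FALSE)
      factor(as.character(stats::predict(model$fit, df, type = "class")),
             levels = model$levels)
    },
    random_forest = ,
    extra_trees =
      # explicit seed: prediction-time vote ties otherwise draw from the
      # ambient R RNG
      factor(as.character(stats::predict(model$fit, data = X,
                                         num.threads = 1L,
                                         seed = model$seed)$predictions),
             levels = model$levels),
    gradient_boosting = {
      p <- stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1L))
      factor(model$levels[(p > 0.5) + 1L], levels = model$levels)
    })
}

# Split-gain (impurity-decrease) importance, named by the original feature
# names; features unused by the model get importance 0.
.modelImportance <- function(model) {
  imp <- stats::setNames(numeric(length(model$features)), model$safe)
  raw <- switch(model$family,
    decision_tree = model$fit$variable.importance,
    random_forest = ,
    extra_trees = ranger::importance(model$fit),
    gradient_boosting = {
      tab <- xgboost::xgb.importance(model = model$fit)
      stats::setNames(tab$Gain, tab$Feature)
    })
  if (length(raw)) imp[names(raw)] <- raw
  stats::setNames(imp, model$features)
}

#' Hyperparameter grids for the four estimator families
#'
#' \code{defaultGrid} returns the full tuning grid used in the pipeline:
#' for the decision tree, \code{max_depth} 1-10 plus none,
#' \code{min_samples_split} 2-10 and \code{min_samples_leaf} 1-10; for the
#' two forests, \code{max_depth} 1-6 plus none, \code{min_samples_leaf}
#' 1-5, \code{max_features} 1-floor(sqrt(p)) and \code{n_estimators}
#' 100/200; for gradient boosting, \code{learning_rate} 0.01/0.1,
#' \code{max_depth} 3/5/7/10, \code{min_child_weight} 1/3/5,
#' \code{subsample} and \code{colsample_bytree} 0.5/0.7 and
#' \code{n_estimators} 100/200 (tree booster). \code{coarseGrid} is a
#' small subset of the same axes for quick exploratory runs.
#'
#' The rpart backend evaluates every feature at every split, so the
#' single-tree grid has no \code{max_features} axis; the ranger backend
#' exposes one node-size control, carried here as
#' \code{min_samples_leaf}.
#'
#' @param family estimator family name.
#' @param numFeatures number of features in the candidate set (bounds the
#'   \code{max_features} axis).
#' @return named list of parameter value vectors.
#' @export
defaultGrid <- function(family, numFeatures) {
  family <- match.arg(family, .estimatorFamilies)
  switch(family,
    decision_tree = list(
      max_depth = c(1:10, NA),
      min_samples_split = 2:10,
      min_samples_leaf = 1:10),
    random_forest = ,
    extra_trees = list(
      max_depth = c(1:6, NA),
      min_samples_leaf = 1:5,
      max_features = seq_len(max(1L, floor(sqrt(numFeatures)))),
      n_estimators = c(100L, 200L)),
    gradient_boosting = list(
      learning_rate = c(0.01, 0.1),
      max_depth = c(3L, 5L, 7L, 10L),
      min_child_weight = c(1, 3, 5),
      subsample = c(0.5, 0.7),
      colsample_bytree = c(0.5, 0.7),
      n_estimators = c(100L, 200L)))
}

#' @rdname defaultGrid
#' @export
coarseGrid <- function(family, numFeatures) {
  family <- match.arg(family, .estimatorFamilies)
  rt <- max(1L, floor(sqrt(numFeatures)))
  switch(family,
    decision_tree = list(
      max_depth = c(3L, 6L, NA),
      min_samples_leaf = c(1L, 3L)),
    random_forest = ,
    extra_trees = list(
      max_depth = c(3L, NA),
      max_features = unique(c(max(1L, rt %/% 2L), rt)),
      n_estimators = 100L),
    gradient_boosting = list(
      learning_rate = c(0.01, 0.1),
      max_depth = c(3L, 7L),
      n_estimators = 100L))
}
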