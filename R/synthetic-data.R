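#' Specification for a synthetic descriptor table
#'
#' Parameterizes a generator that emulates the statistical shape of a
#' PaDEL-style QSAR descriptor matrix: a few informative descriptors
#' driving a tree-learnable class boundary, correlated redundant copies,
#' a large block of constant descriptors (as real descriptor tables
#' contain), pure-noise descriptors with mixed continuous/count marginals,
#' and exact class imbalance. Defaults mirror a toxicity-screen-sized
#' campaign: 171 molecules, 1538 descriptors of which 334 are constant,
#' and a 33\% positive class.
#'
#' @param nMolecules number of molecules (171 toxicity-like, 90
#'   period-like).
#' @param nFeatures total descriptor count.
#' @param nConstant number of constant descriptors (334 or 360 in the
#'   emulated screens).
#' @param nInformative number of descriptors that jointly determine the
#'   class boundary.
#' @param nRedundant number of jittered copies of informative descriptors.
#' @param blockCorrelation target correlation between a redundant copy and
#'   its informative source, in [0,1).
#' @param positiveFraction positive-class fraction in (0,1); the generated
#'   positive count is exactly \code{round(positiveFraction * nMolecules)}.
#' @param boundary class boundary type: \code{"additive_threshold"} (sum
#'   of informative descriptors versus a quantile cut; learnable by
#'   shallow trees), \code{"axis_threshold"} (a single-descriptor
#'   separable cut) or \code{"xor_pair"} (sign pattern of the first two
#'   informative descriptors; not learnable by a stump).
#' @param labelNoise fraction of molecules mislabeled, in [0, 0.5).
#'   Implemented as paired positive/negative label swaps so the printed
#'   class counts stay exact.
#' @param positiveClass,negativeClass class names used in the labels.
#' @param seed integer seed; the dataset is fully determined by it.
#' @return an object of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(nMolecules = 171L, nFeatures = 1538L,
                          nConstant = 334L, nInformative = 8L,
                          nRedundant = 20L, blockCorrelation = 0.9,
                          positiveFraction = 0.33,
                          boundary = c("additive_threshold", "axis_threshold",
                                       "xor_pair"),
                          labelNoise = 0, positiveClass = "toxic",
                          negativeClass = "nontoxic", seed = 1L) {
  boundary <- match.arg(boundary)
  spec <- structure(list(
    nMolecules = as.integer(nMolecules), nFeatures = as.integer(nFeatures),
    nConstant = as.integer(nConstant), nInformative = as.integer(nInformative),
    nRedundant = as.integer(nRedundant),
    blockCorrelation = blockCorrelation,
    positiveFraction = positiveFraction, boundary = boundary,
    labelNoise = labelNoise, positiveClass = positiveClass,
    negativeClass = negativeClass, seed = as.integer(seed)),
    class = "SyntheticSpec")
  .validateSyntheticSpec(spec)
  spec
}

.validateSyntheticSpec <- function(s) {
  if (s$nConstant + s$nInformative + s$nRedundant > s$nFeatures)
    stop("infeasible spec: constant + informative + redundant (",
         s$nConstant + s$nInformative + s$nRedundant,
         ") exceeds nFeatures (", s$nFeatures, ")")
  if (s$nInformative < 1L) stop("need at least one informative feature")
  if (s$positiveFraction <= 0 || s$positiveFraction >= 1)
    stop("positiveFraction must be in (0,1)")
  if (s$labelNoise < 0 || s$labelNoise >= 0.5)
    stop("labelNoise must be in [0, 0.5)")
  if (s$blockCorrelation < 0 || s$blockCorrelation >= 1)
    stop("blockCorrelation must be in [0,1)")
  if (s$boundary == "xor_pair" && s$nInformative < 2L)
    stop("xor_pair boundary needs >= 2 informative features")
  invisible(s)
}

#' Generate a labeled synthetic descriptor table with recorded ground truth
#'
#' Draws the dataset described by a \code{\link{syntheticSpec}}: noise
#' descriptors are independent (standard normal, with a minority of
#' Poisson count-like columns echoing mixed descriptor families),
#' informative descriptors are structured by class according to the
#' chosen boundary, redundant descriptors are informative sources plus
#' Gaussian jitter calibrated to the target correlation, and constant
#' descriptors are literally constant. Feature positions are shuffled and
#' named uniformly (\code{D0001}, ...), so nothing about a column's role
#' is visible to the learners; the mapping is recorded in the returned
#' ground truth.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{dataset} (a labeled
#'   \linkS4class{DescriptorSet}) and \code{truth} (list:
#'   \code{informative}, \code{redundantMap}, \code{constant},
#'   \code{labelsPreflip}).
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .validateSyntheticSpec(spec)
  n <- spec$nMolecules; p <- spec$nFeatures
  nPos <- as.integer(round(spec$positiveFraction * n))
  .withSeed(spec$seed, {
    # class assignment, exact counts
    posIdx <- sample.int(n, nPos)
    pos <- seq_len(n) %in% posIdx

    Xinf <- .drawInformative(spec, n, pos)
    nNoise <- p - spec$nConstant - spec$nInformative - spec$nRedundant
    Xnoise <- .drawNoise(n, nNoise)
    Xred <- .drawRedundant(spec, Xinf)
    Xconst <- matrix(rep(stats::rnorm(spec$nConstant), each = n),
                     nrow = n)

    X <- cbind(Xinf, Xred, Xconst, Xnoise)
    role <- c(rep("informative", spec$nInformative),
              rep("redundant", spec$nRedundant),
              rep("constant", spec$nConstant),
              rep("noise", nNoise))
    srcIdx <- c(seq_len(spec$nInformative),          # informative: itself
                attr(Xred, "source"),                # redundant: its source
                rep(NA_integer_, spec$nConstant + nNoise))

    perm <- sample.int(p)                            # hide the block layout
    X <- X[, perm, drop = FALSE]
    role <- role[perm]; srcIdx <- srcIdx[perm]
    featNames <- sprintf("D%04d", seq_len(p))
    colnames(X) <- featNames
    rownames(X) <- sprintf("MOL%04d", seq_len(n))

    labels <- ifelse(pos, spec$positiveClass, spec$negativeClass)
    preflip <- labels
    # paired swaps keep class counts exact under label noise
    nSwap <- as.integer(round(spec$labelNoise * n / 2))
    if (nSwap > 0L) {
      flipPos <- sample(which(pos), min(nSwap, sum(pos)))
      flipNeg <- sample(which(!pos), min(nSwap, sum(!pos)))
      labels[flipPos] <- spec$negativeClass
      labels[flipNeg] <- spec$positiveClass
    }

    ds <- DescriptorSet(X, sourceNote = sprintf(
      "synthetic: n=%d p=%d seed=%d boundary=%s", n, p, spec$seed,
      spec$boundary))
    ds <- joinLabels(ds, stats::setNames(labels, rownames(X)),
                     spec$positiveClass)
    infNames <- featNames[role == "informative"]
    # informative block index -> shuffled name, for the redundant map
    infByBlock <- character(spec$nInformative)
    infByBlock[srcIdx[role == "informative"]] <- infNames
    redNames <- featNames[role == "redundant"]
    redundantMap <- stats::setNames(infByBlock[srcIdx[role == "redundant"]],
                                    redNames)
    truth <- list(informative = infNames,
                  redundantMap = redundantMap,
                  constant = featNames[role == "constant"],
                  labelsPreflip = stats::setNames(preflip, rownames(X)))
    list(dataset = ds, truth = truth)
  })
}

.drawInformative <- function(spec, n, pos) {
  m <- spec$nInformative
  X <- matrix(stats::rnorm(n * m), n, m)
  switch(spec$boundary,
    axis_threshold = {
      # first informative feature strictly separates the classes
      X[, 1L] <- ifelse(pos, abs(X[, 1L]) + 0.5, -abs(X[, 1L]) - 0.5)
      if (m > 1L)  # remaining informative features: weaker class shift
        X[, -1L] <- X[, -1L] + outer(ifelse(pos, 1, 0), rep(1.0, m - 1L))
      X
    },
    additive_threshold = {
      # molecules ranked by the sum of informative features; positives are
      # re-drawn conditional on exceeding the class quantile cut
      target <- sum(pos)
      score <- rowSums(X)
      cut <- sort(score, decreasing = TRUE)[target]
      hi <- order(score, decreasing = TRUE)[seq_len(target)]
      wantHi <- which(pos); haveHi <- hi
      # swap rows so positives occupy the high-score rows
      map <- seq_len(n)
      map[wantHi] <- haveHi
      map[setdiff(seq_len(n), wantHi)] <- setdiff(seq_len(n), haveHi)
      X[map, , drop = FALSE]
    },
    xor_pair = {
      # class follows the sign pattern of the first two informative
      # features: re-assign rows so positives sit in the xor quadrants
      score <- -(X[, 1L] * X[, 2L])   # high in (+,-) and (-,+) quadrants
      target <- sum(pos)
      hi <- order(score, decreasing = TRUE)[seq_len(target)]
      map <- seq_len(n)
      map[which(pos)] <- hi
      map[setdiff(seq_len(n), which(pos))] <- setdiff(seq_len(n), hi)
      X[map, , drop = FALSE]
    })
}

.drawNoise <- function(n, nNoise) {
  if (nNoise == 0L) return(matrix(numeric(0), n, 0L))
  X <- matrix(stats::rnorm(n * nNoise), n, nNoise)
  # ~15% of noise columns are count-like integers (mixed descriptor families)
  nCount <- floor(0.15 * nNoise)
  if (nCount > 0L) {
    cols <- seq_len(nCount)
    X[, cols] <- matrix(stats::rpois(n * nCount, lambda = 3), n, nCount)
  }
  X
}

.drawRedundant <- function(spec, Xinf) {
  r <- spec$nRedundant
  if (r == 0L) {
    out <- matrix(numeric(0), nrow(Xinf), 0L)
    attr(out, "source") <- integer(0)
    return(out)
  }
  src <- rep_len(seq_len(spec$nInformative), r)
  rho <- max(spec$blockCorrelation, 1e-6)
  jitterSd <- sqrt(1 / rho^2 - 1)   # cor(x, x + e) = 1/sqrt(1+var(e)) for sd(x)=1
  out <- vapply(src, function(j) {
    v <- Xinf[, j]
    v + stats::rnorm(length(v), sd = jitterSd * stats::sd(v))
  }, numeric(nrow(Xinf)))
  out <- matrix(out, nrow = nrow(Xinf))
  attr(out, "source") <- src
  out
}

#' Fraction of a selected feature set that is truly signal-bearing
#'
#' A selected feature counts as recovered if it is informative or a
#' redundant copy of an informative feature.
#'
#' @param selected character vector of selected feature names.
#' @param truth ground truth from \code{\link{generateDataset}}.
#' @return fraction in [0,1] (0 for an empty selection).
#' @export
recoveryScore <- function(selected, truth) {
  if (!length(selected)) return(0)
  good <- union(truth$informative, names(truth$redundantMap))
  mean(selected %in% good)
}
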