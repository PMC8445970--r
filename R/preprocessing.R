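#' Remove descriptors that are constant across all molecules
#'
#' A descriptor repeating the same value for every molecule carries no
#' information for classification and is discarded. Constancy is tested on
#' exact value equality (descriptors are deterministic computations, not
#' measurements), counting all non-finite entries of the same kind as equal.
#' The removal is recorded in the object's cleaning report
#' (\code{\link{cleaningReport}}).
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @return the cleaned \linkS4class{DescriptorSet}; removed names are listed
#'   in \code{cleaningReport(x)$removedConstant}.
#' @export
dropConstantFeatures <- function(x) {
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty descriptor table")
  a <- SummarizedExperiment::assay(x, "descriptors")
  nDistinct <- apply(a, 1L, function(v) length(unique(v[is.finite(v)])))
  # a feature must take >=2 distinct finite values to be retained
  const <- nDistinct < 2L
  if (all(const))
    stop("all descriptors are constant; nothing to learn on")
  .recordCleaning(x[!const, ], removedConstant = rownames(x)[const],
                  before = nrow(x))
}

#' Remove descriptors containing non-finite values
#'
#' Feature-wise removal (not imputation) of any descriptor with NA, NaN or
#' infinite entries, applied before the constancy check so the retained
#' matrix is entirely finite.
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @return the cleaned \linkS4class{DescriptorSet}; removed names appear in
#'   \code{cleaningReport(x)$removedNonfinite}.
#' @export
dropNonfiniteFeatures <- function(x) {
  a <- SummarizedExperiment::assay(x, "descriptors")
  bad <- !apply(is.finite(a), 1L, all)
  .recordCleaning(x[!bad, ], removedNonfinite = rownames(x)[bad],
                  before = nrow(x))
}

.recordCleaning <- function(x, removedConstant = character(0),
                            removedNonfinite = character(0), before) {
  rep <- S4Vectors::metadata(x)$cleaning
  if (is.null(rep))
    rep <- list(removedConstant = character(0),
                removedNonfinite = character(0),
                nFeaturesBefore = before, nFeaturesAfter = before)
  rep$removedConstant <- union(rep$removedConstant, removedConstant)
  rep$removedNonfinite <- union(rep$removedNonfinite, removedNonfinite)
  rep$nFeaturesAfter <- nrow(x)
  S4Vectors::metadata(x)$cleaning <- rep
  x
}

#' Inverse-class-size training weights
#'
#' Computes the balanced class weights w_pos = n/(2 n_pos) and
#' w_neg = n/(2 n_neg), so that each class carries half of the total
#' training mass (n_pos w_pos = n_neg w_neg = n/2). For the 56/115
#' toxic/non-toxic split these are 1.53 and 0.74 (2 dp); for the 27/63
#' period-lengthener split, 1.67 and 0.71. Reporting rounds to two
#' decimals but training always uses full precision.
#'
#' @param x a labeled \linkS4class{DescriptorSet}.
#' @return named numeric vector \code{c(positive=, negative=)} with
#'   attribute \code{counts}.
#' @examples
#' # 171 molecules, 56 positive -> weights 1.53 / 0.74
#' @export
computeClassWeights <- function(x) {
  cc <- .assertBothClasses(x)
  w <- c(positive = cc[["n"]] / (2 * cc[["nPos"]]),
         negative = cc[["n"]] / (2 * cc[["nNeg"]]))
  attr(w, "counts") <- cc
  w
}

#' Per-molecule training weights from the class weights
#'
#' @param x a labeled \linkS4class{DescriptorSet}.
#' @param classWeights optional precomputed result of
#'   \code{\link{computeClassWeights}}.
#' @return numeric vector, one weight per molecule, aligned with
#'   \code{moleculeIds(x)}.
#' @export
sampleWeights <- function(x, classWeights = computeClassWeights(x)) {
  cl <- classLabels(x)
  ifelse(cl == positiveClass(x),
         classWeights[["positive"]], classWeights[["negative"]])
}
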