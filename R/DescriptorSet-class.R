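#' DescriptorSet: molecules x descriptors container
#'
#' An S4 container for a molecular-descriptor table, extending
#' \linkS4class{SummarizedExperiment}. Following Bioconductor convention the
#' assay is stored descriptors-in-rows, molecules-in-columns; use
#' \code{\link{descriptorMatrix}} to obtain the molecules x descriptors
#' orientation that the learners consume. Binary class labels, when present,
#' live in \code{colData(x)$class} together with the positive-class name in
#' the object metadata.
#'
#' @slot sourceNote free-text provenance of the table (file path, generator
#'   spec, ...).
#'
#' @seealso \code{\link{readDescriptorTable}}, \code{\link{joinLabels}},
#'   \code{\link{dropConstantFeatures}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("DescriptorSet",
  contains = "SummarizedExperiment",
  slots = c(sourceNote = "character")
)

setValidity("DescriptorSet", function(object) {
  msg <- character(0)
  ids <- colnames(object)
  feats <- rownames(object)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msg <- c(msg, "molecule ids must be non-empty strings")
  else if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate molecule id(s): ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (is.null(feats) || anyNA(feats) || any(!nzchar(feats)))
    msg <- c(msg, "descriptor names must be non-empty strings")
  else if (anyDuplicated(feats))
    msg <- c(msg, paste0("duplicate descriptor name(s): ",
                         paste(unique(feats[duplicated(feats)]), collapse = ", ")))
  if (!"descriptors" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'descriptors' is required")
  if ("class" %in% colnames(SummarizedExperiment::colData(object))) {
    cl <- SummarizedExperiment::colData(object)$class
    if (!is.factor(cl) || nlevels(cl) != 2L)
      msg <- c(msg, "colData$class must be a two-level factor")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DescriptorSet from a molecules x descriptors matrix
#'
#' @param values numeric matrix, one row per molecule, one column per
#'   descriptor. Non-finite entries are allowed (they are handled by the
#'   preprocessing step).
#' @param moleculeIds character vector of unique molecule identifiers;
#'   defaults to \code{rownames(values)}.
#' @param descriptorNames character vector of unique descriptor names;
#'   defaults to \code{colnames(values)}.
#' @param sourceNote free-text provenance note.
#'
#' @return A \linkS4class{DescriptorSet}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("M1", "M2", "M3"), paste0("D", 1:4)))
#' DescriptorSet(m, sourceNote = "example")
#' @export
DescriptorSet <- function(values, moleculeIds = rownames(values),
                          descriptorNames = colnames(values),
                          sourceNote = "") {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("descriptor values must be numeric")
  if (is.null(moleculeIds) || length(moleculeIds) != nrow(values))
    stop("need one molecule id per row")
  if (is.null(descriptorNames) || length(descriptorNames) != ncol(values))
    stop("need one descriptor name per column")
  assay <- t(values)
  dimnames(assay) <- list(as.character(descriptorNames),
                          as.character(moleculeIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(descriptors = assay))
  methods::new("DescriptorSet", se, sourceNote = as.character(sourceNote))
}

#' @describeIn DescriptorSet molecule identifiers (assay columns).
#' @param x a DescriptorSet.
#' @export
moleculeIds <- function(x) colnames(x)

#' @describeIn DescriptorSet descriptor (feature) names.
#' @export
descriptorNames <- function(x) rownames(x)

#' @describeIn DescriptorSet numeric matrix in molecules x descriptors
#'   orientation (the transpose of the stored assay).
#' @export
descriptorMatrix <- function(x)
  t(SummarizedExperiment::assay(x, "descriptors"))

#' @describeIn DescriptorSet provenance note.
#' @export
sourceNote <- function(x) x@sourceNote

#' @describeIn DescriptorSet class labels as a factor (negative level first),
#'   or NULL when the object is unlabeled.
#' @export
classLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("class" %in% colnames(cd)) cd$class else NULL
}

#' @describeIn DescriptorSet name of the positive class, or NA if unlabeled.
#' @export
positiveClass <- function(x) {
  pc <- S4Vectors::metadata(x)$positiveClass
  if (is.null(pc)) NA_character_ else pc
}

#' @describeIn DescriptorSet named vector c(n, nPos, nNeg) of molecule counts.
#' @export
classCounts <- function(x) {
  cl <- classLabels(x)
  if (is.null(cl)) stop("dataset has no class labels; call joinLabels() first")
  nPos <- sum(cl == positiveClass(x))
  c(n = length(cl), nPos = nPos, nNeg = length(cl) - nPos)
}

#' @describeIn DescriptorSet cleaning report accumulated by the
#'   preprocessing steps (see \code{\link{dropConstantFeatures}}).
#' @export
cleaningReport <- function(x) {
  rep <- S4Vectors::metadata(x)$cleaning
  if (is.null(rep))
    rep <- list(removedConstant = character(0),
                removedNonfinite = character(0),
                nFeaturesBefore = nrow(x), nFeaturesAfter = nrow(x))
  rep
}

.assertBothClasses <- function(x) {
  cc <- classCounts(x)
  if (cc["nPos"] == 0L || cc["nNeg"] == 0L)
    stop("both classes must be non-empty before training (counts: ",
         cc["nPos"], " positive, ", cc["nNeg"], " negative)")
  invisible(cc)
}

#' Display a DescriptorSet summary
#' @param object a DescriptorSet.
#' @export
setMethod("show", "DescriptorSet", function(object) {
  cat("DescriptorSet with", ncol(object), "molecules and",
      nrow(object), "descriptors\n")
  cl <- classLabels(object)
  if (!is.null(cl)) {
    cc <- classCounts(object)
    cat(sprintf("labels: %d '%s' (positive), %d other\n",
                cc[["nPos"]], positiveClass(object), cc[["nNeg"]]))
  } else {
    cat("labels: none\n")
  }
  rep <- S4Vectors::metadata(object)$cleaning
  if (!is.null(rep))
    cat(sprintf("cleaned: %d constant + %d non-finite descriptors removed\n",
                length(rep$removedConstant), length(rep$removedNonfinite)))
  if (nzchar(object@sourceNote))
    cat("source:", object@sourceNote, "\n")
})
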