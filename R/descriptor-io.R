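#' Read a PaDEL/ChemDes-style descriptor table
#'
#' Parses a delimited text file with one header row, the molecule identifier
#' in the first column (PaDEL calls it \code{Name}) and one numeric column
#' per descriptor. Empty cells and any case spelling of NaN/Inf survive the
#' load as non-finite entries so that cleaning is an explicit, auditable
#' step (\code{\link{dropNonfiniteFeatures}}).
#'
#' @param path path to the delimited file.
#' @param sep field delimiter; comma by default, use \code{"\t"} for TSV.
#' @param quiet suppress the row/column count message.
#'
#' @return A \linkS4class{DescriptorSet}.
#' @export
readDescriptorTable <- function(path, sep = ",", quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("descriptor table has zero data rows: ", path)
  if (ncol(raw) < 2L) stop("descriptor table needs an id column plus >=1 descriptor")
  ids <- trimws(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate molecule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  featNames <- colnames(raw)[-1L]
  if (anyDuplicated(featNames))
    stop("duplicate descriptor name(s): ",
         paste(unique(featNames[duplicated(featNames)]), collapse = ", "))
  vals <- vapply(raw[-1L], .parseNumericColumn, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, featNames))
  if (!quiet)
    message("read ", nrow(vals), " molecules x ", ncol(vals),
            " descriptors from ", path)
  DescriptorSet(vals, sourceNote = path)
}

# empty -> NA; nan/inf spellings (any case) -> non-finite; other junk -> NaN
.parseNumericColumn <- function(v) {
  v <- trimws(v)
  out <- suppressWarnings(as.numeric(tolower(v)))
  out[is.na(out) & nzchar(v) & !tolower(v) %in% c("na", "nan")] <- NaN
  out
}

#' Write a DescriptorSet back to delimited text
#'
#' Emits the same dialect \code{\link{readDescriptorTable}} reads (header
#' row, id column first), so a write/read round trip preserves ids, names
#' and finite values exactly.
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @param path output file path.
#' @param sep field delimiter.
#' @param idHeader header for the identifier column.
#' @return \code{path}, invisibly.
#' @export
writeDescriptorTable <- function(x, path, sep = ",", idHeader = "Name") {
  m <- descriptorMatrix(x)
  df <- data.frame(id = rownames(m),
                   # 17 significant digits round-trips doubles exactly
                   as.data.frame(apply(m, 2, format, digits = 17,
                                       scientific = TRUE, trim = TRUE)),
                   check.names = FALSE)
  colnames(df) <- c(idHeader, colnames(m))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a two-column label file (id, class)
#'
#' @param path delimited file with a header row and two columns:
#'   molecule id and class name.
#' @param sep field delimiter.
#' @return named character vector, id -> class.
#' @export
readLabelTable <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns (id, class)")
  stats::setNames(trimws(df[[2L]]), trimws(df[[1L]]))
}

#' Attach binary class labels to a DescriptorSet
#'
#' Joins an id-to-class mapping onto the table and records class counts and
#' the positive-class name. Every molecule in the table must be labeled;
#' labels for molecules absent from the table are reported (message) but not
#' fatal. The label factor is ordered negative-level-first so the positive
#' class is the second level throughout the package.
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @param labels named character vector (id -> class) as returned by
#'   \code{\link{readLabelTable}}, using exactly two class names.
#' @param positiveClass which of the two class names is the positive
#'   (minority-of-interest) class, e.g. \code{"toxic"} or
#'   \code{"lengthener"}.
#' @return the labeled \linkS4class{DescriptorSet}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("M", 1:4), paste0("D", 1:5)))
#' ds <- DescriptorSet(m)
#' lab <- c(M1 = "toxic", M2 = "nontoxic", M3 = "nontoxic", M4 = "toxic")
#' classCounts(joinLabels(ds, lab, "toxic"))
#' @export
joinLabels <- function(x, labels, positiveClass) {
  ids <- moleculeIds(x)
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop("missing label for molecule(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(labels), ids)
  if (length(extra))
    message(length(extra), " labeled molecule(s) absent from table: ",
            paste(utils::head(extra, 10L), collapse = ", "))
  cls <- unname(labels[ids])
  classNames <- sort(unique(unname(labels)))
  if (length(classNames) > 2L)
    stop("label mapping uses more than two classes: ",
         paste(classNames, collapse = ", "))
  if (!positiveClass %in% classNames)
    stop("positive class '", positiveClass, "' not among label classes")
  negative <- setdiff(classNames, positiveClass)
  if (length(negative) == 0L) negative <- ".negative"  # degenerate one-class file
  cl <- factor(cls, levels = c(negative, positiveClass))
  SummarizedExperiment::colData(x)$class <- cl
  S4Vectors::metadata(x)$positiveClass <- positiveClass
  methods::validObject(x)
  x
}
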