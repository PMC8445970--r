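#' Seven-rule drug-likeness elimination filter
#'
#' Applies the rule set used to pre-filter a screening library before
#' docking: a molecule is eliminated iff it has more than 7 H-bond
#' donors, more than 12 H-bond acceptors, molecular weight above 600 Da,
#' logP above 7, more than 8 rotatable bonds, fewer than 3 aromatic
#' rings, or fewer than 4 rings in total. All rules are strict
#' inequalities, so values exactly at a threshold are kept. Every
#' violated rule is reported per molecule.
#'
#' @param molecules data.frame with columns \code{id}, \code{hbd},
#'   \code{hba}, \code{mw}, \code{logp}, \code{rotatable_bonds},
#'   \code{aromatic_rings}, \code{total_rings}.
#' @return an object of class \code{FilterReport}: list with \code{kept}
#'   (id vector), \code{discarded} (named list, id -> violated rules),
#'   \code{ruleCounts} (per-rule elimination tallies) and \code{errors}
#'   (named list, id -> problem, for missing/negative properties).
#' @export
applyDruglikenessFilter <- function(molecules) {
  required <- c("id", "hbd", "hba", "mw", "logp", "rotatable_bonds",
                "aromatic_rings", "total_rings")
  missingCols <- setdiff(required, colnames(molecules))
  if (length(missingCols))
    stop("property table lacks column(s): ", paste(missingCols, collapse = ", "))
  if (anyDuplicated(molecules$id))
    stop("duplicate molecule id(s) in property table")

  rules <- list(
    "hbd>7"            = function(m) m$hbd > 7,
    "hba>12"           = function(m) m$hba > 12,
    "mw>600"           = function(m) m$mw > 600,
    "logp>7"           = function(m) m$logp > 7,
    "rotatable_bonds>8" = function(m) m$rotatable_bonds > 8,
    "aromatic_rings<3" = function(m) m$aromatic_rings < 3,
    "total_rings<4"    = function(m) m$total_rings < 4)

  kept <- character(0)
  discarded <- list()
  errors <- list()
  ruleCounts <- stats::setNames(integer(length(rules)), names(rules))
  counts <- c("hbd", "hba", "rotatable_bonds", "aromatic_rings", "total_rings")
  for (i in seq_len(nrow(molecules))) {
    m <- molecules[i, , drop = FALSE]
    id <- as.character(m$id)
    props <- unlist(m[required[-1L]])
    if (anyNA(props)) {
      errors[[id]] <- "missing property"
      next
    }
    if (any(unlist(m[counts]) < 0) || m$mw <= 0 ||
        any(unlist(m[counts]) != round(unlist(m[counts])))) {
      errors[[id]] <- "negative or non-integral count, or non-positive mw"
      next
    }
    violated <- names(rules)[vapply(rules, function(f) isTRUE(f(m)), logical(1))]
    if (length(violated)) {
      discarded[[id]] <- violated
      ruleCounts[violated] <- ruleCounts[violated] + 1L
    } else {
      kept <- c(kept, id)
    }
  }
  structure(list(kept = kept, discarded = discarded,
                 ruleCounts = ruleCounts, errors = errors),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  total <- length(x$kept) + length(x$discarded) + length(x$errors)
  cat("FilterReport:", total, "molecules;", length(x$kept), "kept,",
      length(x$discarded), "discarded,", length(x$errors), "flagged\n")
  if (any(x$ruleCounts > 0)) {
    cat("  eliminations by rule:\n")
    for (r in names(x$ruleCounts)[x$ruleCounts > 0])
      cat("   ", r, ":", x$ruleCounts[[r]], "\n")
  }
  invisible(x)
}

#' Read a molecule-property table for the drug-likeness filter
#'
#' @param path delimited file with header \code{id, hbd, hba, mw, logp,
#'   rotatable_bonds, aromatic_rings, total_rings}.
#' @param sep field delimiter.
#' @return data.frame suitable for \code{\link{applyDruglikenessFilter}}.
#' @export
readMoleculeProperties <- function(path, sep = ",") {
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Random molecule-property tables for exercising the filter
#'
#' Draws physically plausible property ranges (wide enough that every
#' rule is exercised on both sides of its threshold).
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return data.frame in \code{\link{applyDruglikenessFilter}} layout.
#' @export
randomMoleculeProperties <- function(n, seed = 1L) {
  .withSeed(seed, data.frame(
    id = sprintf("LIB%05d", seq_len(n)),
    hbd = stats::rpois(n, 4),
    hba = stats::rpois(n, 7),
    mw = stats::runif(n, 150, 900),
    logp = stats::runif(n, -2, 10),
    rotatable_bonds = stats::rpois(n, 5),
    aromatic_rings = stats::rpois(n, 3),
    total_rings = stats::rpois(n, 4),
    stringsAsFactors = FALSE))
}
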