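## TSV dialects consumed by the workflow:
##   drug_targets.tsv : columns drug_id, gene_id, optional drug_class
##   medium.tsv       : column metabolite_id
##   expression.tsv   : column gene_id + one numeric column per condition

.readTSV <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("schema error in '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  x
}

#' Read a drug-to-target-gene table
#'
#' Expects tab-separated columns \code{drug_id} and \code{gene_id}; an
#' optional \code{drug_class} column (e.g. \code{natural_product} /
#' \code{cancer_drug}) is carried through. Duplicate (drug, gene) rows are
#' dropped. Genes absent from any particular model are retained here and
#' ignored at knockout time.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{drug_id}, \code{gene_id},
#'   \code{drug_class}.
#' @export
readDrugTargets <- function(path) {
  x <- .readTSV(path, c("drug_id", "gene_id"))
  if (is.null(x$drug_class))
    x$drug_class <- rep("natural_product", nrow(x))
  x <- x[!duplicated(x[, c("drug_id", "gene_id")]), , drop = FALSE]
  rownames(x) <- NULL
  x[, c("drug_id", "gene_id", "drug_class")]
}

#' Read a medium composition
#'
#' One \code{metabolite_id} per row: the extracellular metabolites whose
#' uptake is permitted. See \code{\link{applyMedium}}.
#'
#' @param path TSV file path.
#' @return character vector of metabolite ids.
#' @export
readMedium <- function(path) {
  x <- .readTSV(path, "metabolite_id")
  unique(as.character(x$metabolite_id))
}

#' Read an expression score table
#'
#' \code{gene_id} column plus one numeric column per condition. Scores are
#' whatever continuous activity evidence is available (z-scores, logged
#' intensities); they are only compared against the two activity-call
#' thresholds, see \code{\link{callActivity}}.
#'
#' @param path TSV file path.
#' @return data.frame, first column \code{gene_id}.
#' @export
readExpression <- function(path) {
  x <- .readTSV(path, "gene_id")
  if (ncol(x) < 2L)
    stop("schema error in '", path, "': expression table has no condition columns")
  x
}

#' Read all three workflow tables at once
#'
#' @param targets_path,medium_path,expression_path TSV file paths.
#' @return list with elements \code{targets}, \code{medium},
#'   \code{expression}.
#' @export
readTables <- function(targets_path, medium_path, expression_path) {
  list(targets = readDrugTargets(targets_path),
       medium = readMedium(medium_path),
       expression = readExpression(expression_path))
}

.writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
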