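## GPR-aware gene knockout and growth-ratio readouts.
##
## A knockout disables every reaction whose GPR rule evaluates FALSE once
## the knocked genes are FALSE (AND = complex, OR = isozymes); grRatio is
## the knockout objective over the wild-type objective, with values below
## the zero tolerance reported as exactly 0 for reproducible classification.

.GR_ZERO_TOL <- 1e-6

#' Knock out genes in a model
#'
#' Sets both bounds of every reaction whose GPR rule evaluates FALSE under
#' the knockout to zero. Genes absent from the model are ignored.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param genes character vector of gene ids to knock out.
#' @return list with \code{model} (the constrained model) and
#'   \code{disabled_reactions} (character vector).
#' @examples
#' m <- makeToyNetwork(scenarioSpec(seed = 1))
#' deleteGenes(m, geneIds(m)[1])$disabled_reactions
#' @export
deleteGenes <- function(model, genes) {
  genes <- intersect(as.character(genes), model@genes)
  disabled <- character(0)
  if (length(genes)) {
    off <- !vapply(model@gpr, evaluateGpr, logical(1), knocked = genes)
    if (any(off)) {
      disabled <- model@reactions$id[off]
      model@reactions$lower_bound[off] <- 0
      model@reactions$upper_bound[off] <- 0
    }
  }
  list(model = model, disabled_reactions = disabled)
}

#' Growth ratio after a gene knockout
#'
#' grRatio = knockout objective / wild-type objective. Ratios below the
#' zero tolerance (1e-6) are reported as exactly 0; tiny numerical excesses
#' above 1 are clipped to 1.
#'
#' @param model a \code{\linkS4class{MetabolicModel}} with positive
#'   wild-type growth.
#' @param genes gene ids to knock out (may be empty).
#' @param label label for the result row (defaults to the joined gene ids).
#' @param wt optional precomputed wild-type objective value (saves one LP in
#'   callers that screen many knockouts of the same model).
#' @return one-row data.frame: \code{label}, \code{wt_objective},
#'   \code{ko_objective}, \code{grRatio}, \code{n_disabled_reactions}.
#' @export
growthRatio <- function(model, genes, label = NULL, wt = NULL) {
  if (is.null(wt)) {
    fba <- optimizeModel(model)
    if (fba$status != "optimal") stop("non-growing reference model")
    wt <- fba$objective_value
  }
  if (wt <= .GR_ZERO_TOL) stop("non-growing reference model")
  ko <- deleteGenes(model, genes)
  sol <- optimizeModel(ko$model)
  kobj <- if (sol$status == "optimal") sol$objective_value else 0
  ratio <- kobj / wt
  if (ratio < .GR_ZERO_TOL) ratio <- 0
  if (ratio > 1) ratio <- min(ratio, 1 + .GR_ZERO_TOL)
  data.frame(
    label = if (is.null(label)) paste(sort(genes), collapse = "+") else label,
    wt_objective = wt, ko_objective = kobj, grRatio = ratio,
    n_disabled_reactions = length(ko$disabled_reactions),
    stringsAsFactors = FALSE)
}

#' Screen a drug-target table by knockout
#'
#' One growth-ratio simulation per drug, knocking out all of its target
#' genes at once. Rows are sorted by drug label.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param targets data.frame as returned by \code{\link{readDrugTargets}}.
#' @return data.frame of \code{\link{growthRatio}} rows, one per drug.
#' @export
drugDeletion <- function(model, targets) {
  wt <- optimizeModel(model)
  if (wt$status != "optimal" || wt$objective_value <= .GR_ZERO_TOL)
    stop("non-growing reference model")
  drugs <- sort(unique(targets$drug_id))
  out <- do.call(rbind, lapply(drugs, function(d)
    growthRatio(model, targets$gene_id[targets$drug_id == d], label = d,
                wt = wt$objective_value)))
  rownames(out) <- NULL
  out
}

#' Single-gene deletion screen
#'
#' \code{\link{growthRatio}} for every gene of the model, in declaration
#' order.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @return data.frame with one row per gene (label = gene id).
#' @export
singleGeneDeletion <- function(model) {
  wt <- optimizeModel(model)
  if (wt$status != "optimal" || wt$objective_value <= .GR_ZERO_TOL)
    stop("non-growing reference model")
  if (!length(model@genes))
    return(data.frame(label = character(0), wt_objective = numeric(0),
                      ko_objective = numeric(0), grRatio = numeric(0),
                      n_disabled_reactions = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(model@genes, function(g)
    growthRatio(model, g, label = g, wt = wt$objective_value)))
  rownames(out) <- NULL
  out
}

#' Pairwise combination deletion
#'
#' For each (A, B) pair, computes grRatio for A alone, B alone, and the
#' union of their targets, and flags synergy when the combined ratio drops
#' below the better single ratio by more than \code{synergy_delta}.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param pairs data.frame with columns \code{label_a}, \code{label_b};
#'   target genes are looked up in \code{targets}.
#' @param targets drug-target data.frame (see \code{\link{readDrugTargets}}).
#' @param synergy_delta minimum drop below \code{min(grA, grB)} to call
#'   synergy (default 0.01).
#' @return data.frame: labels, \code{grRatio_A}, \code{grRatio_B},
#'   \code{grRatio_AB}, \code{synergy}.
#' @export
combinationDeletion <- function(model, pairs, targets, synergy_delta = 0.01) {
  wt <- optimizeModel(model)
  if (wt$status != "optimal" || wt$objective_value <= .GR_ZERO_TOL)
    stop("non-growing reference model")
  gset <- function(d) targets$gene_id[targets$drug_id == d]
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$label_a[k]; b <- pairs$label_b[k]
    ga <- gset(a); gb <- gset(b)
    ra <- growthRatio(model, ga, label = a, wt = wt$objective_value)$grRatio
    rb <- growthRatio(model, gb, label = b, wt = wt$objective_value)$grRatio
    rab <- growthRatio(model, union(ga, gb), label = "ab",
                       wt = wt$objective_value)$grRatio
    data.frame(label_a = a, label_b = b, grRatio_A = ra, grRatio_B = rb,
               grRatio_AB = rab,
               synergy = rab < min(ra, rb) - synergy_delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$label_a, out$label_b), , drop = FALSE]
}
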