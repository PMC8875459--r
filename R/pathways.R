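## Pathway-level analysis: subsystem membership, drug-target mapping and
## presence-rate alteration of context models against a control.

#' Build a pathway index from a reference model
#'
#' Maps each subsystem label to its reaction ids (unlabeled reactions are
#' grouped under "UNASSIGNED") and each gene to the reactions whose GPR
#' rule references it (the reaction-gene incidence).
#'
#' @param reference_model a \code{\linkS4class{MetabolicModel}}.
#' @return list with \code{pathways} (named list: label -> reaction ids)
#'   and \code{gene_reactions} (named list: gene id -> reaction ids).
#' @export
buildPathwayIndex <- function(reference_model) {
  subs <- subsystems(reference_model)
  subs[!nzchar(subs)] <- "UNASSIGNED"
  pathways <- split(names(subs), subs)
  gene_rxn <- list()
  for (i in seq_along(reference_model@gpr)) {
    for (g in gprGenes(reference_model@gpr[[i]]))
      gene_rxn[[g]] <- c(gene_rxn[[g]], reference_model@reactions$id[i])
  }
  list(pathways = pathways, gene_reactions = gene_rxn)
}

#' Count drugs targeting each pathway
#'
#' A drug counts for a pathway when at least one of its target genes
#' controls at least one reaction of that pathway. Counts are reported per
#' drug class, together with the number of gene-controlled reactions per
#' pathway (the fair normaliser for pathway size).
#'
#' @param index pathway index from \code{\link{buildPathwayIndex}}.
#' @param targets drug-target data.frame (\code{\link{readDrugTargets}}).
#' @return data.frame: \code{pathway}, one count column per drug class,
#'   \code{n_gene_controlled_reactions}.
#' @export
countPathwayTargets <- function(index, targets) {
  classes <- sort(unique(targets$drug_class))
  labels <- names(index$pathways)
  controlled <- unique(unlist(index$gene_reactions))
  out <- data.frame(pathway = labels, stringsAsFactors = FALSE)
  for (cl in classes) out[[cl]] <- 0L
  out$n_gene_controlled_reactions <-
    vapply(labels, function(p)
      length(intersect(index$pathways[[p]], controlled)), integer(1))
  drugs <- unique(targets[, c("drug_id", "drug_class")])
  for (d in seq_len(nrow(drugs))) {
    genes <- targets$gene_id[targets$drug_id == drugs$drug_id[d]]
    rxns <- unique(unlist(index$gene_reactions[
      intersect(genes, names(index$gene_reactions))]))
    if (!length(rxns)) next
    hit <- vapply(labels, function(p)
      length(intersect(index$pathways[[p]], rxns)) > 0, logical(1))
    cl <- drugs$drug_class[d]
    out[[cl]][hit] <- out[[cl]][hit] + 1L
  }
  rownames(out) <- NULL
  out
}

#' Per-pathway presence rates of a context model
#'
#' rate = |pathway reactions present in the context model| /
#' |pathway reactions in the reference|. Pathways empty in the reference
#' yield \code{NA}.
#'
#' @param context_model context \code{\linkS4class{MetabolicModel}} (or a
#'   character vector of its reaction ids).
#' @param index pathway index built from the \emph{reference} model.
#' @return named numeric vector of rates in [0, 1].
#' @export
presenceRates <- function(context_model, index) {
  present <- if (is.character(context_model)) context_model
             else reactionIds(context_model)
  vapply(index$pathways, function(rxns) {
    if (!length(rxns)) return(NA_real_)
    length(intersect(rxns, present)) / length(rxns)
  }, numeric(1))
}

#' Pathway alteration report
#'
#' For each pathway and each treatment model, the difference of presence
#' rates against the control model. Pathways with
#' \code{<= min_pathway_size} reactions are excluded; pathways are ranked
#' by the interquartile range of their differences across treatments
#' (descending); rows with \code{|difference| >= plot_threshold} are
#' flagged for display.
#'
#' @param treatment_models named list of context models (or of reaction-id
#'   character vectors), one per treatment.
#' @param control_model the control context model (or its reaction ids).
#' @param index pathway index from the reference model.
#' @param min_pathway_size pathways with at most this many reactions are
#'   dropped (default 3).
#' @param plot_threshold display flag threshold on \code{|difference|}
#'   (default 0.1).
#' @return data.frame: \code{pathway}, \code{treatment},
#'   \code{presence_rate_treatment}, \code{presence_rate_control},
#'   \code{difference}, \code{pathway_size}, \code{iqr_across_products},
#'   \code{iqr_rank}, \code{display}; ordered by \code{iqr_rank}.
#' @export
alterationReport <- function(treatment_models, control_model, index,
                             min_pathway_size = 3, plot_threshold = 0.1) {
  stopifnot(length(treatment_models) >= 1)
  if (is.null(names(treatment_models)))
    names(treatment_models) <- paste0("treatment_", seq_along(treatment_models))
  ctrl <- presenceRates(control_model, index)
  sizes <- vapply(index$pathways, length, integer(1))
  keep <- names(sizes)[sizes > min_pathway_size]
  rows <- lapply(names(treatment_models), function(tr) {
    rt <- presenceRates(treatment_models[[tr]], index)
    data.frame(pathway = keep, treatment = tr,
               presence_rate_treatment = unname(rt[keep]),
               presence_rate_control = unname(ctrl[keep]),
               difference = unname(rt[keep] - ctrl[keep]),
               pathway_size = unname(sizes[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  iqr <- vapply(keep, function(p)
    stats::IQR(out$difference[out$pathway == p], na.rm = TRUE, type = 7),
    numeric(1))
  out$iqr_across_products <- unname(iqr[out$pathway])
  ranked <- names(iqr)[order(-iqr, names(iqr))]   # deterministic tie-break
  out$iqr_rank <- match(out$pathway, ranked)
  out$display <- !is.na(out$difference) & abs(out$difference) >= plot_threshold
  out <- out[order(out$iqr_rank, out$treatment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
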