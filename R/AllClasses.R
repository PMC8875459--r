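#' MetabolicModel: a constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric matrix with
#' reaction bounds (mmol/gDW/h), GPR rules, subsystem (pathway) labels, a
#' gene universe, and a designated objective (biomass) reaction.
#'
#' @slot modelId single character model identifier.
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}.
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{subsystem}, \code{lower_bound}, \code{upper_bound}.
#' @slot stoichiometry sparse \code{Matrix} (metabolites x reactions),
#'   dimnames matching the id columns.
#' @slot gpr list of GPR rule trees (see \code{\link{parseGpr}}), one per
#'   reaction, named by reaction id; \code{NULL} entries mean no rule.
#' @slot genes character vector of gene ids; a superset of all GPR leaves.
#' @slot objectiveReaction id of the reaction whose flux is maximised.
#'
#' @seealso \code{\link{readSBML}}, \code{\link{makeToyNetwork}},
#'   \code{\link{optimizeModel}}
#' @export
setClass("MetabolicModel",
  representation(
    modelId = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "Matrix",
    gpr = "list",
    genes = "character",
    objectiveReaction = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- character(0)
  rxn <- object@reactions
  met <- object@metabolites
  need_r <- c("id", "name", "subsystem", "lower_bound", "upper_bound")
  need_m <- c("id", "name", "compartment")
  if (!all(need_r %in% names(rxn)))
    return(paste("reactions must have columns:", paste(need_r, collapse = ", ")))
  if (!all(need_m %in% names(met)))
    return(paste("metabolites must have columns:", paste(need_m, collapse = ", ")))
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (any(rxn$lower_bound > rxn$upper_bound))
    msgs <- c(msgs, "lower_bound > upper_bound for some reaction")
  S <- object@stoichiometry
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    msgs <- c(msgs, "stoichiometry dimensions do not match metabolites x reactions")
  else if (!identical(rownames(S), as.character(met$id)) ||
           !identical(colnames(S), as.character(rxn$id)))
    msgs <- c(msgs, "stoichiometry dimnames do not match metabolite/reaction ids")
  if (length(object@gpr) != nrow(rxn))
    msgs <- c(msgs, "gpr list length does not match number of reactions")
  gpr_genes <- unique(unlist(lapply(object@gpr, gprGenes)))
  if (!all(gpr_genes %in% object@genes))
    msgs <- c(msgs, "GPR rules reference genes absent from the gene set")
  if (length(object@objectiveReaction) != 1L ||
      !(object@objectiveReaction %in% rxn$id))
    msgs <- c(msgs, "objectiveReaction must name exactly one existing reaction")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@modelId, "'\n", sep = "")
  cat("  ", nrow(object@reactions), " reactions, ",
      nrow(object@metabolites), " metabolites, ",
      length(object@genes), " genes\n", sep = "")
  subs <- setdiff(unique(object@reactions$subsystem), "")
  cat("  ", length(subs), " subsystems; objective: ",
      object@objectiveReaction, "\n", sep = "")
})
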