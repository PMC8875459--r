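#' Accessors for MetabolicModel objects
#'
#' Read-only views of the model slots. \code{reactionBounds} returns a
#' data.frame with \code{id}, \code{lower_bound}, \code{upper_bound};
#' \code{subsystems} a named character vector (reaction id -> label);
#' \code{gprRules} the list of rule trees named by reaction id.
#'
#' @param object a \code{\linkS4class{MetabolicModel}}.
#' @return See details per accessor.
#' @name accessors
#' @aliases reactionIds metaboliteIds geneIds objectiveReaction
#'   reactionBounds subsystems gprRules stoichiometricMatrix
NULL

#' @rdname accessors
setMethod("reactionIds", "MetabolicModel", function(object)
  as.character(object@reactions$id))

#' @rdname accessors
setMethod("metaboliteIds", "MetabolicModel", function(object)
  as.character(object@metabolites$id))

#' @rdname accessors
setMethod("geneIds", "MetabolicModel", function(object) object@genes)

#' @rdname accessors
setMethod("objectiveReaction", "MetabolicModel", function(object)
  object@objectiveReaction)

#' @rdname accessors
setMethod("reactionBounds", "MetabolicModel", function(object)
  object@reactions[, c("id", "lower_bound", "upper_bound")])

#' @rdname accessors
setMethod("subsystems", "MetabolicModel", function(object)
  stats::setNames(as.character(object@reactions$subsystem),
                  object@reactions$id))

#' @rdname accessors
setMethod("gprRules", "MetabolicModel", function(object) object@gpr)

#' @rdname accessors
setMethod("stoichiometricMatrix", "MetabolicModel", function(object)
  object@stoichiometry)

#' Subset a model to a set of reactions
#'
#' Returns the sub-model induced by \code{ids}: listed reactions, the
#' metabolites they touch, and the genes referenced by their GPR rules. The
#' objective reaction must be among \code{ids}.
#'
#' @param object a \code{\linkS4class{MetabolicModel}}.
#' @param ids character vector of reaction ids to keep.
#' @return a \code{\linkS4class{MetabolicModel}}.
#' @name subsetReactions
#' @export
setMethod("subsetReactions", "MetabolicModel", function(object, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, reactionIds(object))
  if (length(missing))
    stop("unknown reaction ids: ", paste(missing, collapse = ", "))
  if (!(object@objectiveReaction %in% ids))
    stop("cannot drop the objective reaction '", object@objectiveReaction, "'")
  keep <- reactionIds(object) %in% ids
  S <- object@stoichiometry[, keep, drop = FALSE]
  met_keep <- Matrix::rowSums(S != 0) > 0
  S <- S[met_keep, , drop = FALSE]
  gpr <- object@gpr[keep]
  new("MetabolicModel",
      modelId = object@modelId,
      metabolites = object@metabolites[met_keep, , drop = FALSE],
      reactions = object@reactions[keep, , drop = FALSE],
      stoichiometry = S,
      gpr = gpr,
      genes = intersect(object@genes, unique(unlist(lapply(gpr, gprGenes)))),
      objectiveReaction = object@objectiveReaction)
})

#' Exchange reactions of a model
#'
#' A reaction is an exchange (boundary) reaction when it has exactly one
#' nonzero stoichiometric entry; by convention negative flux is uptake of
#' that metabolite. Reaction ids prefixed \code{EX_} are also honoured as a
#' hint but single-metabolite detection is authoritative.
#'
#' @param object a \code{\linkS4class{MetabolicModel}}.
#' @return data.frame with columns \code{id}, \code{metabolite},
#'   \code{coefficient}.
#' @name exchangeReactions
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(object) {
  S <- object@stoichiometry
  nnz <- Matrix::colSums(S != 0)
  ex <- which(nnz == 1L)
  if (!length(ex))
    return(data.frame(id = character(0), metabolite = character(0),
                      coefficient = numeric(0)))
  met <- vapply(ex, function(j) rownames(S)[which(S[, j] != 0)], character(1))
  coef <- vapply(seq_along(ex), function(k) S[met[k], ex[k]], numeric(1))
  data.frame(id = colnames(S)[ex], metabolite = met, coefficient = coef,
             stringsAsFactors = FALSE, row.names = NULL)
})
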