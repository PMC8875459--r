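#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction", function(object) standardGeneric("objectiveReaction"))

#' @rdname accessors
#' @export
setGeneric("reactionBounds", function(object) standardGeneric("reactionBounds"))

#' @rdname accessors
#' @export
setGeneric("subsystems", function(object) standardGeneric("subsystems"))

#' @rdname accessors
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))

#' @rdname accessors
#' @export
setGeneric("stoichiometricMatrix", function(object) standardGeneric("stoichiometricMatrix"))

#' @rdname subsetReactions
#' @export
setGeneric("subsetReactions", function(object, ids) standardGeneric("subsetReactions"))

#' @rdname exchangeReactions
#' @export
setGeneric("exchangeReactions", function(object) standardGeneric("exchangeReactions"))
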