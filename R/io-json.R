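## Internal JSON model dialect: a faithful, human-readable serialisation of
## MetabolicModel used by the toy generator and as an SBML-free interchange
## format. Schema: top-level object with model_id, metabolites (list of
## {id, name, compartment}), reactions (list of {id, name, subsystem,
## lower_bound, upper_bound, stoichiometry: {met: coef}, gpr: string}),
## genes (array) and objective (reaction id).

#' Read / write the internal JSON model dialect
#'
#' @param path file path.
#' @return \code{readModelJSON} returns a \code{\linkS4class{MetabolicModel}};
#'   \code{writeModelJSON} returns \code{path} invisibly.
#' @seealso \code{\link{readSBML}} for the standard format.
#' @export
readModelJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("model_id", "metabolites", "reactions", "objective")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("model JSON missing fields: ", paste(miss, collapse = ", "))
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "",
               stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(x$reactions, function(r)
    data.frame(id = r$id, name = r$name %||% r$id,
               subsystem = r$subsystem %||% "",
               lower_bound = r$lower_bound %||% -1000,
               upper_bound = r$upper_bound %||% 1000,
               stringsAsFactors = FALSE)))
  stoich <- lapply(x$reactions, function(r)
    vapply(r$stoichiometry, as.numeric, numeric(1)))
  names(stoich) <- rxns$id
  gpr <- lapply(x$reactions, function(r) r$gpr %||% "")
  names(gpr) <- rxns$id
  gpr <- gpr[vapply(gpr, nzchar, logical(1))]
  makeMetabolicModel(x$model_id, mets, rxns, stoich, gpr = gpr,
                     genes = unlist(x$genes), objectiveReaction = x$objective)
}

#' @rdname readModelJSON
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @export
writeModelJSON <- function(model, path) {
  S <- model@stoichiometry
  rxns <- lapply(seq_len(nrow(model@reactions)), function(i) {
    r <- model@reactions[i, ]
    nz <- which(S[, i] != 0)
    list(id = r$id, name = r$name, subsystem = r$subsystem,
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         stoichiometry = as.list(stats::setNames(S[nz, i], rownames(S)[nz])),
         gpr = gprToString(model@gpr[[i]]))
  })
  mets <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    m <- model@metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  out <- list(model_id = model@modelId, metabolites = mets, reactions = rxns,
              genes = model@genes, objective = model@objectiveReaction)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
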