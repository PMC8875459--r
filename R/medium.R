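#' Constrain a model to a medium composition
#'
#' Closes the uptake direction of every exchange reaction whose metabolite
#' is not in the medium; secretion directions and non-exchange reactions are
#' untouched. The uptake direction is the one consuming the extracellular
#' metabolite: negative flux when the exchange coefficient is negative (the
#' usual convention), positive flux otherwise. Idempotent, and never widens
#' a bound.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param medium character vector of permitted extracellular metabolite ids
#'   (may be empty: all uptakes closed).
#' @return the constrained \code{\linkS4class{MetabolicModel}}.
#' @examples
#' m <- makeToyNetwork(scenarioSpec(seed = 1))
#' closed <- applyMedium(m, character(0))
#' @export
applyMedium <- function(model, medium) {
  ex <- exchangeReactions(model)
  if (!nrow(ex)) return(model)
  for (k in seq_len(nrow(ex))) {
    if (ex$metabolite[k] %in% medium) next
    i <- match(ex$id[k], model@reactions$id)
    if (ex$coefficient[k] < 0) {
      ## uptake = negative flux
      model@reactions$lower_bound[i] <- max(model@reactions$lower_bound[i], 0)
    } else {
      ## reversed convention: uptake = positive flux
      model@reactions$upper_bound[i] <- min(model@reactions$upper_bound[i], 0)
    }
    ## a formerly *forced* uptake collapses to a closed reaction
    if (model@reactions$lower_bound[i] > model@reactions$upper_bound[i]) {
      model@reactions$lower_bound[i] <- 0
      model@reactions$upper_bound[i] <- 0
    }
  }
  methods::validObject(model)
  model
}
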