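#' Flux balance analysis
#'
#' Maximises flux through the model's objective reaction subject to the
#' steady-state constraint S v = 0 and the reaction bounds.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @return list with \code{status} (\code{"optimal"} or
#'   \code{"infeasible"}), \code{objective_value}, and \code{flux_vector}
#'   (named numeric, one entry per reaction).
#' @examples
#' m <- makeToyNetwork(scenarioSpec(seed = 1))
#' optimizeModel(m)$objective_value
#' @export
optimizeModel <- function(model) {
  rx <- model@reactions
  obj <- as.numeric(rx$id == model@objectiveReaction)
  sol <- solveLP(obj, model@stoichiometry, rep(0, nrow(model@metabolites)),
                 rx$lower_bound, rx$upper_bound, maximize = TRUE)
  list(status = sol$status,
       objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
       flux_vector = stats::setNames(sol$x, rx$id))
}

#' Flux variability analysis
#'
#' For every reaction, the minimum and maximum feasible flux subject to the
#' objective being at least \code{fraction_of_optimum} times its optimum
#' (two LPs per reaction).
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param fraction_of_optimum number in [0, 1]; 1 fixes the objective at its
#'   optimum.
#' @return data.frame with columns \code{id}, \code{vmin}, \code{vmax} and
#'   attribute \code{fraction_of_optimum}.
#' @export
fluxVariability <- function(model, fraction_of_optimum = 1.0) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  fba <- optimizeModel(model)
  if (fba$status != "optimal")
    stop("flux variability on an infeasible model")
  rx <- model@reactions
  lb <- rx$lower_bound; ub <- rx$upper_bound
  ## pin the objective with an extra row: c'v >= f * opt, encoded by
  ## tightening the objective reaction's lower bound (single-reaction
  ## objective, so this is exact)
  iobj <- match(model@objectiveReaction, rx$id)
  opt <- fba$objective_value
  ## a fraction is only meaningful for a non-negative optimum; a negative
  ## optimum is pinned at its value (relaxing it upward is infeasible)
  floor_obj <- if (opt >= 0) fraction_of_optimum * opt else opt
  lb[iobj] <- max(lb[iobj], floor_obj)
  if (lb[iobj] > ub[iobj]) lb[iobj] <- ub[iobj]
  S <- model@stoichiometry
  b <- rep(0, nrow(model@metabolites))
  n <- nrow(rx)
  vmin <- numeric(n); vmax <- numeric(n)
  for (i in seq_len(n)) {
    obj <- numeric(n); obj[i] <- 1
    lo <- solveLP(obj, S, b, lb, ub, maximize = FALSE)
    hi <- solveLP(obj, S, b, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("flux variability subproblem infeasible for reaction ", rx$id[i])
    vmin[i] <- lo$objective; vmax[i] <- hi$objective
  }
  ## numerical guard: a range is never inverted
  swap <- vmin > vmax
  if (any(swap)) { tmp <- vmin[swap]; vmin[swap] <- vmax[swap]; vmax[swap] <- tmp }
  out <- data.frame(id = rx$id, vmin = vmin, vmax = vmax,
                    stringsAsFactors = FALSE)
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  out
}
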