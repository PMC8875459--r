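## Context-specific model extraction.
##
## Given a flux-consistent reference model and a core set of reactions that
## expression evidence demands, the extractor searches for a compact
## flux-consistent sub-model containing every core reaction, by the classic
## alternation of two LPs: one pushing flux through the not-yet-covered
## core (LP7 of the consistency scheme) and one minimising the L1 norm of
## flux over penalised non-core reactions. Minimality is heuristic, not
## guaranteed; tie-breaking is declaration order, so extraction is
## deterministic.

## L1-minimisation step: min sum_{p in P} |v_p|  s.t.  S v = 0,
## v_k >= eps for k in K, bounds. |.| via t_p >= +-v_p.
.lpSparse <- function(S, lb, ub, K, P, eps) {
  n <- ncol(S); m <- nrow(S); k <- length(P)
  lb2 <- lb; lb2[K] <- pmax(lb[K], eps)
  if (!k) {
    sol <- solveLP(numeric(n), S, rep(0, m), lb2, ub, maximize = FALSE)
    return(if (sol$status == "optimal") sol$x else NULL)
  }
  Aeq <- cbind(S, matrix(0, m, k))
  ## t_p - v_p >= 0 and t_p + v_p >= 0
  A1 <- matrix(0, k, n + k); A2 <- matrix(0, k, n + k)
  for (t in seq_len(k)) {
    A1[t, P[t]] <- -1; A1[t, n + t] <- 1
    A2[t, P[t]] <- 1; A2[t, n + t] <- 1
  }
  sol <- .solveLPG(c(rep(0, n), rep(1, k)), Aeq, rep(0, m),
                   rbind(A1, A2), rep(0, 2 * k),
                   c(lb2, rep(0, k)), c(ub, rep(.LP_BIG, k)),
                   maximize = FALSE)
  if (sol$status != "optimal") return(NULL)
  sol$x[seq_len(n)]
}

#' Extract a context-specific sub-model
#'
#' Returns a flux-consistent sub-model of \code{model} containing every
#' reaction in \code{core}. The medium is applied before extraction. The
#' objective (biomass) reaction is always forced into the core. Reactions
#' in \code{unpenalized} (e.g. reactions whose activity is undecided by the
#' expression evidence, or reactions with no GPR rule) carry zero weight in
#' the expansion objective: they may be recruited freely but are not sought.
#'
#' @param model a flux-consistent \code{\linkS4class{MetabolicModel}}
#'   (apply \code{\link{dropBlockedReactions}} first).
#' @param core character vector of reaction ids that must be present.
#' @param medium extracellular metabolite ids allowed for uptake, or
#'   \code{NULL} to leave exchanges as they are.
#' @param flux_epsilon activation threshold (default 1e-4).
#' @param unpenalized reaction ids excluded from the L1 penalty.
#' @return a \code{\linkS4class{MetabolicModel}}.
#' @export
extractContextModel <- function(model, core, medium = NULL,
                                flux_epsilon = 1e-4,
                                unpenalized = character(0)) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  core <- union(as.character(core), model@objectiveReaction)
  unknown <- setdiff(core, model@reactions$id)
  if (length(unknown))
    stop("core contains unknown reaction ids: ", paste(unknown, collapse = ", "))

  ## reject cores blocked under the medium, with an explicit listing
  ## (checked per core reaction only; 2 LPs each)
  blocked_core <- setdiff(core, .consistentAmong(model, core, flux_epsilon))
  if (length(blocked_core))
    stop("infeasible core: reaction(s) blocked under the given medium/bounds: ",
         paste(sort(blocked_core), collapse = ", "))

  ids <- model@reactions$id
  A_idx <- .fastcoreIndices(model, match(core, ids),
                            match(intersect(unpenalized, ids), ids),
                            flux_epsilon)
  out <- subsetReactions(model, ids[sort(A_idx)])

  ## guarantee: every retained reaction is active at flux_epsilon in the
  ## sub-model; prune any non-core stragglers (rare numerical corner)
  ok <- consistentReactionsOracle(out, flux_epsilon)
  straggler <- setdiff(reactionIds(out), union(ok, core))
  if (length(straggler))
    out <- subsetReactions(out, setdiff(reactionIds(out), straggler))
  out
}

.fastcoreIndices <- function(model, core_idx, unpen_idx, eps) {
  S <- as.matrix(model@stoichiometry)
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  n <- ncol(S)
  supp_tol <- eps * 0.99
  irr <- lb >= 0
  P_all <- setdiff(setdiff(seq_len(n), core_idx), unpen_idx)

  lp7 <- function(J) {
    k <- length(J)
    if (!k) return(numeric(n))
    m <- nrow(S)
    Aeq <- cbind(S, matrix(0, m, k))
    Age <- matrix(0, k, n + k)
    for (t in seq_len(k)) { Age[t, J[t]] <- 1; Age[t, n + t] <- -1 }
    sol <- .solveLPG(c(rep(0, n), rep(1, k)), Aeq, rep(0, m), Age, rep(0, k),
                     c(lb, rep(0, k)), c(ub, rep(eps, k)), maximize = TRUE)
    if (sol$status != "optimal") return(numeric(n))
    sol$x[seq_len(n)]
  }
  findSparseMode <- function(J, P) {
    v <- lp7(J)
    K <- intersect(J, which(v >= supp_tol))
    if (!length(K)) return(integer(0))
    v <- .lpSparse(S, lb, ub, K, P, eps)
    if (is.null(v)) return(integer(0))
    which(abs(v) >= supp_tol)
  }

  flipped <- FALSE; singleton <- FALSE
  J <- intersect(core_idx, which(irr))
  P <- P_all
  A <- findSparseMode(J, P)
  if (length(setdiff(J, A)))
    stop("infeasible core: irreversible core reaction(s) cannot carry flux: ",
         paste(model@reactions$id[setdiff(J, A)], collapse = ", "))
  J <- setdiff(core_idx, A)
  while (length(J)) {
    P <- setdiff(P, A)
    Ji <- if (singleton) J[1] else J
    Anew <- findSparseMode(Ji, P)
    A <- union(A, Anew)
    if (any(J %in% A)) {
      J <- setdiff(J, A); flipped <- FALSE; singleton <- FALSE
    } else {
      JiRev <- setdiff(Ji, which(irr))
      if (flipped || !length(JiRev)) {
        if (singleton)
          stop("infeasible core: reaction cannot be activated: ",
               model@reactions$id[J[1]])
        flipped <- FALSE; singleton <- TRUE
      } else {
        S[, JiRev] <- -S[, JiRev]
        tmp <- lb[JiRev]; lb[JiRev] <- -ub[JiRev]; ub[JiRev] <- -tmp
        irr <- lb >= 0
        flipped <- TRUE
      }
    }
  }
  A
}

#' Build one context model from expression evidence
#'
#' Convenience pipeline for a single condition: apply the medium, drop
#' blocked reactions, call gene activity, map calls to core reactions
#' (forcing the biomass reaction), and extract.
#'
#' @param model reference \code{\linkS4class{MetabolicModel}}.
#' @param expression expression table (see \code{\link{readExpression}}).
#' @param condition_id condition column to use.
#' @param medium permitted uptake metabolites, or NULL.
#' @param high_threshold,low_threshold activity-call thresholds.
#' @param flux_epsilon activation threshold.
#' @return a \code{\linkS4class{MetabolicModel}} named
#'   \code{<model>_<condition>}.
#' @export
buildContextModel <- function(model, expression, condition_id, medium = NULL,
                              high_threshold = 1, low_threshold = 0,
                              flux_epsilon = 1e-4) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  consistent <- dropBlockedReactions(model, flux_epsilon)
  calls <- callActivity(expression, condition_id, high_threshold, low_threshold)
  mapped <- genesToCoreReactions(consistent, calls)
  out <- extractContextModel(consistent,
                             core = union(mapped$core,
                                          consistent@objectiveReaction),
                             medium = NULL, flux_epsilon = flux_epsilon,
                             unpenalized = mapped$unpenalized)
  out@modelId <- paste0(model@modelId, "_", condition_id)
  out
}
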