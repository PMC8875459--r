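## Flux-consistency testing.
##
## A reaction is blocked when it cannot carry |flux| >= epsilon in any
## steady state within bounds. fastcc() finds the consistent set with the
## classic LP scheme: one LP that simultaneously pushes flux through as
## many candidate reactions as possible (auxiliary variables z_j <= eps,
## v_j >= z_j), plus direction flips for reversible candidates. The
## brute-force alternative (two LPs per reaction) is exposed as
## consistentReactionsOracle() and doubles as the test oracle.

## general LP with equality rows plus ">=0" coupling rows, built by slack
## augmentation on top of solveLP
.solveLPG <- function(obj, Aeq, beq, Age = NULL, bge = NULL, lb, ub,
                      maximize = TRUE) {
  Aeq <- as.matrix(Aeq)
  n <- ncol(Aeq)
  if (is.null(Age)) {
    return(solveLP(obj, Aeq, beq, lb, ub, maximize))
  }
  Age <- as.matrix(Age)
  k <- nrow(Age)
  ## a'x >= b  <=>  a'x - s = b, s in [0, BIG]
  A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), k)),
             cbind(Age, diag(-1, k)))
  sol <- solveLP(c(obj, rep(0, k)), A, c(beq, bge),
                 c(lb, rep(0, k)), c(ub, rep(.LP_BIG, k)), maximize)
  sol$x <- sol$x[seq_len(n)]
  sol
}

#' Consistent reactions of a model
#'
#' Returns the ids of reactions able to carry \code{|flux| >= flux_epsilon}
#' in some steady-state solution within bounds, using the LP scheme with
#' auxiliary per-reaction activation variables and direction flips.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param flux_epsilon activation threshold (default 1e-4 mmol/gDW/h).
#' @return character vector of consistent reaction ids.
#' @seealso \code{\link{consistentReactionsOracle}} for the brute-force
#'   equivalent, \code{\link{dropBlockedReactions}}.
#' @export
fastcc <- function(model, flux_epsilon = 1e-4) {
  S <- as.matrix(model@stoichiometry)
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  ids <- model@reactions$id
  n <- length(ids)
  eps <- flux_epsilon
  supp_tol <- eps * 0.99

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

  irr <- lb >= 0
  J <- which(irr)
  v <- lp7(J)
  A <- which(abs(v) >= supp_tol)
  incI <- setdiff(J, A)
  J <- setdiff(setdiff(seq_len(n), A), incI)
  singleton <- FALSE; flipped <- FALSE
  while (length(J)) {
    Ji <- if (singleton) J[1] else J
    v <- lp7(Ji)
    A <- union(A, which(abs(v) >= supp_tol))
    if (any(J %in% A)) {
      J <- setdiff(J, A); flipped <- FALSE; singleton <- FALSE
    } else {
      JiRev <- setdiff(Ji, which(irr))
      if (flipped || !length(JiRev)) {
        flipped <- FALSE
        if (singleton) J <- setdiff(J, Ji) else singleton <- TRUE
      } else {
        ## flip direction of the reversible candidates
        S[, JiRev] <- -S[, JiRev]
        tmp <- lb[JiRev]; lb[JiRev] <- -ub[JiRev]; ub[JiRev] <- -tmp
        flipped <- TRUE
      }
    }
  }
  ids[sort(A)]
}

#' Brute-force consistency oracle
#'
#' Two LPs per reaction: maximise and minimise its flux; consistent iff the
#' maximum is \code{>= flux_epsilon} or the minimum \code{<= -flux_epsilon}
#' (within solver tolerance). Independent of \code{\link{fastcc}}'s search
#' strategy.
#'
#' @inheritParams fastcc
#' @return character vector of consistent reaction ids.
#' @export
consistentReactionsOracle <- function(model, flux_epsilon = 1e-4) {
  .consistentAmong(model, model@reactions$id, flux_epsilon)
}

## per-reaction max/min-flux test restricted to `ids`
.consistentAmong <- function(model, ids, flux_epsilon) {
  S <- model@stoichiometry
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  b <- rep(0, nrow(model@metabolites))
  n <- nrow(model@reactions)
  idx <- match(ids, model@reactions$id)
  ok <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    obj <- numeric(n); obj[i] <- 1
    hi <- solveLP(obj, S, b, lb, ub, maximize = TRUE)
    if (hi$status == "optimal" && hi$objective >= flux_epsilon - 1e-9) {
      ok[k] <- TRUE; next
    }
    lo <- solveLP(obj, S, b, lb, ub, maximize = FALSE)
    ok[k] <- lo$status == "optimal" && lo$objective <= -(flux_epsilon - 1e-9)
  }
  ids[ok]
}

#' Drop blocked reactions
#'
#' Convenience wrapper: subset the model to its \code{\link{fastcc}}
#' consistent set (the objective reaction is always retained).
#'
#' @inheritParams fastcc
#' @return a flux-consistent \code{\linkS4class{MetabolicModel}}.
#' @export
dropBlockedReactions <- function(model, flux_epsilon = 1e-4) {
  keep <- union(fastcc(model, flux_epsilon), model@objectiveReaction)
  subsetReactions(model, keep)
}

#' Discretise expression scores into activity calls
#'
#' Genes scoring at or above \code{high_threshold} are called active
#' (core), at or below \code{low_threshold} inactive, in between unknown.
#' A deliberately simple stand-in for full microarray discretisation
#' pipelines: the thresholds are explicit and the caller owns them.
#'
#' @param expression data.frame from \code{\link{readExpression}}.
#' @param condition_id name of the condition column.
#' @param high_threshold,low_threshold numeric thresholds,
#'   \code{high_threshold >= low_threshold}.
#' @return list with \code{condition_id}, \code{core_genes},
#'   \code{inactive_genes}, \code{unknown_genes} (disjoint character sets).
#' @export
callActivity <- function(expression, condition_id, high_threshold = 1,
                         low_threshold = 0) {
  stopifnot(high_threshold >= low_threshold)
  if (!condition_id %in% names(expression))
    stop("condition '", condition_id, "' absent from expression table")
  sc <- expression[[condition_id]]
  if (all(is.na(sc)))
    stop("condition '", condition_id, "' has no usable scores (all missing)")
  genes <- as.character(expression$gene_id)
  core <- genes[!is.na(sc) & sc >= high_threshold]
  inactive <- genes[!is.na(sc) & sc <= low_threshold & sc < high_threshold]
  list(condition_id = condition_id,
       core_genes = core,
       inactive_genes = inactive,
       unknown_genes = setdiff(genes, c(core, inactive)))
}

#' Map gene activity calls to core reactions
#'
#' A reaction is core when its GPR rule is satisfied by the active genes
#' alone (inactive and unknown genes FALSE). A reaction that fails that
#' test but is satisfied once unknown genes are allowed TRUE is left
#' undecided: neither core nor penalised during extraction. Reactions with
#' no GPR rule carry no expression evidence and are likewise unpenalised.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param calls activity calls from \code{\link{callActivity}}.
#' @return list with character vectors \code{core}, \code{unpenalized},
#'   \code{inactive} (reaction ids; the remainder of the model is the
#'   penalised background).
#' @export
genesToCoreReactions <- function(model, calls) {
  states_strict <- c(
    stats::setNames(rep(TRUE, length(calls$core_genes)), calls$core_genes),
    stats::setNames(rep(FALSE, length(calls$inactive_genes)),
                    calls$inactive_genes),
    stats::setNames(rep(FALSE, length(calls$unknown_genes)),
                    calls$unknown_genes))
  states_optimistic <- states_strict
  states_optimistic[calls$unknown_genes] <- TRUE
  ids <- model@reactions$id
  has_rule <- !vapply(model@gpr, is.null, logical(1))
  strict <- vapply(model@gpr, evaluateGprStates, logical(1),
                   states = states_strict, default = FALSE)
  optimistic <- vapply(model@gpr, evaluateGprStates, logical(1),
                       states = states_optimistic, default = FALSE)
  core <- ids[has_rule & strict]
  unpen <- ids[(!has_rule) | (has_rule & !strict & optimistic)]
  inactive <- ids[has_rule & !optimistic]
  list(core = core, unpenalized = unpen, inactive = inactive)
}
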