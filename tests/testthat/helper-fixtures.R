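# Hand-built fixtures and a small random-network generator used across the
# suite. All expected values asserted against these were computed by hand
# (linear chains / parallel paths admit closed-form LP solutions) or by the
# enumeration oracle.

# EX_A (uptake up to 10) -> A -> B -> biomass; optimum 10
chainModel <- function() {
  makeMetabolicModel("chain",
    metabolites = data.frame(id = c("A_e", "A", "B"),
                             compartment = c("e", "c", "c")),
    reactions = data.frame(id = c("EX_A", "T_A", "R1", "BIO"),
                           subsystem = c("exchange", "transport", "core", "biomass"),
                           lower_bound = c(-10, 0, 0, 0),
                           upper_bound = c(1000, 1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A_e = -1),
                         T_A = c(A_e = -1, A = 1),
                         R1 = c(A = -1, B = 1),
                         BIO = c(B = -1)),
    gpr = c(T_A = "gT", R1 = "g1a and g1b"),
    objectiveReaction = "BIO")
}

# two routes of capacity 4 and 6 from A to D, biomass drains D; optimum 10.
# R_hi / R_lo carry OR-isozyme and single-gene rules for knockout tests.
parallelModel <- function() {
  makeMetabolicModel("parallel",
    metabolites = data.frame(id = c("A_e", "A", "B", "C", "D"),
                             compartment = c("e", rep("c", 4))),
    reactions = data.frame(id = c("EX_A", "T_A", "R_lo", "R_hi", "J_lo", "J_hi", "BIO"),
                           lower_bound = c(-10, 0, 0, 0, 0, 0, 0),
                           upper_bound = c(1000, 1000, 4, 6, 1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A_e = -1),
                         T_A = c(A_e = -1, A = 1),
                         R_lo = c(A = -1, B = 1),
                         R_hi = c(A = -1, C = 1),
                         J_lo = c(B = -1, D = 1),
                         J_hi = c(C = -1, D = 1),
                         BIO = c(D = -1)),
    gpr = c(R_lo = "gLo", R_hi = "gHiA or gHiB", T_A = "gT"),
    objectiveReaction = "BIO")
}

# random small network: n reactions touching m metabolites, random bounds
# and a random objective; may be infeasible or have zero optimum -- callers
# handle both. Used for solver-vs-oracle and consistency-vs-oracle checks.
randomNetwork <- function(seed, n_max = 8, contain_zero = FALSE) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  m <- sample(2:(n - 1), 1)
  mets <- sprintf("M%d", seq_len(m))
  S <- matrix(0, m, n, dimnames = list(mets, sprintf("R%d", seq_len(n))))
  for (j in seq_len(n)) {
    touch <- sample(m, sample(1:min(2, m), 1))
    S[touch, j] <- sample(c(-2, -1, 1, 2), length(touch), replace = TRUE)
  }
  lb <- round(runif(n, -10, 2), 1)
  ub <- lb + round(runif(n, 0, 10), 1)
  keep0 <- runif(n) < 0.5           # half the reactions are irreversible
  lb[keep0] <- pmax(lb[keep0], 0); ub[keep0] <- pmax(ub[keep0], lb[keep0])
  if (contain_zero) {               # zero flux feasible, as in real models
    lb <- pmin(lb, 0); ub <- pmax(ub, 0)
  }
  makeMetabolicModel(sprintf("rand%d", seed),
    metabolites = data.frame(id = mets),
    reactions = data.frame(id = colnames(S), lower_bound = lb, upper_bound = ub),
    stoichiometry = S,
    objectiveReaction = sample(colnames(S), 1))
}

# random GPR tree over a gene pool, depth-bounded
randomGprTree <- function(depth, genes) {
  if (depth <= 0 || runif(1) < 0.35) return(sample(genes, 1))
  list(op = sample(c("and", "or"), 1),
       args = lapply(seq_len(sample(2:3, 1)),
                     function(i) randomGprTree(depth - 1, genes)))
}

# straight-line truth-table evaluation: enumerate nothing, just recurse
# with explicit boolean substitution (independent of evaluateGpr's
# knocked-set interface)
evalTreeWith <- function(tree, assignment) {
  if (is.character(tree)) return(assignment[[tree]])
  vals <- vapply(tree$args, evalTreeWith, logical(1), assignment = assignment)
  if (tree$op == "and") all(vals) else any(vals)
}
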