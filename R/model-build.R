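#' Construct a MetabolicModel
#'
#' Builds and validates a \code{\linkS4class{MetabolicModel}} from plain R
#' structures. Bounds default to the conventional \code{c(-1000, 1000)} for
#' reversible reactions when absent.
#'
#' @param modelId model identifier.
#' @param metabolites data.frame with column \code{id}; \code{name} and
#'   \code{compartment} are filled with \code{id} / \code{""} when missing.
#' @param reactions data.frame with column \code{id}; missing \code{name},
#'   \code{subsystem}, \code{lower_bound}, \code{upper_bound} columns are
#'   defaulted.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (metabolite id -> coefficient), or a matrix with matching dimnames.
#' @param gpr named character vector or list of rule strings / parsed trees,
#'   by reaction id; unlisted reactions get no rule.
#' @param genes gene universe; defaults to the union of GPR leaves.
#' @param objectiveReaction id of the biomass/objective reaction.
#' @return a validated \code{\linkS4class{MetabolicModel}}.
#' @examples
#' m <- makeMetabolicModel("mini",
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = c("EX_A", "R1", "BIO"),
#'                          lower_bound = c(-10, 0, 0),
#'                          upper_bound = c(1000, 1000, 1000)),
#'   stoichiometry = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
#'                        BIO = c(B = -1)),
#'   gpr = c(R1 = "g1"), objectiveReaction = "BIO")
#' @export
makeMetabolicModel <- function(modelId, metabolites, reactions, stoichiometry,
                               gpr = list(), genes = NULL,
                               objectiveReaction) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- ""
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$lower_bound)) reactions$lower_bound <- -1000
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- 1000
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  metabolites <- metabolites[, c("id", "name", "compartment")]
  reactions <- reactions[, c("id", "name", "subsystem",
                             "lower_bound", "upper_bound")]
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL

  if (is.matrix(stoichiometry) || methods::is(stoichiometry, "Matrix")) {
    S <- Matrix::Matrix(stoichiometry, sparse = TRUE)
    S <- S[match(metabolites$id, rownames(S)),
           match(reactions$id, colnames(S)), drop = FALSE]
  } else {
    S <- Matrix::Matrix(0, nrow(metabolites), nrow(reactions), sparse = TRUE,
                        dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoichiometry)) {
      entry <- stoichiometry[[rid]]
      if (!rid %in% reactions$id)
        stop("stoichiometry given for undeclared reaction '", rid, "'")
      bad <- setdiff(names(entry), metabolites$id)
      if (length(bad))
        stop("reaction '", rid, "' references undeclared metabolites: ",
             paste(bad, collapse = ", "))
      S[names(entry), rid] <- unname(entry)
    }
  }

  rules <- stats::setNames(vector("list", nrow(reactions)), reactions$id)
  for (rid in names(gpr)) {
    if (!rid %in% reactions$id)
      stop("GPR rule given for undeclared reaction '", rid, "'")
    r <- gpr[[rid]]
    rules[[rid]] <- if (is.character(r) && length(r) == 1L) parseGpr(r) else r
  }
  leaf_genes <- unique(unlist(lapply(rules, gprGenes)))
  if (is.null(genes)) genes <- leaf_genes
  genes <- sort(unique(c(genes, leaf_genes)))

  methods::new("MetabolicModel",
               modelId = as.character(modelId),
               metabolites = metabolites,
               reactions = reactions,
               stoichiometry = S,
               gpr = rules,
               genes = as.character(genes),
               objectiveReaction = as.character(objectiveReaction))
}

#' Structural equality of two models
#'
#' TRUE when the two models agree on metabolites, reactions (ids, names,
#' subsystems, bounds), stoichiometry, GPR rules, genes and objective,
#' ignoring row order. Used by the read/write round-trip tests.
#'
#' @param a,b \code{\linkS4class{MetabolicModel}} objects.
#' @param tol numeric tolerance on bounds and coefficients.
#' @return logical scalar.
#' @export
modelsEqual <- function(a, b, tol = 1e-9) {
  ra <- a@reactions[order(a@reactions$id), ]
  rb <- b@reactions[order(b@reactions$id), ]
  ma <- a@metabolites[order(a@metabolites$id), ]
  mb <- b@metabolites[order(b@metabolites$id), ]
  if (!identical(ra$id, rb$id) || !identical(ma$id, mb$id)) return(FALSE)
  if (!identical(ra$subsystem, rb$subsystem)) return(FALSE)
  if (max(abs(ra$lower_bound - rb$lower_bound),
          abs(ra$upper_bound - rb$upper_bound)) > tol) return(FALSE)
  Sa <- a@stoichiometry[ma$id, ra$id, drop = FALSE]
  Sb <- b@stoichiometry[ma$id, ra$id, drop = FALSE]
  if (max(abs(Sa - Sb)) > tol) return(FALSE)
  if (!identical(sort(a@genes), sort(b@genes))) return(FALSE)
  if (!identical(a@objectiveReaction, b@objectiveReaction)) return(FALSE)
  for (rid in ra$id) {
    if (!identical(gprToString(a@gpr[[rid]]), gprToString(b@gpr[[rid]])))
      return(FALSE)
  }
  TRUE
}
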