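## Seeded toy scenarios with planted signals.
##
## The generated network has one essential "backbone" pathway producing a
## biomass precursor E, and n_pathways - 1 redundant pathways that each
## produce the common currency X; biomass consumes E + X. Knocking out the
## backbone therefore arrests growth (grRatio 0) while any single
## redundant pathway can be lost without growth cost -- which is exactly
## what lets a planted expression shutdown of a redundant pathway show up
## as a presence-rate drop without making extraction infeasible.

#' Scenario specification for the toy-data generator
#'
#' Defaults describe a small screen: a control plus 12 product conditions
#' in a 4-pathway network, two planted growth-essential products, two
#' planted pathway shutdowns and a handful of reference cancer drugs, two
#' of which hit the essential backbone.
#'
#' @param n_pathways number of pathways (>= 2; pathway 1 is the backbone).
#' @param reactions_per_pathway chain length per pathway (>= 1; the
#'   default 4 keeps pathways above the default report size cutoff of 3).
#' @param n_products number of natural-product conditions.
#' @param n_reference_drugs number of cancer drugs in the target table.
#' @param planted_essential_products product labels whose targets are the
#'   essential backbone genes.
#' @param planted_pathway_shutdown data.frame with columns \code{product},
#'   \code{pathway}: conditions whose expression silences that pathway.
#' @param noise_rate probability that a gene's score in a given condition
#'   is an ambiguous (contaminated) measurement drawn from a
#'   mid-distribution centred between the activity thresholds (default 0:
#'   clean separation).
#' @param seed integer RNG seed.
#' @return list of class \code{npflux_scenario_spec}.
#' @export
scenarioSpec <- function(n_pathways = 4, reactions_per_pathway = 4,
                         n_products = 12, n_reference_drugs = 4,
                         planted_essential_products = c("product_01",
                                                        "product_04"),
                         planted_pathway_shutdown = data.frame(
                           product = c("product_02", "product_03"),
                           pathway = c("pathway_2", "pathway_3"),
                           stringsAsFactors = FALSE),
                         noise_rate = 0, seed = 1L) {
  if (n_pathways < 2) stop("degenerate scenario: need at least 2 pathways")
  stopifnot(reactions_per_pathway >= 1, n_products >= 1,
            noise_rate >= 0, noise_rate <= 1)
  labels <- sprintf("product_%02d", seq_len(n_products))
  ## default plantings silently shrink to fit small custom scenarios;
  ## explicitly supplied plantings are validated strictly below
  if (missing(planted_essential_products))
    planted_essential_products <-
      intersect(planted_essential_products, labels)
  if (missing(planted_pathway_shutdown))
    planted_pathway_shutdown <- planted_pathway_shutdown[
      planted_pathway_shutdown$product %in% labels &
      planted_pathway_shutdown$pathway %in%
        sprintf("pathway_%d", seq_len(n_pathways))[-1], , drop = FALSE]
  if (!all(planted_essential_products %in% labels))
    stop("planted essential products outside the generated label set")
  if (nrow(planted_pathway_shutdown) &&
      !all(planted_pathway_shutdown$product %in% labels))
    stop("planted shutdown products outside the generated label set")
  ok_pw <- sprintf("pathway_%d", 2:n_pathways)
  if (nrow(planted_pathway_shutdown) &&
      !all(planted_pathway_shutdown$pathway %in% ok_pw))
    stop("planted shutdowns must hit a redundant pathway (pathway_2 ...)")
  structure(list(
    n_pathways = n_pathways,
    reactions_per_pathway = reactions_per_pathway,
    n_products = n_products,
    n_reference_drugs = n_reference_drugs,
    planted_essential_products = planted_essential_products,
    planted_pathway_shutdown = planted_pathway_shutdown,
    noise_rate = noise_rate,
    seed = as.integer(seed)),
    class = "npflux_scenario_spec")
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a toy metabolic network
#'
#' See \code{\link{scenarioSpec}} for the layout. GPR rules mix single
#' genes, two-gene AND complexes (second chain position) and two-gene OR
#' isozyme pairs (third chain position). Every exchange has uptake bound
#' -10; internal bounds are 0..1000; the biomass reaction is the
#' objective. Wild-type growth is positive by construction.
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @return a \code{\linkS4class{MetabolicModel}}.
#' @export
makeToyNetwork <- function(spec) {
  stopifnot(inherits(spec, "npflux_scenario_spec"))
  .withSeed(spec$seed, {
    P <- spec$n_pathways; k <- spec$reactions_per_pathway
    mets <- data.frame(id = character(0), name = character(0),
                       compartment = character(0), stringsAsFactors = FALSE)
    rxns <- list(); stoich <- list(); gpr <- list()
    addMet <- function(id, comp) {
      if (!id %in% mets$id)
        mets <<- rbind(mets, data.frame(id = id, name = id, compartment = comp,
                                        stringsAsFactors = FALSE))
    }
    addRxn <- function(id, sub, lb, ub, st, rule = NULL) {
      rxns[[id]] <<- data.frame(id = id, name = id, subsystem = sub,
                                lower_bound = lb, upper_bound = ub,
                                stringsAsFactors = FALSE)
      stoich[[id]] <<- st
      if (!is.null(rule)) gpr[[id]] <<- rule
    }
    addMet("E_pre", "c"); addMet("X_cur", "c")
    for (p in seq_len(P)) {
      nut <- sprintf("nut%d_e", p)
      addMet(nut, "e")
      addRxn(sprintf("EX_nut%d", p), "exchange", -10, 1000,
             stats::setNames(-1, nut))
      prev <- nut
      for (j in seq_len(k)) {
        prod_met <- if (j < k) sprintf("m%d_%d", p, j)
                    else if (p == 1) "E_pre" else "X_cur"
        if (j < k) addMet(prod_met, "c")
        rid <- sprintf("C%d_%d", p, j)
        rule <- if (j == 2 && k >= 2) {
          list(op = "and", args = list(sprintf("g_p%d_r%d_a", p, j),
                                       sprintf("g_p%d_r%d_b", p, j)))
        } else if (j == 3 && k >= 3) {
          list(op = "or", args = list(sprintf("g_p%d_r%d_a", p, j),
                                      sprintf("g_p%d_r%d_b", p, j)))
        } else sprintf("g_p%d_r%d", p, j)
        addRxn(rid, sprintf("pathway_%d", p), 0, 1000,
               stats::setNames(c(-1, 1), c(prev, prod_met)), rule)
        prev <- prod_met
      }
    }
    addRxn("BIOMASS", "biomass", 0, 1000,
           c(E_pre = -1, X_cur = -1))
    makeMetabolicModel(
      sprintf("toy_P%d_k%d_seed%d", P, k, spec$seed),
      metabolites = mets,
      reactions = do.call(rbind, rxns),
      stoichiometry = stoich, gpr = gpr,
      objectiveReaction = "BIOMASS")
  })
}

## genes controlling the reactions of one pathway subsystem
.pathwayGenes <- function(model, pathway) {
  idx <- which(model@reactions$subsystem == pathway)
  unique(unlist(lapply(model@gpr[idx], gprGenes)))
}

#' Generate per-condition data for a toy scenario
#'
#' Produces the expression table (control plus one column per product),
#' the drug-target table (products and reference cancer drugs), the medium
#' (all nutrient metabolites) and a truth record of everything planted.
#'
#' Expression scores are drawn from N(2, 0.5^2) for intended-active genes
#' and N(-2, 0.5^2) for intended-inactive ones, cleanly separated by the
#' default activity thresholds (1, 0); with probability \code{noise_rate}
#' a measurement is contaminated: its score comes from an ambiguous
#' mid-distribution N(0.5, 0.5^2) straddling the threshold band, so the
#' resulting call is usually unknown and occasionally an outright
#' miscall.
#'
#' @param model model from \code{\link{makeToyNetwork}}.
#' @param spec the same \code{\link{scenarioSpec}}.
#' @return list with \code{expression}, \code{targets}, \code{medium},
#'   \code{truth}.
#' @export
makeConditionData <- function(model, spec) {
  stopifnot(inherits(spec, "npflux_scenario_spec"))
  .withSeed(spec$seed + 1L, {
    genes <- model@genes
    products <- sprintf("product_%02d", seq_len(spec$n_products))
    shutdown <- spec$planted_pathway_shutdown
    backbone_genes <- .pathwayGenes(model, "pathway_1")
    ## the single-gene essential step of the backbone (first chain position)
    essential_target <- grep("^g_p1_r1$", genes, value = TRUE)
    if (!length(essential_target)) essential_target <- backbone_genes[1]
    redundant_pw <- sprintf("pathway_%d", 2:spec$n_pathways)
    redundant_genes <- unique(unlist(lapply(redundant_pw, .pathwayGenes,
                                            model = model)))

    ## scores: N(2, .5^2) for intended-active, N(-2, .5^2) for
    ## intended-inactive; with probability noise_rate a measurement is
    ## contaminated and drawn from an ambiguous mid-distribution
    ## N(0.5, .5^2) centred between the default thresholds (1, 0)
    draw <- function(active) {
      contaminated <- stats::runif(length(active)) < spec$noise_rate
      mu <- ifelse(contaminated, 0.5, ifelse(active, 2, -2))
      stats::rnorm(length(active), mu, 0.5)
    }
    expr <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    expr[["DMSO"]] <- draw(rep(TRUE, length(genes)))
    for (p in products) {
      active <- rep(TRUE, length(genes))
      hit <- shutdown$pathway[shutdown$product == p]
      if (length(hit))
        active[genes %in% unlist(lapply(hit, .pathwayGenes, model = model))] <- FALSE
      expr[[p]] <- draw(active)
    }

    rows <- list()
    for (p in products) {
      if (p %in% spec$planted_essential_products) {
        tg <- essential_target
      } else if (p %in% shutdown$product) {
        pw <- shutdown$pathway[shutdown$product == p][1]
        tg <- utils::head(.pathwayGenes(model, pw), 2)
      } else {
        tg <- sample(redundant_genes, 1)
      }
      rows[[p]] <- data.frame(drug_id = p, gene_id = tg,
                              drug_class = "natural_product",
                              stringsAsFactors = FALSE)
    }
    for (d in seq_len(spec$n_reference_drugs)) {
      lab <- sprintf("cancer_drug_%02d", d)
      tg <- if (d <= 2) essential_target else sample(redundant_genes, 2)
      rows[[lab]] <- data.frame(drug_id = lab, gene_id = tg,
                                drug_class = "cancer_drug",
                                stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, rows)
    rownames(targets) <- NULL
    targets <- targets[!duplicated(targets[, c("drug_id", "gene_id")]), ]

    list(expression = expr,
         targets = targets,
         medium = grep("^nut", model@metabolites$id, value = TRUE),
         truth = list(
           seed = spec$seed,
           essential_products = spec$planted_essential_products,
           essential_genes = essential_target,
           shutdown = shutdown,
           backbone_pathway = "pathway_1",
           noise_rate = spec$noise_rate))
  })
}

#' Planted-signal recovery for one seeded scenario
#'
#' Runs the two readouts that the planted signals are designed to drive:
#' the knockout screen on the control context model (step 1) and the
#' pathway presence-rate alteration of the first planted shutdown
#' condition (step 4). Recovery means the screen flags exactly the planted
#' essential products, and the planted pathway ranks first by absolute
#' presence-rate difference with \code{|difference| >= 0.1}.
#'
#' @param seed scenario seed.
#' @param noise_rate activity-state flip probability.
#' @return list with logicals \code{step1_ok}, \code{step4_ok},
#'   \code{recovered}, plus \code{flagged_products},
#'   \code{top_pathway} and \code{planted_difference}.
#' @export
plantedSignalRecovery <- function(seed, noise_rate = 0) {
  spec <- scenarioSpec(noise_rate = noise_rate, seed = seed)
  m <- makeToyNetwork(spec)
  dat <- makeConditionData(m, spec)
  ctrl <- buildContextModel(m, dat$expression, "DMSO", dat$medium)
  np <- dat$targets[dat$targets$drug_class == "natural_product", , drop = FALSE]
  screen <- drugDeletion(ctrl, np)
  flagged <- screen$label[screen$grRatio == 0]
  step1_ok <- setequal(flagged, spec$planted_essential_products)

  sh <- spec$planted_pathway_shutdown[1, ]
  tr <- buildContextModel(m, dat$expression, sh$product, dat$medium)
  idx <- buildPathwayIndex(m)
  rep <- alterationReport(list(reactionIds(tr)), reactionIds(ctrl), idx)
  ord <- order(-abs(rep$difference), rep$pathway)
  top_pathway <- rep$pathway[ord[1]]
  planted_diff <- rep$difference[rep$pathway == sh$pathway]
  step4_ok <- identical(top_pathway, sh$pathway) &&
    length(planted_diff) == 1 && abs(planted_diff) >= 0.1
  list(step1_ok = step1_ok, step4_ok = step4_ok,
       recovered = step1_ok && step4_ok,
       flagged_products = flagged, top_pathway = top_pathway,
       planted_difference = if (length(planted_diff)) planted_diff else NA_real_)
}

#' Write a full scenario to disk
#'
#' SBML model, expression/targets/medium TSVs and a JSON truth record --
#' everything \code{\link{runPipeline}} (or the command line) needs.
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
writeScenario <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- makeToyNetwork(spec)
  dat <- makeConditionData(model, spec)
  paths <- c(model = file.path(out_dir, "model.xml"),
             expression = file.path(out_dir, "expression.tsv"),
             targets = file.path(out_dir, "drug_targets.tsv"),
             medium = file.path(out_dir, "medium.tsv"),
             truth = file.path(out_dir, "truth.json"))
  writeSBML(model, paths["model"])
  .writeTSV(dat$expression, paths["expression"])
  .writeTSV(dat$targets, paths["targets"])
  .writeTSV(data.frame(metabolite_id = dat$medium), paths["medium"])
  jsonlite::write_json(dat$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
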