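## Candidate aggregation: the four evidence streams are combined into one
## verdict per product. The rule set mirrors common screening practice:
## products flagged by at least `min_steps` steps are selected unless
## explicitly excluded (toxicity, already-characterised compounds);
## products on the include list are kept regardless of their step count
## because external evidence (literature, databases) supports them.

#' Selection configuration
#'
#' @param top_k_content how many products the content-dissimilarity step
#'   flags (default 5).
#' @param top_k_flux how many products each reference drug's flux
#'   similarity ranking flags; the step-3 flag is the union over reference
#'   drugs (default 10).
#' @param reference_drug_dissimilarity_floor minimum flux dissimilarity to
#'   the control for a drug to serve as reference (default 1e-4).
#' @param min_steps minimum number of steps for selection (default 2).
#' @param exclude_list,include_list character vectors of product ids;
#'   names, if present, carry the reason.
#' @param pathway_of_interest subsystem label used by the step-4 flag.
#' @return a list of class \code{npflux_selection_config}.
#' @export
selectionConfig <- function(top_k_content = 5, top_k_flux = 10,
                            reference_drug_dissimilarity_floor = 1e-4,
                            min_steps = 2,
                            exclude_list = character(0),
                            include_list = character(0),
                            pathway_of_interest = NULL) {
  stopifnot(top_k_content >= 1, top_k_flux >= 1, min_steps >= 1)
  structure(list(
    top_k_content = top_k_content, top_k_flux = top_k_flux,
    reference_drug_dissimilarity_floor = reference_drug_dissimilarity_floor,
    min_steps = min_steps, exclude_list = exclude_list,
    include_list = include_list, pathway_of_interest = pathway_of_interest),
    class = "npflux_selection_config")
}

#' Pick reference drugs by flux dissimilarity to the control
#'
#' @param flux_scores data.frame with columns \code{label},
#'   \code{dissimilarity} (or a named numeric vector of dissimilarities).
#' @param floor dissimilarity floor; drugs strictly above it qualify.
#' @return character vector of drug labels, highest dissimilarity first
#'   (ties broken alphabetically); may be empty.
#' @export
pickReferenceDrugs <- function(flux_scores, floor = 1e-4) {
  if (is.data.frame(flux_scores))
    flux_scores <- stats::setNames(flux_scores$dissimilarity,
                                   flux_scores$label)
  hit <- flux_scores[flux_scores > floor]
  names(hit)[order(-hit, names(hit))]
}

#' Aggregate per-step flags into a candidate table
#'
#' @param step1,step2,step3,step4 character vectors of product labels
#'   flagged by each step (any may be empty).
#' @param config a \code{\link{selectionConfig}}.
#' @param all_products optional label universe; defaults to the union of
#'   the step flags and the include/exclude lists.
#' @return data.frame with one row per product: the four logical step
#'   flags, \code{n_steps}, \code{verdict} (one of \code{selected},
#'   \code{included_by_evidence}, \code{excluded}, \code{rejected}) and
#'   \code{note}; sorted by label, so the result is independent of input
#'   order.
#' @export
aggregateCandidates <- function(step1, step2, step3, step4, config,
                                all_products = NULL) {
  excl <- as.character(config$exclude_list)
  incl <- as.character(config$include_list)
  both <- intersect(excl, incl)
  if (length(both))
    stop("configuration error: product(s) on both include and exclude lists: ",
         paste(both, collapse = ", "))
  labels <- sort(unique(c(step1, step2, step3, step4, excl, incl,
                          all_products)))
  if (!length(labels))
    return(data.frame(product = character(0), step1_deletion = logical(0),
                      step2_dissimilarity = logical(0),
                      step3_flux_similarity = logical(0),
                      step4_pathway = logical(0), n_steps = integer(0),
                      verdict = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  f1 <- labels %in% step1; f2 <- labels %in% step2
  f3 <- labels %in% step3; f4 <- labels %in% step4
  n_steps <- f1 + f2 + f3 + f4
  reason <- function(lst, lab) {
    nm <- names(lst)
    if (!is.null(nm) && lab %in% lst && nzchar(nm[match(lab, lst)]))
      nm[match(lab, lst)] else ""
  }
  verdict <- character(length(labels)); note <- character(length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab %in% excl) {
      verdict[i] <- "excluded"
      note[i] <- reason(config$exclude_list, lab)
    } else if (lab %in% incl) {
      verdict[i] <- "included_by_evidence"
      note[i] <- reason(config$include_list, lab)
    } else if (n_steps[i] >= config$min_steps) {
      verdict[i] <- "selected"
    } else {
      verdict[i] <- "rejected"
    }
  }
  data.frame(product = labels, step1_deletion = f1, step2_dissimilarity = f2,
             step3_flux_similarity = f3, step4_pathway = f4,
             n_steps = as.integer(n_steps), verdict = verdict, note = note,
             stringsAsFactors = FALSE)
}

#' Published worked example: candidate step flags
#'
#' The step-flag table for the 23 natural products flagged by at least one
#' workflow step in the published breast-cancer screen that this workflow
#' reproduces, shipped as a packaged fixture for the selection worked
#' example.
#'
#' @return data.frame with columns \code{product} and the four step-flag
#'   columns (logical).
#' @export
candidateStepFlags <- function() {
  path <- system.file("extdata", "candidate_step_flags.tsv",
                      package = "npflux", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cl in names(x)[-1]) x[[cl]] <- as.logical(x[[cl]])
  x
}

#' Run the four-step workflow end to end
#'
#' Builds context models for every condition, runs the four analysis steps
#' and aggregates the verdicts. All inputs are in-memory objects; see
#' \code{\link{npfluxMain}} for the file-based front end.
#'
#' @param model reference \code{\linkS4class{MetabolicModel}}.
#' @param expression expression table; must contain \code{control_id} and
#'   one column per product condition.
#' @param targets drug-target table with \code{drug_class} distinguishing
#'   \code{natural_product} from \code{cancer_drug} rows.
#' @param medium permitted uptake metabolites or NULL.
#' @param config a \code{\link{selectionConfig}}.
#' @param control_id name of the control condition column (default
#'   \code{"DMSO"}).
#' @param high_threshold,low_threshold activity-call thresholds.
#' @param flux_epsilon activation threshold for consistency/extraction.
#' @param fva_fraction fraction of optimum for FVA (default 1).
#' @param epsilon smoothing constant of the flux overlap score.
#' @param out_dir if non-NULL, all intermediate tables are written there
#'   as TSV plus a JSON run manifest.
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return list with \code{candidates} (the aggregated table) and
#'   \code{reports} (per-step intermediate results).
#' @export
runPipeline <- function(model, expression, targets, medium, config,
                        control_id = "DMSO", high_threshold = 1,
                        low_threshold = 0, flux_epsilon = 1e-4,
                        fva_fraction = 1.0, epsilon = 1e-4,
                        out_dir = NULL, seed = NULL) {
  t_start <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  conds <- setdiff(names(expression), "gene_id")
  if (!control_id %in% conds)
    stop("[stage build] control condition '", control_id,
         "' absent from expression table")
  products <- sort(unique(targets$drug_id[
    targets$drug_class != "cancer_drug"]))
  cancer_drugs <- sort(unique(targets$drug_id[
    targets$drug_class == "cancer_drug"]))
  product_conds <- intersect(conds, products)

  ## stage: context models
  ctx <- stage("build", {
    lapply(stats::setNames(c(control_id, product_conds),
                           c(control_id, product_conds)), function(cd)
      buildContextModel(model, expression, cd, medium,
                        high_threshold, low_threshold, flux_epsilon))
  })
  control_ctx <- ctx[[control_id]]

  ## stage 1: target deletion on the control model
  np_targets <- targets[targets$drug_class != "cancer_drug", , drop = FALSE]
  deletions <- stage("deletion", drugDeletion(control_ctx, np_targets))
  step1 <- deletions$label[deletions$grRatio == 0]

  ## stage 2: content dissimilarity of product models vs control
  content <- stage("score-content", {
    do.call(rbind, lapply(product_conds, function(p) {
      d <- jaccardDissimilarity(reactionIds(ctx[[p]]),
                                reactionIds(control_ctx))
      data.frame(label = p, jaccard = d$jaccard,
                 dissimilarity = d$dissimilarity, stringsAsFactors = FALSE)
    }))
  })
  step2 <- if (is.null(content)) character(0) else
    rankProducts(stats::setNames(content$dissimilarity, content$label),
                 config$top_k_content)

  ## stage 3: flux similarity to reference cancer drugs
  flux_report <- stage("score-flux", {
    fva_control <- fluxVariability(control_ctx, fva_fraction)
    cd_scores <- do.call(rbind, lapply(cancer_drugs, function(d) {
      ko <- deleteGenes(control_ctx,
                        targets$gene_id[targets$drug_id == d])$model
      fv <- tryCatch(fluxVariability(ko, fva_fraction), error = function(e) NULL)
      dis <- if (is.null(fv)) 1 else fluxDissimilarity(fv, fva_control,
                                                       epsilon)$dissimilarity
      data.frame(label = d, dissimilarity = dis, stringsAsFactors = FALSE)
    }))
    refs <- if (is.null(cd_scores)) character(0) else
      pickReferenceDrugs(cd_scores, config$reference_drug_dissimilarity_floor)
    prod_fva <- lapply(stats::setNames(product_conds, product_conds),
                       function(p) fluxVariability(ctx[[p]], fva_fraction))
    per_ref <- lapply(stats::setNames(refs, refs), function(d) {
      ko <- deleteGenes(control_ctx,
                        targets$gene_id[targets$drug_id == d])$model
      fv_ref <- tryCatch(fluxVariability(ko, fva_fraction),
                         error = function(e) NULL)
      if (is.null(fv_ref)) return(character(0))
      sims <- vapply(product_conds, function(p)
        fluxDissimilarity(prod_fva[[p]], fv_ref, epsilon)$si, numeric(1))
      rankProducts(stats::setNames(sims, product_conds), config$top_k_flux)
    })
    list(cancer_drug_scores = cd_scores, reference_drugs = refs,
         top_per_reference = per_ref)
  })
  step3 <- sort(unique(unlist(flux_report$top_per_reference)))

  ## stage 4: pathway alteration
  index <- buildPathwayIndex(model)
  pathway_report <- stage("pathways", {
    alterationReport(lapply(ctx[product_conds], reactionIds),
                     reactionIds(control_ctx), index)
  })
  step4 <- character(0)
  if (!is.null(config$pathway_of_interest) &&
      config$pathway_of_interest %in% names(index$pathways)) {
    poi <- config$pathway_of_interest
    poi_genes <- names(index$gene_reactions)[vapply(index$gene_reactions,
      function(r) any(r %in% index$pathways[[poi]]), logical(1))]
    diff_poi <- pathway_report[pathway_report$pathway == poi, , drop = FALSE]
    step4 <- vapply(product_conds, function(p) {
      has_target <- any(targets$gene_id[targets$drug_id == p] %in% poi_genes)
      dp <- diff_poi$difference[diff_poi$treatment == p]
      has_target && length(dp) == 1 && !is.na(dp) && dp != 0
    }, logical(1))
    step4 <- product_conds[step4]
  }

  candidates <- aggregateCandidates(step1, step2, step3, step4, config,
                                    all_products = products)

  result <- list(candidates = candidates,
                 reports = list(deletions = deletions, content = content,
                                flux = flux_report, pathways = pathway_report,
                                context_sizes = data.frame(
                                  condition = names(ctx),
                                  n_reactions = vapply(ctx, function(m)
                                    nrow(m@reactions), integer(1)),
                                  n_metabolites = vapply(ctx, function(m)
                                    nrow(m@metabolites), integer(1)),
                                  n_genes = vapply(ctx, function(m)
                                    length(m@genes), integer(1)),
                                  stringsAsFactors = FALSE, row.names = NULL)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .writeTSV(candidates, file.path(out_dir, "candidate_table.tsv"))
    .writeTSV(deletions, file.path(out_dir, "deletions.tsv"))
    if (!is.null(content))
      .writeTSV(content, file.path(out_dir, "content_scores.tsv"))
    if (!is.null(flux_report$cancer_drug_scores))
      .writeTSV(flux_report$cancer_drug_scores,
                file.path(out_dir, "flux_scores.tsv"))
    .writeTSV(pathway_report, file.path(out_dir, "pathway_report.tsv"))
    .writeTSV(result$reports$context_sizes,
              file.path(out_dir, "build_report.tsv"))
    writeRunManifest(out_dir, config = config, seed = seed,
                     started = t_start,
                     outputs = c("candidate_table.tsv", "deletions.tsv",
                                 "content_scores.tsv", "flux_scores.tsv",
                                 "pathway_report.tsv", "build_report.tsv"))
  }
  result
}
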