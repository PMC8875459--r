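## SBML Level 3 Version 1 + FBC v2 reader/writer built on xml2.
##
## Scope: species/reactions/bounds, FBC flux objectives and gene-product
## associations, subsystems via the groups package (fallback: a SUBSYSTEM
## key in reaction notes). Kinetic laws, units and MIRIAM annotations are
## out of scope. XPaths use local-name() so files from other writers parse
## regardless of their namespace prefixes.

.SBML_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
.SBML_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.SBML_GROUPS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"

.sbmlSanitize <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("x", x))
}

.attrAny <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (!is.na(v)) return(v)
  attrs <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(attrs))
  if (length(hit)) attrs[[hit[1]]] else NA_character_
}

.localFind <- function(node, ...) {
  path <- paste(vapply(list(...), function(p)
    sprintf("*[local-name()='%s']", p), character(1)), collapse = "/")
  xml2::xml_find_all(node, paste0("./", path))
}

#' Read an SBML (Level 3 + FBC) metabolic model
#'
#' Parses species, reactions with bounds (FBC flux-bound parameters or
#' kineticless defaults of +/-1000), the active FBC objective, FBC
#' gene-product associations into GPR rule trees, and subsystem labels from
#' groups (or a \code{SUBSYSTEM:} entry in reaction notes). Transcript
#' suffixes on gene labels are stripped.
#'
#' @param path SBML file path.
#' @return a \code{\linkS4class{MetabolicModel}}.
#' @export
readSBML <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  model <- .localFind(doc, "model")
  if (length(model) != 1L) stop("SBML format error: expected one <model> element")
  model <- model[[1]]
  model_id <- .attrAny(model, "id")
  if (is.na(model_id)) model_id <- "model"

  ## gene products: sbml id -> label
  gp_nodes <- xml2::xml_find_all(model, ".//*[local-name()='geneProduct']")
  gp_map <- stats::setNames(
    sub("\\.[0-9]+$", "", vapply(gp_nodes, function(n) {
      lab <- .attrAny(n, "label")
      if (is.na(lab)) .attrAny(n, "id") else lab
    }, character(1))),
    vapply(gp_nodes, function(n) .attrAny(n, "id"), character(1)))

  ## bound parameters
  par_nodes <- .localFind(model, "listOfParameters", "parameter")
  par_map <- stats::setNames(
    as.numeric(vapply(par_nodes, function(n) .attrAny(n, "value"), character(1))),
    vapply(par_nodes, function(n) .attrAny(n, "id"), character(1)))

  sp_nodes <- .localFind(model, "listOfSpecies", "species")
  if (!length(sp_nodes)) stop("SBML format error: no <species> found")
  mets <- data.frame(
    sbml_id = vapply(sp_nodes, function(n) .attrAny(n, "id"), character(1)),
    name = vapply(sp_nodes, function(n) {
      v <- .attrAny(n, "name"); if (is.na(v)) "" else v }, character(1)),
    compartment = vapply(sp_nodes, function(n) {
      v <- .attrAny(n, "compartment"); if (is.na(v)) "" else v }, character(1)),
    stringsAsFactors = FALSE)
  mets$id <- sub("^M_", "", mets$sbml_id)
  mets$name[!nzchar(mets$name)] <- mets$id[!nzchar(mets$name)]

  rx_nodes <- .localFind(model, "listOfReactions", "reaction")
  if (!length(rx_nodes)) stop("SBML format error: no <reaction> found")
  n <- length(rx_nodes)
  rid <- character(n); rname <- character(n); subsys <- character(n)
  lbv <- numeric(n); ubv <- numeric(n)
  stoich <- vector("list", n); gpr <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    sb_id <- .attrAny(node, "id")
    if (is.na(sb_id)) stop("SBML format error: reaction without id")
    rid[i] <- sub("^R_", "", sb_id)
    nm <- .attrAny(node, "name"); rname[i] <- if (is.na(nm)) rid[i] else nm
    lb_ref <- .attrAny(node, "lowerFluxBound")
    ub_ref <- .attrAny(node, "upperFluxBound")
    rev <- identical(.attrAny(node, "reversible"), "true")
    lbv[i] <- if (!is.na(lb_ref) && lb_ref %in% names(par_map))
      par_map[[lb_ref]] else if (rev) -1000 else 0
    ubv[i] <- if (!is.na(ub_ref) && ub_ref %in% names(par_map))
      par_map[[ub_ref]] else 1000

    coefs <- numeric(0)
    for (sr in .localFind(node, "listOfReactants", "speciesReference")) {
      sp <- .attrAny(sr, "species")
      st <- as.numeric(.attrAny(sr, "stoichiometry")); if (is.na(st)) st <- 1
      coefs[sub("^M_", "", sp)] <- (coefs[sub("^M_", "", sp)] %||na% 0) - st
    }
    for (sr in .localFind(node, "listOfProducts", "speciesReference")) {
      sp <- .attrAny(sr, "species")
      st <- as.numeric(.attrAny(sr, "stoichiometry")); if (is.na(st)) st <- 1
      coefs[sub("^M_", "", sp)] <- (coefs[sub("^M_", "", sp)] %||na% 0) + st
    }
    stoich[[i]] <- coefs

    gpa <- xml2::xml_find_first(node,
      ".//*[local-name()='geneProductAssociation']")
    gpr[i] <- list(if (inherits(gpa, "xml_node")) .parseAssociation(
      xml2::xml_find_first(gpa, "./*"), gp_map) else NULL)

    notes <- xml2::xml_find_first(node, ".//*[local-name()='notes']")
    if (inherits(notes, "xml_node")) {
      txt <- xml2::xml_text(notes)
      mm <- regmatches(txt, regexpr("SUBSYSTEM:\\s*[^<\n]*", txt))
      if (length(mm)) subsys[i] <- trimws(sub("SUBSYSTEM:\\s*", "", mm))
    }
  }

  ## subsystems from groups override notes
  grp_nodes <- xml2::xml_find_all(model, ".//*[local-name()='group']")
  for (g in grp_nodes) {
    label <- .attrAny(g, "name")
    if (is.na(label)) label <- .attrAny(g, "id")
    members <- xml2::xml_find_all(g, ".//*[local-name()='member']")
    for (mnode in members) {
      ref <- .attrAny(mnode, "idRef")
      j <- match(sub("^R_", "", ref), rid)
      if (!is.na(j)) subsys[j] <- label
    }
  }

  fo <- xml2::xml_find_first(model, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_node"))
    stop("no objective: SBML model has no active FBC flux objective")
  obj_id <- sub("^R_", "", .attrAny(fo, "reaction"))

  names(stoich) <- rid
  gpr <- stats::setNames(gpr, rid)
  makeMetabolicModel(model_id,
    metabolites = mets[, c("id", "name", "compartment")],
    reactions = data.frame(id = rid, name = rname, subsystem = subsys,
                           lower_bound = lbv, upper_bound = ubv,
                           stringsAsFactors = FALSE),
    stoichiometry = stoich, gpr = gpr[!vapply(gpr, is.null, logical(1))],
    genes = unname(gp_map), objectiveReaction = obj_id)
}

`%||na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

.parseAssociation <- function(node, gp_map) {
  if (is.null(node) || !inherits(node, "xml_node")) return(NULL)
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- .attrAny(node, "geneProduct")
    return(if (ref %in% names(gp_map)) gp_map[[ref]]
           else sub("^G_", "", ref))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), .parseAssociation, gp_map = gp_map)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    return(list(op = nm, args = kids))
  }
  stop("SBML format error: unexpected GPR association element <", nm, ">")
}

#' Write a model as SBML Level 3 + FBC v2
#'
#' Inverse of \code{\link{readSBML}}: bounds become FBC flux-bound
#' parameters, the objective an FBC flux objective, GPR trees nested
#' fbc:and/fbc:or associations, and subsystems one groups:group per label.
#' \code{readSBML(writeSBML(m))} reproduces \code{m} up to
#' \code{\link{modelsEqual}}.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSBML <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = .SBML_CORE, "xmlns:fbc" = .SBML_FBC, "xmlns:groups" = .SBML_GROUPS,
    level = "3", version = "1",
    "fbc:required" = "false", "groups:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = .sbmlSanitize(model@modelId),
                               "fbc:strict" = "true")

  comps <- unique(model@metabolites$compartment)
  comps[!nzchar(comps)] <- "c"
  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in unique(comps))
    xml2::xml_add_child(lc, "compartment", id = .sbmlSanitize(cp),
                        constant = "true")

  ls <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model@metabolites))) {
    m <- model@metabolites[i, ]
    cp <- if (nzchar(m$compartment)) m$compartment else "c"
    xml2::xml_add_child(ls, "species", id = paste0("M_", .sbmlSanitize(m$id)),
      name = m$name, compartment = .sbmlSanitize(cp),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }

  ## one shared parameter per distinct bound value
  bounds <- sort(unique(c(model@reactions$lower_bound,
                          model@reactions$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)),
                         sprintf("%.17g", bounds))
  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  for (k in seq_along(bounds))
    xml2::xml_add_child(lp, "parameter", id = pid[[k]],
      value = sprintf("%.17g", bounds[k]), constant = "true",
      "sboTerm" = "SBO:0000626")

  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  S <- model@stoichiometry
  for (i in seq_len(nrow(model@reactions))) {
    r <- model@reactions[i, ]
    rn <- xml2::xml_add_child(lr, "reaction",
      id = paste0("R_", .sbmlSanitize(r$id)), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = pid[[sprintf("%.17g", r$lower_bound)]],
      "fbc:upperFluxBound" = pid[[sprintf("%.17g", r$upper_bound)]])
    nz <- which(S[, i] != 0)
    reac <- nz[S[nz, i] < 0]; prod <- nz[S[nz, i] > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (j in reac)
        xml2::xml_add_child(lre, "speciesReference",
          species = paste0("M_", .sbmlSanitize(rownames(S)[j])),
          stoichiometry = sprintf("%.17g", -S[j, i]), constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (j in prod)
        xml2::xml_add_child(lpr, "speciesReference",
          species = paste0("M_", .sbmlSanitize(rownames(S)[j])),
          stoichiometry = sprintf("%.17g", S[j, i]), constant = "true")
    }
    rule <- model@gpr[[i]]
    if (!is.null(rule)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      .writeAssociation(gpa, rule)
    }
  }

  lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
    "fbc:reaction" = paste0("R_", .sbmlSanitize(model@objectiveReaction)),
    "fbc:coefficient" = "1")

  if (length(model@genes)) {
    lgp <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model@genes)
      xml2::xml_add_child(lgp, "fbc:geneProduct",
        "fbc:id" = paste0("G_", .sbmlSanitize(g)), "fbc:label" = g)
  }

  labels <- setdiff(unique(model@reactions$subsystem), "")
  if (length(labels)) {
    lg <- xml2::xml_add_child(mnode, "groups:listOfGroups")
    for (k in seq_along(labels)) {
      g <- xml2::xml_add_child(lg, "groups:group",
        "groups:id" = sprintf("sg_%d", k), "groups:name" = labels[k],
        "groups:kind" = "partonomy")
      lm <- xml2::xml_add_child(g, "groups:listOfMembers")
      for (rid2 in model@reactions$id[model@reactions$subsystem == labels[k]])
        xml2::xml_add_child(lm, "groups:member",
          "groups:idRef" = paste0("R_", .sbmlSanitize(rid2)))
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

.writeAssociation <- function(parent, rule) {
  if (is.character(rule)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
      "fbc:geneProduct" = paste0("G_", .sbmlSanitize(rule)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", rule$op))
    for (a in rule$args) .writeAssociation(node, a)
  }
}
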