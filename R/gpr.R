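## Gene-protein-reaction (GPR) boolean rules.
##
## A rule is stored as a nested list: a leaf is a length-1 character vector
## (the gene id); an internal node is list(op = "and"|"or", args = list(...)).
## NULL means "no rule": the reaction is not under gene control.

#' Parse a GPR rule string
#'
#' Accepts the conventional textual dialect: case-insensitive \code{and} /
#' \code{or}, parentheses, gene tokens matching \code{[A-Za-z0-9_.]+}.
#' Transcript suffixes (a trailing \code{.N} with numeric N) are stripped so
#' that splice variants collapse onto their gene, the usual convention when
#' expression data are keyed by gene identifiers.
#'
#' @param text rule string; \code{""} or \code{NA} yield \code{NULL} (no rule).
#' @param strip_transcripts strip trailing \code{.N} suffixes (default TRUE).
#' @return A rule tree (nested list) or \code{NULL}.
#' @examples
#' parseGpr("(g1 and g2) or g3")
#' @export
parseGpr <- function(text, strip_transcripts = TRUE) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(NULL)
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|[A-Za-z0-9_.]+", text))[[1]]
  consumed <- gsub("[()A-Za-z0-9_. ]", "", text)
  if (nzchar(consumed))
    stop("GPR rule contains unexpected characters: '", text, "'")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR rule ended unexpectedly: '", text, "'")
    if (t == "(") {
      take()
      node <- parse_or()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR: '", text, "'")
      take()
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule: '", text, "'")
    g <- take()
    if (strip_transcripts) g <- sub("\\.[0-9]+$", "", g)
    g
  }
  parse_and <- function() {
    args <- list(parse_primary())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_primary()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  rule <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in GPR rule: '", text, "'")
  rule
}

#' @rdname parseGpr
#' @param rule a rule tree as returned by \code{parseGpr}.
#' @export
gprToString <- function(rule) {
  if (is.null(rule)) return("")
  if (is.character(rule)) return(rule)
  parts <- vapply(rule$args, function(a) {
    s <- gprToString(a)
    if (is.character(a)) s else paste0("(", s, ")")
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

#' Genes referenced by a rule
#' @inheritParams gprToString
#' @return character vector of gene ids (unique, in first-appearance order).
#' @export
gprGenes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (is.character(rule)) return(rule)
  unique(unlist(lapply(rule$args, gprGenes)))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' A leaf is FALSE iff its gene is in \code{knocked}; \code{and} = protein
#' complex (all subunits needed), \code{or} = isozymes (any suffices). A
#' reaction with no rule (\code{NULL}) is not gene-controlled and evaluates
#' TRUE.
#'
#' @inheritParams gprToString
#' @param knocked character vector of knocked-out gene ids.
#' @return logical scalar: can the reaction still be catalysed?
#' @examples
#' evaluateGpr(parseGpr("(g1 and g2) or g3"), knocked = c("g1", "g3"))
#' @export
evaluateGpr <- function(rule, knocked) {
  evaluateGprStates(rule, stats::setNames(
    rep(FALSE, length(knocked)), knocked), default = TRUE)
}

#' Evaluate a GPR rule under explicit per-gene truth states
#'
#' Used by the context builder, where genes are active (TRUE), inactive
#' (FALSE) or unknown (the \code{default}).
#'
#' @inheritParams gprToString
#' @param states named logical vector of gene truth values.
#' @param default truth value for genes absent from \code{states}.
#' @return logical scalar; \code{NULL} rules evaluate TRUE.
#' @export
evaluateGprStates <- function(rule, states, default = TRUE) {
  if (is.null(rule)) return(TRUE)
  if (is.character(rule)) {
    if (rule %in% names(states)) return(unname(states[[rule]]))
    return(default)
  }
  vals <- vapply(rule$args, evaluateGprStates, logical(1),
                 states = states, default = default)
  if (rule$op == "and") all(vals) else any(vals)
}
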