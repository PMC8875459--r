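## The two model-comparison scores of the workflow.
##
## Content: D = 1 - J with J the Jaccard index of two reaction sets.
## Flux: per-reaction overlap of FVA ranges,
##   term = max(0, min(v1max, v2max) - max(v1min, v2min) + eps) /
##          (max(v1max, v2max) - min(v1min, v2min) + eps),
## averaged over the union of reaction ids; a reaction absent from one
## table contributes the range [0, 0]. Identical tables score si = 1
## (dissimilarity 0); eps (default 1e-4) keeps zero-width ranges and
## absent-vs-absent comparisons well defined.

#' Reaction-content Jaccard dissimilarity
#'
#' \code{J = |A n B| / |A u B|}, \code{D = 1 - J}.
#'
#' @param reactions_a,reactions_b character vectors of reaction ids (at
#'   least one non-empty).
#' @return list with \code{jaccard} and \code{dissimilarity}.
#' @examples
#' jaccardDissimilarity(c("r1", "r2", "r3"), c("r2", "r3", "r4"))
#' @export
jaccardDissimilarity <- function(reactions_a, reactions_b) {
  a <- unique(as.character(reactions_a))
  b <- unique(as.character(reactions_b))
  if (!length(a) && !length(b))
    stop("both reaction sets are empty")
  J <- length(intersect(a, b)) / length(union(a, b))
  list(jaccard = J, dissimilarity = 1 - J)
}

#' Overlap score of two flux ranges
#'
#' @param r1,r2 numeric length-2 vectors \code{c(vmin, vmax)}.
#' @param epsilon positive smoothing constant (default 1e-4).
#' @return score in [0, 1]: 1 for identical ranges (including two
#'   zero-width ranges), 0 for disjoint ranges.
#' @examples
#' rangeOverlap(c(0, 4), c(2, 6))          # (2 + eps) / (6 + eps)
#' rangeOverlap(c(0, 1), c(2, 3))          # 0
#' @export
rangeOverlap <- function(r1, r2, epsilon = 1e-4) {
  stopifnot(epsilon > 0, r1[1] <= r1[2], r2[1] <= r2[2])
  num <- max(0, min(r1[2], r2[2]) - max(r1[1], r2[1]) + epsilon)
  den <- max(r1[2], r2[2]) - min(r1[1], r2[1]) + epsilon
  num / den
}

#' Flux-range dissimilarity of two FVA tables
#'
#' Mean \code{\link{rangeOverlap}} over the union of reaction ids, with
#' absent reactions as \code{[0, 0]}; dissimilarity = 1 - mean.
#'
#' @param fva_a,fva_b data.frames with columns \code{id}, \code{vmin},
#'   \code{vmax} (as returned by \code{\link{fluxVariability}}).
#' @param epsilon positive smoothing constant.
#' @return list with \code{si} (mean overlap), \code{dissimilarity},
#'   \code{epsilon}, \code{n_reactions} (union size).
#' @export
fluxDissimilarity <- function(fva_a, fva_b, epsilon = 1e-4) {
  stopifnot(epsilon > 0)
  if (!nrow(fva_a) && !nrow(fva_b)) stop("both FVA tables are empty")
  ids <- union(fva_a$id, fva_b$id)
  a1 <- fva_a$vmin[match(ids, fva_a$id)]; a2 <- fva_a$vmax[match(ids, fva_a$id)]
  b1 <- fva_b$vmin[match(ids, fva_b$id)]; b2 <- fva_b$vmax[match(ids, fva_b$id)]
  a1[is.na(a1)] <- 0; a2[is.na(a2)] <- 0
  b1[is.na(b1)] <- 0; b2[is.na(b2)] <- 0
  num <- pmax(0, pmin(a2, b2) - pmax(a1, b1) + epsilon)
  den <- pmax(a2, b2) - pmin(a1, b1) + epsilon
  si <- mean(num / den)
  list(si = si, dissimilarity = 1 - si, epsilon = epsilon,
       n_reactions = length(ids))
}

#' Rank products by a score
#'
#' Stable descending sort with lexicographic tie-break on labels; returns
#' the top-k labels (all if fewer).
#'
#' @param scores named numeric vector (names = product labels) or
#'   data.frame with columns \code{label}, \code{score}.
#' @param k number of labels to return.
#' @param decreasing sort direction (default TRUE: highest score first).
#' @return character vector of at most \code{k} labels.
#' @export
rankProducts <- function(scores, k, decreasing = TRUE) {
  stopifnot(k >= 1)
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$score, scores$label)
  ord <- order(if (decreasing) -scores else scores, names(scores))
  utils::head(names(scores)[ord], k)
}
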