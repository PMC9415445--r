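#' Stable gene pairs of one phenotype
#'
#' A \code{StablePairSet} records the gene pairs whose within-sample ordering
#' (relative expression ordering, REO) is identical in at least — or, in
#' strict mode, in more than — a threshold fraction of one phenotype's
#' samples. Pairs are stored canonically (\code{gene_a} before \code{gene_b}
#' in C collation), with the majority direction and its support fraction.
#' Tied values count as neither direction but remain in the denominator, so
#' support is conservative in the presence of ties.
#'
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{direction} (\code{"a_gt_b"} or \code{"a_lt_b"}), \code{support}.
#' @slot threshold numeric in (0.5, 1]; the stability threshold.
#' @slot strict logical; \code{FALSE} means support >= threshold qualifies,
#'   \code{TRUE} means support must exceed it.
#' @slot nSamples integer; samples the set was computed over.
#' @slot phenotype character; label of the phenotype.
#'
#' @seealso \code{\link{stablePairs}}
#' @export
setClass("StablePairSet",
  representation(pairs = "data.frame", threshold = "numeric",
                 strict = "logical", nSamples = "integer",
                 phenotype = "character"))

setValidity("StablePairSet", function(object) {
  p <- object@pairs
  need <- c("gene_a", "gene_b", "direction", "support")
  if (!all(need %in% names(p)))
    return(sprintf("pairs must have columns: %s", paste(need, collapse = ", ")))
  if (length(object@threshold) != 1L || object@threshold <= 0.5 ||
      object@threshold > 1)
    return("threshold must be a single value in (0.5, 1]")
  if (nrow(p)) {
    if (any(p$gene_a == p$gene_b)) return("a pair must use two distinct genes")
    if (any(.str_gt(p$gene_a, p$gene_b)))
      return("pairs must be canonical (gene_a before gene_b)")
    if (anyDuplicated(pairKeys(p))) return("duplicate canonical pair")
    if (!all(p$direction %in% .DIRECTIONS)) return("invalid direction code")
    ok <- if (object@strict) p$support > object@threshold
          else p$support >= object@threshold
    if (!all(ok)) return("a pair's support falls below the threshold")
  }
  TRUE
})

#' Reversal gene pairs between two phenotypes
#'
#' Pairs that are stable in both of two phenotypes but with opposite REO
#' directions — the building block of a qualitative signature.
#'
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{direction_group1}, \code{direction_group2} (always opposite),
#'   \code{support_group1}, \code{support_group2}.
#' @slot groupLabels character(2); the phenotype labels of groups 1 and 2.
#'
#' @seealso \code{\link{reversalPairs}}, \code{\link{intersectReversalSets}}
#' @export
setClass("ReversalPairSet",
  representation(pairs = "data.frame", groupLabels = "character"))

setValidity("ReversalPairSet", function(object) {
  p <- object@pairs
  need <- c("gene_a", "gene_b", "direction_group1", "direction_group2")
  if (!all(need %in% names(p)))
    return(sprintf("pairs must have columns: %s", paste(need, collapse = ", ")))
  if (length(object@groupLabels) != 2L)
    return("groupLabels must have length 2")
  if (nrow(p)) {
    if (any(.str_gt(p$gene_a, p$gene_b)))
      return("pairs must be canonical (gene_a before gene_b)")
    if (anyDuplicated(pairKeys(p))) return("duplicate canonical pair")
    if (!all(p$direction_group1 %in% .DIRECTIONS) ||
        !all(p$direction_group2 %in% .DIRECTIONS))
      return("invalid direction code")
    if (any(p$direction_group1 == p$direction_group2))
      return("the two group directions must be opposite for every pair")
  }
  TRUE
})

#' Reversal-pair signature
#'
#' The final cross-platform signature: canonical gene pairs with the ordering
#' that characterizes the reference (e.g. normal) phenotype and the opposite
#' ordering characterizing the case (e.g. cancer) phenotype, together with
#' the configuration and stage counts of the build that produced it.
#'
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{normal_direction}, \code{cancer_direction} and optionally
#'   per-platform support columns.
#' @slot buildConfig list of thresholds and options used by the build.
#' @slot buildReport list of per-stage pair counts (discovery, intersection,
#'   filter).
#'
#' @seealso \code{\link{buildSignature}}, \code{\link{scoreCohort}}
#' @export
setClass("PairSignature",
  representation(pairs = "data.frame", buildConfig = "list",
                 buildReport = "list"))

setValidity("PairSignature", function(object) {
  p <- object@pairs
  need <- c("gene_a", "gene_b", "normal_direction", "cancer_direction")
  if (!all(need %in% names(p)))
    return(sprintf("pairs must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (any(.str_gt(p$gene_a, p$gene_b)))
      return("pairs must be canonical (gene_a before gene_b)")
    if (anyDuplicated(pairKeys(p))) return("duplicate canonical pair")
    if (!all(p$normal_direction %in% .DIRECTIONS) ||
        !all(p$cancer_direction %in% .DIRECTIONS))
      return("invalid direction code")
    if (any(p$normal_direction == p$cancer_direction))
      return("normal and cancer directions must be opposite for every pair")
  }
  TRUE
})
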