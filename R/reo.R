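#' Direction support of one gene pair
#'
#' Fractions of samples in which gene A's measurement is greater than, less
#' than, or exactly equal to gene B's. The three fractions sum to 1; ties are
#' counted separately and never attributed to a direction.
#'
#' @param x expression matrix (genes x samples; matrix, data.frame or
#'   SummarizedExperiment), positive processed intensities.
#' @param geneA,geneB feature ids present in \code{x}.
#' @return named numeric(3): \code{a_gt_b}, \code{a_lt_b}, \code{tied}.
#' @examples
#' m <- matrix(c(5, 1, 5, 1, 5, 9), 2, 3,
#'             dimnames = list(c("A", "B"), paste0("s", 1:3)))
#' pairSupport(m, "A", "B")
#' @export
pairSupport <- function(x, geneA, geneB) {
  x <- .asExprMatrix(x)
  for (g in c(geneA, geneB))
    if (!g %in% rownames(x)) stop(sprintf("unknown gene: %s", g))
  a <- x[geneA, ]
  b <- x[geneB, ]
  c(a_gt_b = mean(a > b), a_lt_b = mean(a < b), tied = mean(a == b))
}

#' Identify stable gene pairs within one phenotype
#'
#' Scans all gene pairs of a cohort and keeps those whose within-sample
#' ordering is identical in at least (inclusive mode, the default) or in more
#' than (strict mode) \code{threshold} of the samples. The scan runs in
#' compiled code over row blocks, so at most one block of the G x G pair
#' space is held at a time; its output is bit-identical to the naive
#' per-pair counting loop.
#'
#' The threshold must exceed 0.5 — below that the two directions are not
#' mutually exclusive and "the stable direction" is ill-defined. Exactly
#' equal values count as neither direction but remain in the denominator, so
#' tie-heavy pairs (e.g. genes constant across samples) simply fail to reach
#' the threshold.
#'
#' @param x expression matrix (genes x samples), at least 2 genes.
#' @param threshold stability threshold in (0.5, 1]; default 0.9.
#' @param inclusive logical; \code{TRUE} (default) keeps support >=
#'   threshold, \code{FALSE} requires support > threshold.
#' @param phenotype label stored in the result.
#' @param blockSize rows per block of the compiled scan.
#' @return a \code{\link{StablePairSet}}.
#' @seealso \code{\link{reversalPairs}}
#' @export
stablePairs <- function(x, threshold = 0.9, inclusive = TRUE,
                        phenotype = "unspecified", blockSize = 512L) {
  x <- .asExprMatrix(x)
  if (nrow(x) < 2L) stop("need at least 2 genes")
  if (ncol(x) < 1L) stop("need at least 1 sample")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0.5 || threshold > 1)
    stop("threshold must be a single value in (0.5, 1]: below 0.5 the two directions are not mutually exclusive")
  hits <- .count_stable_pairs(x, threshold, inclusive, as.integer(blockSize))
  rn <- rownames(x)
  pairs <- data.frame(
    gene_a = rn[hits$i], gene_b = rn[hits$j],
    direction = as.character(ifelse(hits$n_gt > hits$n_lt,
                                    "a_gt_b", "a_lt_b")),
    support = pmax(hits$n_gt, hits$n_lt) / ncol(x),
    stringsAsFactors = FALSE)
  pairs <- .canonicalizePairs(pairs, "direction")
  rownames(pairs) <- NULL
  new("StablePairSet", pairs = pairs, threshold = threshold,
      strict = !inclusive, nSamples = ncol(x), phenotype = phenotype)
}

#' Reversal gene pairs between two phenotypes
#'
#' Intersects two \code{StablePairSet}s (one per phenotype) and keeps exactly
#' the canonical pairs that are stable in both but with opposite directions.
#' Swapping the two arguments yields the same pairs with the group columns
#' exchanged.
#'
#' @param set1,set2 \code{StablePairSet}s built on two phenotypes.
#' @return a \code{\link{ReversalPairSet}} with \code{groupLabels}
#'   \code{c(phenotypeLabel(set1), phenotypeLabel(set2))}. May be empty.
#' @export
reversalPairs <- function(set1, set2) {
  stopifnot(is(set1, "StablePairSet"), is(set2, "StablePairSet"))
  p1 <- set1@pairs
  p2 <- set2@pairs
  k1 <- pairKeys(p1)
  k2 <- pairKeys(p2)
  idx <- match(k1, k2)
  keep <- !is.na(idx) & p1$direction != p2$direction[idx]
  pairs <- data.frame(
    gene_a = p1$gene_a[keep], gene_b = p1$gene_b[keep],
    direction_group1 = p1$direction[keep],
    direction_group2 = p2$direction[idx[keep]],
    support_group1 = p1$support[keep],
    support_group2 = p2$support[idx[keep]],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("ReversalPairSet", pairs = pairs,
      groupLabels = c(phenotypeLabel(set1), phenotypeLabel(set2)))
}
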