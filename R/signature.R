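#' Intersect reversal-pair sets across platforms
#'
#' Keeps exactly the canonical pairs present in every input set with the
#' same orientation in both groups — a pair reversed one way on one platform
#' and the opposite way on another is contradictory evidence and is dropped.
#' The result is invariant to the order of the input sets; the recorded
#' supports are the per-group minima across platforms (the weakest evidence).
#'
#' @param sets list of >= 2 \code{\link{ReversalPairSet}}s whose
#'   \code{groupLabels} agree.
#' @return a \code{ReversalPairSet}.
#' @export
intersectReversalSets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  for (s in sets) stopifnot(is(s, "ReversalPairSet"))
  labs <- groupLabels(sets[[1L]])
  for (s in sets[-1L])
    if (!identical(groupLabels(s), labs))
      stop(sprintf("mismatched group labels: (%s) vs (%s)",
                   paste(labs, collapse = ","),
                   paste(groupLabels(s), collapse = ",")))
  acc <- pairTable(sets[[1L]])
  for (s in sets[-1L]) {
    p <- pairTable(s)
    idx <- match(pairKeys(acc), pairKeys(p))
    keep <- !is.na(idx) &
      acc$direction_group1 == p$direction_group1[idx] &
      acc$direction_group2 == p$direction_group2[idx]
    acc <- acc[keep, , drop = FALSE]
    idx <- idx[keep]
    acc$support_group1 <- pmin(acc$support_group1, p$support_group1[idx])
    acc$support_group2 <- pmin(acc$support_group2, p$support_group2[idx])
  }
  rownames(acc) <- NULL
  new("ReversalPairSet", pairs = acc, groupLabels = labs)
}

#' Filter candidate reversal pairs on an independent reference cohort
#'
#' Retains the candidates whose reference-phenotype direction also holds in
#' more than (strict mode, the default) or at least \code{threshold} of the
#' samples of an independent cohort of the reference phenotype, and promotes
#' the survivors to a \code{\link{PairSignature}}. Candidates with a gene
#' unmeasured in the filter cohort are dropped first (their count is
#' reported via a message and in the build report). Ties count against the
#' direction, never for it.
#'
#' @param candidates a \code{ReversalPairSet}; group 1 is taken as the
#'   reference (normal-like) phenotype unless \code{referenceGroup = 2}.
#' @param normalMatrix expression matrix of the independent reference cohort.
#' @param threshold consistency threshold in (0.5, 1]; default 0.9.
#' @param strict logical; \code{TRUE} (default) requires support strictly
#'   above \code{threshold}.
#' @param referenceGroup 1 or 2; which group of \code{candidates} is the
#'   reference phenotype.
#' @return a \code{PairSignature} whose \code{normal_direction} is the
#'   reference direction and \code{cancer_direction} its opposite; column
#'   \code{filter_support} records the filter-cohort support.
#' @export
consistencyFilter <- function(candidates, normalMatrix, threshold = 0.9,
                              strict = TRUE, referenceGroup = 1L) {
  stopifnot(is(candidates, "ReversalPairSet"),
            referenceGroup %in% c(1L, 2L))
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  x <- .asExprMatrix(normalMatrix, "normalMatrix")
  p <- pairTable(candidates)
  ref_dir <- if (referenceGroup == 1L) p$direction_group1 else
    p$direction_group2
  present <- p$gene_a %in% rownames(x) & p$gene_b %in% rownames(x)
  n_dropped <- sum(!present)
  if (n_dropped)
    message(sprintf(
      "consistencyFilter: %d candidate pair(s) dropped (gene unmeasured in filter cohort)",
      n_dropped))
  p <- p[present, , drop = FALSE]
  ref_dir <- ref_dir[present]
  if (nrow(p)) {
    A <- x[p$gene_a, , drop = FALSE]
    B <- x[p$gene_b, , drop = FALSE]
    frac_gt <- rowMeans(A > B)
    frac_lt <- rowMeans(A < B)
    supp <- ifelse(ref_dir == "a_gt_b", frac_gt, frac_lt)
  } else supp <- numeric()
  keep <- if (strict) supp > threshold else supp >= threshold
  if (!any(keep))
    stop(sprintf(
      "consistency filter removed every candidate (n=%d candidates, %d with both genes measured, max support %.3f at threshold %s%.3g)",
      nPairs(candidates), nrow(p),
      if (length(supp)) max(supp) else NA_real_,
      if (strict) ">" else ">=", threshold))
  pairs <- data.frame(
    gene_a = p$gene_a[keep], gene_b = p$gene_b[keep],
    normal_direction = ref_dir[keep],
    cancer_direction = .oppositeDirection(ref_dir[keep]),
    filter_support = supp[keep], stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("PairSignature", pairs = pairs,
      buildConfig = list(consistency_threshold = threshold,
                         consistency_strict = strict,
                         filter_n_samples = ncol(x)),
      buildReport = list(n_candidates = nPairs(candidates),
                         n_dropped_unmeasured = n_dropped,
                         n_signature = sum(keep)))
}

#' Build a cross-platform reversal-pair signature
#'
#' Orchestrates the full discovery: per discovery platform, stable pairs are
#' found in each phenotype at the stability threshold (inclusive: "at least")
#' and reduced to reversal pairs; the per-platform reversal sets are
#' intersected requiring consistent orientation; the consistent candidates
#' are then filtered on an independent reference-phenotype cohort at the
#' consistency threshold (strict: "more than"). Stage counts for every step
#' are recorded in the build report.
#'
#' @param discovery list of >= 1 discovery platforms, each a list holding
#'   one expression matrix per phenotype under the names given by
#'   \code{referenceLabel} and \code{caseLabel}.
#' @param filterMatrix expression matrix of the independent reference-
#'   phenotype cohort used by the consistency filter.
#' @param stabilityThreshold,stabilityInclusive stable-pair discovery
#'   threshold and mode (defaults 0.9, inclusive).
#' @param consistencyThreshold,consistencyStrict filter threshold and mode
#'   (defaults 0.9, strict).
#' @param referenceLabel,caseLabel phenotype names (defaults "normal",
#'   "cancer").
#' @param blockSize block size for the all-pairs scan.
#' @return a \code{\link{PairSignature}}; \code{buildReport} holds
#'   per-platform stable/reversal counts, the intersection count, and the
#'   final signature size.
#' @examples
#' cc <- simulateCaseControl(simConfig(nGenes = 60, nPlantedPairs = 10,
#'   nSamplesPerGroup = 15, noiseSd = 0, platforms = c(1, 1, 1), seed = 11))
#' sig <- buildSignature(cc$platforms[1:2], cc$platforms[[3]]$normal)
#' nPairs(sig)
#' @export
buildSignature <- function(discovery, filterMatrix,
                           stabilityThreshold = 0.9,
                           stabilityInclusive = TRUE,
                           consistencyThreshold = 0.9,
                           consistencyStrict = TRUE,
                           referenceLabel = "normal", caseLabel = "cancer",
                           blockSize = 512L) {
  stopifnot(is.list(discovery), length(discovery) >= 1L)
  platform_report <- list()
  revsets <- vector("list", length(discovery))
  for (k in seq_along(discovery)) {
    plat <- discovery[[k]]
    if (!all(c(referenceLabel, caseLabel) %in% names(plat)))
      stop(sprintf("discovery platform %d lacks matrices named '%s' and '%s'",
                   k, referenceLabel, caseLabel))
    sp_ref <- stablePairs(plat[[referenceLabel]], stabilityThreshold,
                          stabilityInclusive, phenotype = referenceLabel,
                          blockSize = blockSize)
    sp_case <- stablePairs(plat[[caseLabel]], stabilityThreshold,
                           stabilityInclusive, phenotype = caseLabel,
                           blockSize = blockSize)
    revsets[[k]] <- reversalPairs(sp_ref, sp_case)
    platform_report[[k]] <- list(
      platform = k,
      n_stable_reference = nPairs(sp_ref),
      n_stable_case = nPairs(sp_case),
      n_reversal = nPairs(revsets[[k]]))
  }
  candidates <- if (length(revsets) > 1L) intersectReversalSets(revsets)
                else revsets[[1L]]
  sig <- consistencyFilter(candidates, filterMatrix,
                           threshold = consistencyThreshold,
                           strict = consistencyStrict, referenceGroup = 1L)
  sig@buildConfig <- list(
    stability_threshold = stabilityThreshold,
    stability_inclusive = stabilityInclusive,
    consistency_threshold = consistencyThreshold,
    consistency_strict = consistencyStrict,
    reference_label = referenceLabel, case_label = caseLabel,
    n_discovery_platforms = length(discovery))
  sig@buildReport <- c(
    list(platforms = platform_report,
         n_consistent = nPairs(candidates)),
    sig@buildReport[c("n_dropped_unmeasured", "n_signature")])
  validObject(sig)
  sig
}
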