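#' Incidence-risk score of a single sample
#'
#' Of the signature's pairs, let m be the number evaluable in this sample
#' (both genes measured and not exactly tied) and n the number showing the
#' cancer-characteristic ordering; the incidence-risk score is n/m. Pairs
#' with a missing gene or a tie are excluded from both numerator and
#' denominator, and the evaluable fraction of the full signature is reported
#' as coverage so scores remain comparable across platforms that measure
#' different gene subsets. Because the score depends only on within-sample
#' orderings, it is invariant under any strictly increasing transform of the
#' sample's expression vector.
#'
#' @param sample named numeric vector of one sample's expression values, or
#'   a one-column matrix.
#' @param sig a \code{\link{PairSignature}}.
#' @param coverageFloor minimum acceptable coverage in (0, 1]; default 0.5.
#'   Scoring fails below the floor rather than returning a score built on
#'   too little of the signature.
#' @return one-row data.frame: \code{sample_id}, \code{m}, \code{n},
#'   \code{score}, \code{coverage}.
#' @export
riskScore <- function(sample, sig, coverageFloor = 0.5) {
  if (is.matrix(sample)) {
    stopifnot(ncol(sample) == 1L)
    v <- sample[, 1L]
    names(v) <- rownames(sample)
    id <- colnames(sample)[1L]
    sample <- v
  } else id <- "sample"
  stopifnot(is.numeric(sample), !is.null(names(sample)))
  x <- matrix(sample, ncol = 1L, dimnames = list(names(sample), id))
  res <- scoreCohort(x, sig, coverageFloor = coverageFloor)
  res
}

#' Incidence-risk scores for every sample of a cohort
#'
#' Applies the n/m incidence-risk score to each column of an expression
#' matrix. Scoring is strictly per-sample: a sample's score never depends on
#' which other samples are present. Sample order is preserved.
#'
#' @param x expression matrix (genes x samples).
#' @param sig a \code{\link{PairSignature}}.
#' @param coverageFloor minimum acceptable per-sample coverage; any sample
#'   below the floor (or with no evaluable pair) is an error naming the
#'   number of signature genes missing from the matrix.
#' @return data.frame with one row per sample, in input order:
#'   \code{sample_id}, \code{m}, \code{n}, \code{score}, \code{coverage}.
#' @examples
#' cc <- simulateCaseControl(simConfig(nGenes = 40, nPlantedPairs = 8,
#'   nSamplesPerGroup = 10, noiseSd = 0, platforms = c(1, 1, 1), seed = 2))
#' sig <- buildSignature(cc$platforms[1:2], cc$platforms[[3]]$normal)
#' head(scoreCohort(cc$platforms[[3]]$cancer, sig))
#' @export
scoreCohort <- function(x, sig, coverageFloor = 0.5) {
  x <- .asExprMatrix(x)
  stopifnot(is(sig, "PairSignature"))
  if (!is.numeric(coverageFloor) || coverageFloor <= 0 || coverageFloor > 1)
    stop("coverageFloor must be in (0, 1]")
  p <- pairTable(sig)
  M <- nrow(p)
  if (!M) stop("empty signature")
  present <- p$gene_a %in% rownames(x) & p$gene_b %in% rownames(x)
  n_missing_genes <- length(setdiff(
    unique(c(p$gene_a, p$gene_b)), rownames(x)))
  pp <- p[present, , drop = FALSE]
  S <- ncol(x)
  if (nrow(pp)) {
    A <- x[pp$gene_a, , drop = FALSE]
    B <- x[pp$gene_b, , drop = FALSE]
    tie <- A == B
    cancer_gt <- pp$cancer_direction == "a_gt_b"
    shows_cancer <- (A > B) == cancer_gt & !tie
    m <- colSums(!tie)
    n <- colSums(shows_cancer)
  } else {
    m <- n <- rep(0L, S)
  }
  coverage <- m / M
  bad <- m == 0L | coverage < coverageFloor
  if (any(bad))
    stop(sprintf(
      "coverage below floor %.2f for sample(s) %s (%d of %d signature genes missing from the matrix)",
      coverageFloor, paste(colnames(x)[bad], collapse = ", "),
      n_missing_genes, length(unique(c(p$gene_a, p$gene_b)))))
  data.frame(sample_id = colnames(x), m = as.integer(m), n = as.integer(n),
             score = n / m, coverage = coverage, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Majority-vote classification of risk scores
#'
#' A sample is called cancer-like when more than half (or, generally, more
#' than \code{cutoff}) of its evaluable signature pairs show the
#' cancer-characteristic ordering. A score exactly at the cutoff is called
#' normal-like (the conservative tie-break).
#'
#' @param score numeric vector of scores in [0, 1].
#' @param cutoff classification cutoff; default 0.5 (majority vote).
#' @return character vector, \code{"cancer_like"} or \code{"normal_like"}.
#' @export
classifyScores <- function(score, cutoff = 0.5) {
  stopifnot(is.numeric(score), all(score >= 0 & score <= 1, na.rm = TRUE))
  ifelse(score > cutoff, "cancer_like", "normal_like")
}

#' ROC AUC with bootstrap confidence interval
#'
#' Area under the ROC curve by the rank (Mann-Whitney) construction: the
#' probability that a random positive sample scores above a random negative
#' one, with ties counted 1/2. The confidence interval is a seeded
#' percentile bootstrap, resampling within each class.
#'
#' @param scores numeric vector.
#' @param labels vector with exactly two classes present.
#' @param positive the label of the positive (high-score) class; defaults to
#'   \code{TRUE} for logical labels and must be given otherwise.
#' @param nBoot bootstrap resamples (default 2000); 0 skips the interval.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list: \code{auc}, \code{ci_low}, \code{ci_high}, \code{n_pos},
#'   \code{n_neg}, \code{n_boot}, \code{conf}.
#' @export
rocAuc <- function(scores, labels, positive = NULL, nBoot = 2000L,
                   seed = 1L, conf = 0.95) {
  stopifnot(length(scores) == length(labels))
  if (is.null(positive)) {
    if (is.logical(labels)) positive <- TRUE
    else stop("'positive' must name the positive class for non-logical labels")
  }
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present to compute an AUC")
  auc_of <- function(sp, sn) {
    r <- rank(c(sp, sn))
    np <- length(sp)
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(sn))
  }
  sp <- scores[pos]
  sn <- scores[!pos]
  auc <- auc_of(sp, sn)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0L) {
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(nBoot), function(i)
      auc_of(sp[sample.int(length(sp), replace = TRUE)],
             sn[sample.int(length(sn), replace = TRUE)]), numeric(1L))
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  list(auc = auc, ci_low = ci[1L], ci_high = ci[2L],
       n_pos = length(sp), n_neg = length(sn),
       n_boot = as.integer(nBoot), conf = conf)
}

#' Compare risk scores between two groups
#'
#' Two-sided Wilcoxon rank-sum test between two score vectors: the exact
#' null distribution when the combined sample size is at most
#' \code{exactLimit} and the data are tie-free, otherwise the normal
#' approximation with tie correction and continuity correction. Group
#' medians are reported alongside.
#'
#' @param scoresA,scoresB numeric vectors (nonempty).
#' @param labels character(2) group labels for reporting.
#' @param exactLimit combined-size switch point between the exact and
#'   approximate null (default 20).
#' @return list: \code{labels}, \code{n}, \code{medians}, \code{statistic}
#'   (Mann-Whitney W of group A), \code{p_value}, \code{method}.
#' @examples
#' compareScoreGroups(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
compareScoreGroups <- function(scoresA, scoresB,
                               labels = c("group_a", "group_b"),
                               exactLimit = 20L) {
  stopifnot(length(scoresA) >= 1L, length(scoresB) >= 1L)
  n_tot <- length(scoresA) + length(scoresB)
  has_ties <- anyDuplicated(c(scoresA, scoresB)) > 0L
  exact <- n_tot <= exactLimit && !has_ties
  wt <- suppressWarnings(
    wilcox.test(scoresA, scoresB, alternative = "two.sided",
                exact = exact, correct = TRUE))
  list(labels = labels,
       n = c(length(scoresA), length(scoresB)),
       medians = c(median(scoresA), median(scoresB)),
       statistic = unname(wt$statistic),
       p_value = wt$p.value,
       method = if (exact) "wilcoxon_exact"
                else "wilcoxon_normal_approx_tie_corrected")
}
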