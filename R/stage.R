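#' Per-sample REO indicator matrix of a signature
#'
#' Binary pairs x samples grid: entry 1 when the pair shows the
#' cancer-characteristic ordering in that sample, 0 when it shows the normal
#' ordering, NA when the two genes are exactly tied. Pairs with a gene
#' missing from the matrix appear as all-NA rows (their count is reported
#' via a message). Column sums divided by the evaluable pair count reproduce
#' the incidence-risk scores, and the whole grid is invariant under strictly
#' monotone per-sample transforms.
#'
#' @param x expression matrix (genes x samples).
#' @param sig a \code{\link{PairSignature}}.
#' @return integer matrix, one row per signature pair (rownames are
#'   canonical pair keys), one column per sample.
#' @export
reoIndicatorMatrix <- function(x, sig) {
  x <- .asExprMatrix(x)
  stopifnot(is(sig, "PairSignature"))
  p <- pairTable(sig)
  if (!nrow(p)) stop("empty signature")
  out <- matrix(NA_integer_, nrow(p), ncol(x),
                dimnames = list(pairKeys(p), colnames(x)))
  present <- p$gene_a %in% rownames(x) & p$gene_b %in% rownames(x)
  if (any(!present))
    message(sprintf(
      "reoIndicatorMatrix: %d pair(s) unmeasured (gene missing from matrix)",
      sum(!present)))
  if (any(present)) {
    pp <- p[present, , drop = FALSE]
    A <- x[pp$gene_a, , drop = FALSE]
    B <- x[pp$gene_b, , drop = FALSE]
    cancer_gt <- pp$cancer_direction == "a_gt_b"
    ind <- (A > B) == cancer_gt
    mode(ind) <- "integer"
    ind[A == B] <- NA_integer_
    out[present, ] <- ind
  }
  out
}

# distinct arrangements of a binary vector = positions of its ones; used for
# the exact permutation null of the rank correlation
.exact_perm_spearman_p <- function(ind, stage_rank, maxArrangements = 1e5) {
  ones <- sum(ind == 1)
  n <- length(ind)
  n_arr <- choose(n, ones)
  if (n_arr > maxArrangements) return(NA_real_)
  rho_obs <- abs(cor(ind, stage_rank, method = "spearman"))
  pos <- utils::combn(n, ones)
  hits <- 0L
  for (j in seq_len(ncol(pos))) {
    v <- integer(n)
    v[pos[, j]] <- 1L
    if (abs(cor(v, stage_rank, method = "spearman")) >= rho_obs - 1e-12)
      hits <- hits + 1L
  }
  hits / ncol(pos)
}

#' Stage-correlated signature pairs
#'
#' Correlates each pair's per-sample cancer-ordering indicator with an
#' ordinal stage label by Spearman's rank correlation (the standard
#' tie-corrected rank formula). Two-sided p-values come from the exact
#' permutation null when fewer than \code{exactN} samples are evaluable
#' (feasible because the binary indicator has only \code{choose(n, ones)}
#' distinct arrangements), otherwise from the t approximation
#' \code{t = rho * sqrt((n-2) / (1-rho^2))}. Benjamini-Hochberg q-values
#' control the FDR across the tested pairs. Pairs whose indicator (or whose
#' stage vector after NA removal) is constant have no defined correlation
#' and are excluded with a reported count.
#'
#' @param indicator pairs x samples 0/1/NA matrix from
#'   \code{\link{reoIndicatorMatrix}}.
#' @param stages per-sample ordinal stage: an ordered factor, or a factor /
#'   character coerced with levels in the given order, or numeric codes
#'   (e.g. moderate=1 < severe=2).
#' @param fdr FDR level for the \code{significant} flag (default 0.05).
#' @param exactN below this evaluable-sample count the exact permutation
#'   null is used (default 12).
#' @return data.frame: \code{pair}, \code{gene_a}, \code{gene_b},
#'   \code{rho}, \code{p_value}, \code{q_value}, \code{n_used},
#'   \code{method}, \code{significant}; attribute \code{n_excluded} counts
#'   constant/unevaluable pairs.
#' @export
stageCorrelatedPairs <- function(indicator, stages, fdr = 0.05,
                                 exactN = 12L) {
  stopifnot(is.matrix(indicator))
  if (is.numeric(stages)) stage_num <- stages
  else if (is.factor(stages)) stage_num <- as.integer(stages)
  else stage_num <- as.integer(factor(stages, levels = unique(stages)))
  if (length(stage_num) != ncol(indicator))
    stop("one stage label per indicator column required")
  if (length(unique(stage_num)) < 2L)
    stop("at least two distinct stage levels are required")
  stage_rank_all <- rank(stage_num)

  rows <- vector("list", nrow(indicator))
  n_excluded <- 0L
  for (i in seq_len(nrow(indicator))) {
    ind <- indicator[i, ]
    ok <- !is.na(ind)
    ind <- ind[ok]
    st <- stage_num[ok]
    n <- length(ind)
    if (n < 3L || length(unique(ind)) < 2L || length(unique(st)) < 2L) {
      n_excluded <- n_excluded + 1L
      next
    }
    st_rank <- rank(st)
    rho <- cor(ind, st_rank, method = "spearman")
    if (n < exactN && all(ind %in% c(0L, 1L))) {
      p <- .exact_perm_spearman_p(ind, st_rank)
      method <- "exact_permutation"
      if (is.na(p)) { method <- "t_approximation"; p <- NULL }
    } else p <- NULL
    if (is.null(p)) {
      method <- "t_approximation"
      tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
      p <- 2 * pt(-abs(tt), n - 2)
      p <- max(p, .Machine$double.xmin)
    }
    rows[[i]] <- data.frame(pair = rownames(indicator)[i], rho = rho,
                            p_value = p, n_used = n, method = method,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(pair = character(), rho = numeric(),
                      p_value = numeric(), n_used = integer(),
                      method = character(), stringsAsFactors = FALSE)
  if (n_excluded)
    message(sprintf(
      "stageCorrelatedPairs: %d pair(s) excluded (constant indicator or too few evaluable samples)",
      n_excluded))
  genes <- strsplit(res$pair, "|", fixed = TRUE)
  res$gene_a <- vapply(genes, `[`, "", 1L)
  res$gene_b <- vapply(genes, `[`, "", 2L)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr
  res <- res[order(res$p_value, res$pair),
             c("pair", "gene_a", "gene_b", "rho", "p_value", "q_value",
               "n_used", "method", "significant")]
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for the number X of marked elements among n draws without
#' replacement from a universe of N elements of which m are marked —
#' equivalently 1 minus the cumulative sum of the hypergeometric mass up to
#' k-1. The sum is evaluated in log space (log-binomial terms combined by
#' log-sum-exp) for numerical safety at large N.
#'
#' @param N universe size (e.g. genes detected on the platform, or signature
#'   pairs).
#' @param m marked elements (e.g. genes annotated to the pathway).
#' @param n drawn elements (e.g. interested genes).
#' @param k observed marked draws; must satisfy \code{k <= min(m, n)}.
#' @return the tail probability, in (0, 1].
#' @examples
#' hypergeometricTail(2046, 33, 301, 8)
#' @export
hypergeometricTail <- function(N, m, n, k) {
  for (v in list(N = N, m = m, n = n, k = k)) {
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v < 0 ||
        v != round(v))
      stop("N, m, n, k must be single non-negative integers")
  }
  if (m > N || n > N)
    stop("m and n cannot exceed the universe size N")
  if (k > min(m, n))
    stop(sprintf("impossible arguments: k=%d exceeds min(m, n)=%d",
                 k, min(m, n)))
  if (k == 0) return(1)  # empty sum: P(X >= 0) = 1
  i <- seq.int(max(k, n - (N - m)), min(m, n))
  logterms <- lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
  mx <- max(logterms)
  min(exp(mx + log(sum(exp(logterms - mx)))), 1)
}

#' Significance of the overlap between two lists
#'
#' Hypergeometric upper-tail test for the size of the intersection of two
#' lists drawn from a common universe of stated size.
#'
#' @param listA,listB character vectors (deduplicated internally), subsets
#'   of the universe.
#' @param universeSize size of the common universe.
#' @return list: \code{n_a}, \code{n_b}, \code{overlap},
#'   \code{universe_size}, \code{p_value}.
#' @examples
#' # two stage-related pair lists of 33 and 301 sharing 8 pairs among 2046
#' overlapSignificance(paste0("p", 1:33), paste0("p", c(1:8, 100:392)), 2046)
#' @export
overlapSignificance <- function(listA, listB, universeSize) {
  a <- unique(listA)
  b <- unique(listB)
  if (length(a) > universeSize || length(b) > universeSize)
    stop("a list cannot exceed the universe size")
  k <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), overlap = k,
       universe_size = universeSize,
       p_value = hypergeometricTail(universeSize, length(a), length(b), k))
}

#' Hypergeometric pathway enrichment
#'
#' One hypergeometric upper-tail test per gene set: with N genes detected on
#' the platform, m of them annotated to the set, and n interested genes of
#' which k fall in the set, the enrichment p-value is P(X >= k). Sets with
#' no interested gene (k = 0) are omitted. Benjamini-Hochberg q-values are
#' computed across the reported sets; with \code{uncorrected = TRUE} the
#' \code{significant} flag uses the raw p-value instead (a deliberately
#' loose mode for small interest lists).
#'
#' @param genes character vector of interested genes (deduplicated; must be
#'   nonempty).
#' @param geneSets named list of character vectors (e.g. from
#'   \code{\link{readGeneSets}}).
#' @param universeSize number N of genes detected by the platform; never
#'   inferred from the gene sets. Must be >= the number of interested genes.
#' @param fdr significance level for the flag (default 0.05).
#' @param uncorrected logical; flag on raw p instead of BH q.
#' @return data.frame sorted by p-value: \code{set_name}, \code{N},
#'   \code{m}, \code{n}, \code{k}, \code{p_value}, \code{q_value},
#'   \code{significant}.
#' @export
pathwayEnrichment <- function(genes, geneSets, universeSize, fdr = 0.05,
                              uncorrected = FALSE) {
  genes <- unique(genes)
  if (!length(genes)) stop("empty gene list")
  stopifnot(is.list(geneSets), !is.null(names(geneSets)))
  if (universeSize < length(genes))
    stop("universe size cannot be smaller than the interested gene list")
  n <- length(genes)
  rows <- lapply(names(geneSets), function(nm) {
    set <- unique(geneSets[[nm]])
    k <- length(intersect(genes, set))
    if (k == 0L) return(NULL)
    m <- length(set)
    if (m > universeSize)
      stop(sprintf("gene set '%s' is larger than the universe", nm))
    data.frame(set_name = nm, N = universeSize, m = m, n = n, k = k,
               p_value = hypergeometricTail(universeSize, m, n, k),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res))
    return(data.frame(set_name = character(), N = integer(), m = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- (if (uncorrected) res$p_value else res$q_value) < fdr
  res <- res[order(res$p_value, res$set_name), ]
  rownames(res) <- NULL
  res
}

#' Combine two pair lists
#'
#' Deduplicated union preserving first-seen order: all of \code{listA}, then
#' the members of \code{listB} not already present. For data.frames of
#' canonical pairs, membership is judged on the \code{gene_a|gene_b} key.
#'
#' @param listA,listB character vectors of pair keys, or data.frames with
#'   columns \code{gene_a}, \code{gene_b} (both arguments must be of the
#'   same kind).
#' @return the union, of the same kind as the inputs.
#' @export
combinePairLists <- function(listA, listB) {
  if (is.data.frame(listA) && is.data.frame(listB)) {
    a <- listA[!duplicated(pairKeys(listA)), , drop = FALSE]
    b <- listB[!duplicated(pairKeys(listB)), , drop = FALSE]
    add <- !pairKeys(b) %in% pairKeys(a)
    common <- intersect(names(a), names(b))
    out <- rbind(a[, common, drop = FALSE], b[add, common, drop = FALSE])
    rownames(out) <- NULL
    out
  } else if (is.character(listA) && is.character(listB)) {
    a <- unique(listA)
    c(a, setdiff(unique(listB), a))
  } else stop("listA and listB must both be character keys or both data.frames")
}
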