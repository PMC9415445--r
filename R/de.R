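#' Two-group differential expression statistics
#'
#' Per gene: fold-change as the ratio of arithmetic group means on the
#' loaded (linear) scale, Student's two-sample t statistic with pooled
#' variance (df = n_a + n_b - 2), and the two-sided p-value. Welch's
#' unequal-variance form is available behind a flag; a log2 fold-change
#' column can be added. Genes with zero pooled variance have no defined t
#' and are reported with NA statistics and flagged, never with a silent
#' p of 0.
#'
#' @param groupA,groupB expression matrices over identical gene sets, >= 2
#'   samples each. Fold-change and t are oriented as A relative to B.
#' @param welch logical; use Welch's t with Satterthwaite df instead of the
#'   pooled form.
#' @param log2fc logical; add a \code{log2fc} column.
#' @return data.frame: \code{gene}, \code{fc}, \code{t}, \code{p},
#'   \code{df}, \code{degenerate}.
#' @examples
#' a <- matrix(c(1, 2, 3), 1, dimnames = list("g1", paste0("a", 1:3)))
#' b <- matrix(c(4, 5, 6), 1, dimnames = list("g1", paste0("b", 1:3)))
#' twoGroupStats(a, b)  # t = -3.6742 on 4 df
#' @export
twoGroupStats <- function(groupA, groupB, welch = FALSE, log2fc = FALSE) {
  a <- .asExprMatrix(groupA, "groupA")
  b <- .asExprMatrix(groupB, "groupB")
  if (!setequal(rownames(a), rownames(b)))
    stop("the two groups must cover identical gene sets")
  b <- b[rownames(a), , drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
    tt <- (ma - mb) / sqrt(se2)
    degenerate <- se2 == 0
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- rep(na + nb - 2, length(ma))
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    degenerate <- sp2 == 0
  }
  tt[degenerate] <- NA_real_
  df[degenerate] <- NA_real_
  p <- studentTPvalue(tt, df)
  if (any(degenerate))
    message(sprintf(
      "twoGroupStats: %d gene(s) with zero pooled variance; statistics set to NA",
      sum(degenerate)))
  out <- data.frame(gene = rownames(a), fc = ma / mb, t = tt, p = p,
                    df = df, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (log2fc) out$log2fc <- log2(out$fc)
  out
}

#' Two-sided Student t p-value
#'
#' Tail probability of the central t distribution:
#' \code{2 * pt(-|t|, df)}. Vectorized over \code{t} (and \code{df}).
#'
#' @param t t statistic(s).
#' @param df degrees of freedom (>= 1).
#' @return two-sided p-value(s) in (0, 1]; NA propagates.
#' @examples
#' studentTPvalue(-3.72567, 10)  # 0.003938
#' @export
studentTPvalue <- function(t, df) {
  if (any(df < 1, na.rm = TRUE)) stop("df must be >= 1")
  2 * pt(-abs(t), df)
}

#' Map genes across species via a provided ortholog table
#'
#' Keeps only strict one-to-one mappings: an input gene with no table entry
#' counts as unmapped, one with several distinct targets as ambiguous;
#' neither contributes to the output. Targets are deduplicated in
#' first-seen order.
#'
#' @param genes character vector of source-species gene ids.
#' @param map data.frame with columns \code{source_gene},
#'   \code{target_gene} (repeated source rows allowed).
#' @return list: \code{mapped} (character), \code{n_unmapped},
#'   \code{n_ambiguous}.
#' @export
mapOrthologs <- function(genes, map) {
  stopifnot(is.data.frame(map),
            all(c("source_gene", "target_gene") %in% names(map)))
  map <- unique(map[, c("source_gene", "target_gene")])
  genes <- unique(genes)
  targets <- split(map$target_gene, map$source_gene)
  n_tgt <- vapply(genes, function(g) {
    tg <- targets[[g]]
    if (is.null(tg)) 0L else length(tg)
  }, integer(1L))
  mapped <- unlist(targets[genes[n_tgt == 1L]], use.names = FALSE)
  list(mapped = unique(mapped),
       n_unmapped = sum(n_tgt == 0L),
       n_ambiguous = sum(n_tgt > 1L))
}

#' Treatment-reversal frequency table
#'
#' For the genes dysregulated in the disease model versus control
#' (two-sided p below \code{pFilter}, uncorrected), records each
#' treatment-vs-model p-value and counts, per gene, in how many treatment
#' protocols that p falls strictly below each threshold. Counts are
#' necessarily nondecreasing across thresholds and bounded by the number of
#' treatments. By default a treatment "reversal" is judged on the p-value
#' alone; \code{directionCheck = TRUE} additionally requires the
#' treatment-vs-model effect to point opposite to the model-vs-control t.
#'
#' @param modelStats data.frame from \code{\link{twoGroupStats}} for the
#'   model-vs-control comparison.
#' @param treatmentStats named list of data.frames from
#'   \code{\link{twoGroupStats}}, one per treatment (treatment vs model);
#'   every filtered gene must be present in each.
#' @param thresholds increasing p thresholds for the counts (default .05,
#'   .1, .2).
#' @param pFilter model-vs-control significance filter (default 0.05,
#'   strict, uncorrected).
#' @param directionCheck logical; require opposite effect direction.
#' @return data.frame, one row per filtered gene ordered by model p:
#'   \code{gene}, \code{fc_model}, \code{t_model}, \code{p_model}, one
#'   \code{p_<treatment>} column per treatment, and one
#'   \code{n_p_lt_<threshold>} count column per threshold.
#' @export
treatmentReversalTable <- function(modelStats, treatmentStats,
                                   thresholds = c(0.05, 0.1, 0.2),
                                   pFilter = 0.05, directionCheck = FALSE) {
  stopifnot(is.data.frame(modelStats),
            all(c("gene", "fc", "t", "p") %in% names(modelStats)),
            is.list(treatmentStats), length(treatmentStats) >= 1L,
            !is.null(names(treatmentStats)),
            is.numeric(thresholds), !is.unsorted(thresholds))
  sel <- modelStats[!is.na(modelStats$p) & modelStats$p < pFilter, ,
                    drop = FALSE]
  sel <- sel[order(sel$p), , drop = FALSE]
  if (!nrow(sel)) stop("no gene passes the model-vs-control filter")
  out <- data.frame(gene = sel$gene, fc_model = sel$fc, t_model = sel$t,
                    p_model = sel$p, stringsAsFactors = FALSE)
  pmat <- matrix(NA_real_, nrow(sel), length(treatmentStats))
  counted <- matrix(FALSE, nrow(sel), length(treatmentStats))
  for (j in seq_along(treatmentStats)) {
    ts <- treatmentStats[[j]]
    idx <- match(sel$gene, ts$gene)
    if (anyNA(idx))
      stop(sprintf("gene missing from treatment comparison '%s': %s",
                   names(treatmentStats)[j], sel$gene[is.na(idx)][1L]))
    pmat[, j] <- ts$p[idx]
    counted[, j] <- if (directionCheck)
      sign(ts$t[idx]) == -sign(sel$t) else TRUE
    out[[paste0("p_", names(treatmentStats)[j])]] <- ts$p[idx]
  }
  for (th in thresholds)
    out[[sprintf("n_p_lt_%g", th)]] <-
      as.integer(rowSums(pmat < th & counted, na.rm = TRUE))
  rownames(out) <- NULL
  out
}
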