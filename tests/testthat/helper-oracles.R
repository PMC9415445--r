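# Independent brute-force oracles. These deliberately re-derive each
# quantity by the most literal counting route available, sharing no code
# with the package implementations they check.

rand_expr <- function(G, S, seed, integers = FALSE) {
  set.seed(seed)
  vals <- if (integers) sample(1:15, G * S, replace = TRUE)
          else runif(G * S, 1, 100)
  matrix(vals, G, S,
         dimnames = list(sprintf("g%03d", seq_len(G)),
                         sprintf("s%02d", seq_len(S))))
}

# exhaustive per-pair counting (triple loop) for stable pairs
naive_stable_pairs <- function(x, threshold, inclusive = TRUE) {
  rn <- rownames(x)
  S <- ncol(x)
  rows <- list()
  for (i in seq_len(nrow(x) - 1L)) {
    for (j in seq(i + 1L, nrow(x))) {
      gt <- 0L
      lt <- 0L
      for (s in seq_len(S)) {
        if (x[i, s] > x[j, s]) gt <- gt + 1L
        else if (x[i, s] < x[j, s]) lt <- lt + 1L
      }
      supp <- max(gt, lt) / S
      keep <- if (inclusive) supp >= threshold else supp > threshold
      if (keep && gt != lt) {
        a <- rn[i]
        b <- rn[j]
        dir <- if (gt > lt) "a_gt_b" else "a_lt_b"
        if (a > b) {
          tmp <- a; a <- b; b <- tmp
          dir <- if (dir == "a_gt_b") "a_lt_b" else "a_gt_b"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = a, gene_b = b, direction = dir, support = supp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      direction = character(), support = numeric()))
  df <- do.call(rbind, rows)
  df <- df[order(df$gene_a, df$gene_b, method = "radix"), ]
  rownames(df) <- NULL
  df
}

# AUC by explicit enumeration of all positive-negative sample pairs
naive_auc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (i in seq_along(sp)) {
    for (j in seq_along(sn)) {
      tot <- tot + if (sp[i] > sn[j]) 1 else if (sp[i] == sn[j]) 0.5 else 0
    }
  }
  tot / (length(sp) * length(sn))
}

# hypergeometric upper tail by full enumeration of all size-n draws
enum_hyper_tail <- function(N, m, n, k) {
  marked <- seq_len(m)
  combos <- utils::combn(N, n)
  mean(apply(combos, 2L, function(s) sum(s %in% marked) >= k))
}

# minimal hand-built signature for scoring tests; pairs must be canonical
make_sig <- function(pairs) {
  methods::new("PairSignature", pairs = pairs,
               buildConfig = list(), buildReport = list())
}
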