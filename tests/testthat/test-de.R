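ratTable2 <- function() {
  read.delim(system.file("extdata", "copd_rat_model_de.tsv",
                         package = "reosig"))
}

ratTable3 <- function() {
  read.delim(system.file("extdata", "copd_rat_treatment_pvalues.tsv",
                         package = "reosig"))
}

test_that("pooled t matches the closed-form textbook computation", {
  a <- matrix(c(1, 2, 3), 1, dimnames = list("g1", paste0("a", 1:3)))
  b <- matrix(c(4, 5, 6), 1, dimnames = list("g1", paste0("b", 1:3)))
  st <- twoGroupStats(a, b)
  expect_equal(st$t, -3.6742, tolerance = 1e-4)
  expect_equal(st$df, 4)
  expect_equal(st$fc, 2 / 5)
  expect_equal(st$p, 2 * pt(-3.674235, 4), tolerance = 1e-5)
  # against base R's pooled t-test
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(st$t, unname(ref$statistic))
  expect_equal(st$p, ref$p.value)
})

test_that("identical groups give t = 0 and p = 1 for every gene", {
  x <- rand_expr(20, 4, seed = 44)
  st <- twoGroupStats(x, x)
  expect_true(all(st$t == 0))
  expect_true(all(st$p == 1))
  expect_true(all(st$fc == 1))
})

test_that("swapping the groups negates t and preserves p", {
  set.seed(27)
  a <- rand_expr(50, 6, seed = 27)
  b <- rand_expr(50, 6, seed = 28)
  ab <- twoGroupStats(a, b)
  ba <- twoGroupStats(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("zero-variance genes are flagged, not silently significant", {
  a <- matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "ok"), paste0("a", 1:3)))
  b <- matrix(c(1, 1, 1, 5, 6, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "ok"), paste0("b", 1:3)))
  expect_message(st <- twoGroupStats(a, b), "zero pooled variance")
  expect_true(st$degenerate[st$gene == "flat"])
  expect_true(is.na(st$p[st$gene == "flat"]))
  expect_false(is.na(st$p[st$gene == "ok"]))
})

test_that("Welch flag departs from the pooled form under unequal variances", {
  set.seed(77)
  a <- matrix(rnorm(30, 0, 1), 3, 10,
              dimnames = list(paste0("g", 1:3), paste0("a", 1:10)))
  b <- matrix(rnorm(30, 0, 5), 3, 10,
              dimnames = list(paste0("g", 1:3), paste0("b", 1:10)))
  pooled <- twoGroupStats(a, b)
  welch <- twoGroupStats(a, b, welch = TRUE)
  expect_false(isTRUE(all.equal(pooled$p, welch$p)))
  ref <- t.test(a[1, ], b[1, ])
  expect_equal(welch$t[1], unname(ref$statistic))
  expect_equal(welch$p[1], ref$p.value)
})

test_that("published rat-model p-values reproduce from t at 10 degrees of freedom", {
  tab <- ratTable2()
  expect_equal(nrow(tab), 16L)
  p <- studentTPvalue(tab$t, 10)
  expect_equal(p, tab$p, tolerance = 1e-3)
  expect_equal(studentTPvalue(-3.72567, 10), 0.003938, tolerance = 1e-3)
  expect_equal(studentTPvalue(-2.24158, 10), 0.048873, tolerance = 1e-3)
  expect_equal(studentTPvalue(0, 10), 1)
  expect_error(studentTPvalue(1, 0), "df")
})

test_that("t p-value is monotone decreasing in the statistic's magnitude", {
  ts <- seq(0, 6, by = 0.5)
  p <- studentTPvalue(ts, 10)
  expect_false(is.unsorted(rev(p)))
  expect_equal(studentTPvalue(-2, 10), studentTPvalue(2, 10))
})

test_that("ortholog mapping keeps only strict one-to-one translations", {
  map <- data.frame(source_gene = c("A", "B", "C", "C"),
                    target_gene = c("a", "b", "c1", "c2"))
  out <- mapOrthologs(c("A", "B", "C", "D"), map)
  expect_identical(out$mapped, c("a", "b"))
  expect_equal(out$n_unmapped, 1L)   # D
  expect_equal(out$n_ambiguous, 1L)  # C

  # seeded random map against an independent dictionary walk
  set.seed(33)
  src <- paste0("S", 1:60)
  tgt <- paste0("t", sample(1:50, 80, replace = TRUE))
  map2 <- data.frame(source_gene = sample(src, 80, replace = TRUE),
                     target_gene = tgt)
  genes <- sample(src, 40)
  got <- mapOrthologs(genes, map2)
  lookup <- new.env()
  for (i in seq_len(nrow(map2))) {
    prev <- get0(map2$source_gene[i], envir = lookup, ifnotfound = NULL)
    assign(map2$source_gene[i], unique(c(prev, map2$target_gene[i])),
           envir = lookup)
  }
  exp_mapped <- character()
  exp_un <- exp_amb <- 0L
  for (g in genes) {
    tg <- get0(g, envir = lookup, ifnotfound = NULL)
    if (is.null(tg)) exp_un <- exp_un + 1L
    else if (length(tg) > 1L) exp_amb <- exp_amb + 1L
    else exp_mapped <- c(exp_mapped, tg)
  }
  expect_setequal(got$mapped, unique(exp_mapped))
  expect_equal(got$n_unmapped, exp_un)
  expect_equal(got$n_ambiguous, exp_amb)
})

test_that("published reversal-frequency counts reproduce by strict p counting", {
  t2 <- ratTable2()
  t3 <- ratTable3()
  model <- data.frame(gene = t2$gene, fc = t2$fc, t = t2$t, p = t2$p)
  treatments <- lapply(c("p_BYF", "p_BJF", "p_YZF", "p_APL"), function(cn)
    data.frame(gene = t3$gene, fc = NA_real_, t = NA_real_, p = t3[[cn]]))
  names(treatments) <- c("BYF", "BJF", "YZF", "APL")
  out <- treatmentReversalTable(model, treatments)
  expect_equal(nrow(out), 16L)
  idx <- match(out$gene, t3$gene)
  expect_equal(out$n_p_lt_0.05, t3$num_p_lt_0.05[idx])
  expect_equal(out$n_p_lt_0.1, t3$num_p_lt_0.1[idx])
  expect_equal(out$n_p_lt_0.2, t3$num_p_lt_0.2[idx])
  expect_equal(out$n_p_lt_0.05[out$gene == "Upf2"], 3L)
  expect_equal(out$n_p_lt_0.2[out$gene == "Upf2"], 4L)
  expect_equal(unlist(out[out$gene == "Dhx16",
                          c("n_p_lt_0.05", "n_p_lt_0.1", "n_p_lt_0.2")],
                      use.names = FALSE), c(2L, 3L, 3L))
})

test_that("reversal counts are monotone in threshold and bounded by treatments", {
  t2 <- ratTable2()
  t3 <- ratTable3()
  model <- data.frame(gene = t2$gene, fc = t2$fc, t = t2$t, p = t2$p)
  treatments <- lapply(c("p_BYF", "p_BJF", "p_YZF", "p_APL"), function(cn)
    data.frame(gene = t3$gene, fc = NA_real_, t = NA_real_, p = t3[[cn]]))
  names(treatments) <- c("BYF", "BJF", "YZF", "APL")
  out <- treatmentReversalTable(model, treatments)
  expect_true(all(out$n_p_lt_0.05 <= out$n_p_lt_0.1))
  expect_true(all(out$n_p_lt_0.1 <= out$n_p_lt_0.2))
  expect_true(all(out$n_p_lt_0.2 <= 4L))

  # indifferent treatments count nothing
  flat <- lapply(treatments, function(d) transform(d, p = 0.5))
  out_flat <- treatmentReversalTable(model, flat)
  expect_true(all(out_flat$n_p_lt_0.2 == 0L))

  # a gene absent from one treatment table is a hard error
  broken <- treatments
  broken$BYF <- broken$BYF[broken$BYF$gene != "Plk4", ]
  expect_error(treatmentReversalTable(model, broken),
               "missing from treatment comparison 'BYF': Plk4")
})

test_that("direction-aware mode only counts opposite-signed treatment effects", {
  model <- data.frame(gene = c("gU", "gD"), fc = c(2, 0.5),
                      t = c(5, -5), p = c(0.001, 0.001))
  tr <- list(T1 = data.frame(gene = c("gU", "gD"), fc = 1,
                             t = c(-3, -3), p = c(0.01, 0.01)))
  plain <- treatmentReversalTable(model, tr)
  strict <- treatmentReversalTable(model, tr, directionCheck = TRUE)
  expect_equal(plain$n_p_lt_0.05, c(1L, 1L))
  # gD's treatment effect points the same way as its model effect
  expect_equal(strict$n_p_lt_0.05[strict$gene == "gU"], 1L)
  expect_equal(strict$n_p_lt_0.05[strict$gene == "gD"], 0L)
})

test_that("planted reversed genes accumulate higher reversal counts", {
  ts <- simulateTreatmentStudy(nGenes = 400, nDeGenes = 60,
                               effectSize = 1.5, reversalFraction = 1,
                               reversedPerTreatment = 0.5, noiseSd = 0.5,
                               seed = 61)
  model <- twoGroupStats(ts$model, ts$control)
  treatments <- lapply(ts$treatments, function(m) twoGroupStats(m, ts$model))
  out <- treatmentReversalTable(model, treatments)
  reversed_any <- unique(unlist(ts$truth_reversed))
  in_rev <- out$gene %in% reversed_any
  expect_gt(mean(out$n_p_lt_0.1[in_rev]), mean(out$n_p_lt_0.1[!in_rev]))
})
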