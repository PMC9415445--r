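test_that("indicator matrix flags the cancer orientation per pair and sample", {
  sig <- make_sig(data.frame(
    gene_a = c("g1", "g3"), gene_b = c("g2", "g4"),
    normal_direction = c("a_lt_b", "a_gt_b"),
    cancer_direction = c("a_gt_b", "a_lt_b"),
    stringsAsFactors = FALSE))
  x <- matrix(c(5, 1, 1, 5,   # s1: both pairs cancer-like
                1, 5, 5, 1,   # s2: both normal-like
                2, 2, 1, 5),  # s3: pair1 tied, pair2 cancer-like
              4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  ind <- reoIndicatorMatrix(x, sig)
  expect_identical(rownames(ind), c("g1|g2", "g3|g4"))
  expect_equal(unname(ind[, "s1"]), c(1L, 1L))
  expect_equal(unname(ind[, "s2"]), c(0L, 0L))
  expect_equal(unname(ind[, "s3"]), c(NA_integer_, 1L))
})

test_that("unmeasured pairs become all-NA rows with a reported count", {
  sig <- make_sig(data.frame(
    gene_a = c("g1", "g8"), gene_b = c("g2", "g9"),
    normal_direction = "a_lt_b", cancer_direction = "a_gt_b",
    stringsAsFactors = FALSE))
  x <- matrix(c(1, 2), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_message(ind <- reoIndicatorMatrix(x, sig), "1 pair")
  expect_true(all(is.na(ind["g8|g9", ])))
})

test_that("indicator is distortion-invariant and consistent with risk scores", {
  cc <- simulateCaseControl(simConfig(nGenes = 50, nPlantedPairs = 10,
                                      nSamplesPerGroup = 12, noiseSd = 0.8,
                                      platforms = c(1, 1), seed = 19))
  sig <- buildSignature(list(cc$platforms[[1]]), cc$platforms[[2]]$normal)
  x <- cc$platforms[[2]]$cancer
  ind <- reoIndicatorMatrix(x, sig)
  for (seed in 1:10)
    expect_identical(reoIndicatorMatrix(applyMonotoneDistortion(x, seed),
                                        sig), ind)
  sc <- scoreCohort(x, sig)
  expect_equal(unname(colSums(ind, na.rm = TRUE) /
                      colSums(!is.na(ind))), sc$score)

  # noise-free cancer samples: all-ones columns
  cc0 <- simulateCaseControl(simConfig(nGenes = 30, nPlantedPairs = 6,
                                       nSamplesPerGroup = 8, noiseSd = 0,
                                       platforms = c(1, 1), seed = 4))
  sig0 <- buildSignature(list(cc0$platforms[[1]]), cc0$platforms[[2]]$normal)
  ind0 <- reoIndicatorMatrix(cc0$platforms[[2]]$cancer, sig0)
  expect_true(all(ind0 == 1L))
})

test_that("stage correlation handles perfect agreement, constants, and bad input", {
  ind <- rbind("gA|gB" = c(0L, 0L, 1L, 1L),
               "gC|gD" = c(1L, 1L, 1L, 1L))
  colnames(ind) <- paste0("s", 1:4)
  res <- suppressMessages(
    stageCorrelatedPairs(ind, c(1, 1, 2, 2), fdr = 0.5))
  expect_equal(nrow(res), 1L)          # constant row excluded
  expect_equal(attr(res, "n_excluded"), 1L)
  expect_equal(res$rho, 1)
  # exact permutation: 2 of choose(4,2)=6 arrangements reach |rho|=1
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$method, "exact_permutation")
  expect_identical(res$gene_a, "gA")

  expect_error(stageCorrelatedPairs(ind, c(1, 1, 1, 1)),
               "two distinct stage")
  expect_error(stageCorrelatedPairs(ind, c(1, 2)), "one stage label per")
})

test_that("ordinal stage coding accepts factors and labels in given order", {
  ind <- rbind("gA|gB" = c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, 0L,
                           1L, 1L))
  colnames(ind) <- paste0("s", 1:14)
  stages_chr <- rep(c("moderate", "severe"), 7)
  stages_num <- rep(c(1, 2), 7)
  a <- stageCorrelatedPairs(ind, stages_chr)
  b <- stageCorrelatedPairs(ind, stages_num)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_value, b$p_value)
})

test_that("exact permutation null is complete for uncorrelated indicators", {
  # rho = 0 here, and every arrangement has |rho| >= 0: p must be exactly 1
  ind <- matrix(c(0L, 1L, 0L, 1L), 1, 4,
                dimnames = list("gA|gB", paste0("s", 1:4)))
  res <- stageCorrelatedPairs(ind, c(1, 1, 2, 2))
  expect_equal(res$rho, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$method, "exact_permutation")
  # the same pair under the t approximation keeps the same rho
  ap <- stageCorrelatedPairs(ind, c(1, 1, 2, 2), exactN = 0)
  expect_equal(ap$rho, 0)
  expect_equal(ap$p_value, 1)
})

test_that("null stage cohorts stay within the BH false-discovery budget", {
  cfg <- simConfig(nGenes = 300, nPlantedPairs = 60, nSamplesPerGroup = 30,
                   noiseSd = 0.8, seed = 55)
  cc <- simulateCaseControl(cfg)
  sig <- buildSignature(list(cc$platforms[[1]]), cc$platforms[[2]]$normal)
  st <- simulateStageCohort(cfg, nPerStage = c(40L, 40L),
                            flipProb = c(0.4, 0.4), stageFraction = 1)
  res <- suppressMessages(
    stageCorrelatedPairs(reoIndicatorMatrix(st$matrix, sig), st$stages,
                         fdr = 0.05))
  expect_lte(sum(res$significant), ceiling(0.05 * nrow(res)))
})

test_that("hypergeometric tail reproduces printed and closed-form values", {
  # overlap of 33- and 301-element lists among 2046, 8 common
  expect_equal(signif(hypergeometricTail(2046, 33, 301, 8), 3), 0.0997)
  expect_equal(hypergeometricTail(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(hypergeometricTail(100, 10, 10, 0), 1)
  expect_error(hypergeometricTail(10, 3, 4, 5), "impossible")
  expect_error(hypergeometricTail(10, 12, 4, 2), "universe")
})

test_that("tail equals exhaustive draw enumeration and phyper on small universes", {
  cases <- list(c(8, 3, 4, 2), c(10, 5, 5, 3), c(12, 6, 4, 1),
                c(12, 2, 9, 2), c(20, 6, 4, 3))
  for (cs in cases) {
    expect_equal(hypergeometricTail(cs[1], cs[2], cs[3], cs[4]),
                 enum_hyper_tail(cs[1], cs[2], cs[3], cs[4]))
  }
  set.seed(14)
  for (i in 1:25) {
    N <- sample(50:5000, 1)
    m <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample.int(min(m, n), 1)
    expect_equal(hypergeometricTail(N, m, n, k),
                 phyper(k - 1, m, N - m, n, lower.tail = FALSE))
  }
})

test_that("tail probability is nonincreasing in k", {
  p <- vapply(0:10, function(k) hypergeometricTail(40, 10, 15, k),
              numeric(1L))
  expect_false(is.unsorted(rev(p)))
  expect_equal(p[1], 1)
})

test_that("list overlap significance matches the tail at the observed intersection", {
  a <- paste0("pair", 1:33)
  b <- paste0("pair", c(1:8, 1000:1292))
  ov <- overlapSignificance(a, b, 2046)
  expect_equal(ov$overlap, 8L)
  expect_equal(signif(ov$p_value, 3), 0.0997)

  expect_equal(overlapSignificance(paste0("x", 1:5),
                                   paste0("y", 1:5), 100)$p_value, 1)
  same <- overlapSignificance(paste0("x", 1:5), paste0("x", 1:5), 40)
  expect_equal(same$p_value, hypergeometricTail(40, 5, 5, 5))
  expect_error(overlapSignificance(paste0("x", 1:50), "y", 40), "universe")
})

test_that("pathway enrichment reproduces hand-computed tail values", {
  sets <- list(hit = paste0("g", 1:5),
               part = paste0("g", c(4:8)),
               miss = paste0("h", 1:6))
  genes <- paste0("g", 1:5)
  res <- pathwayEnrichment(genes, sets, universeSize = 20)
  expect_identical(res$set_name[1], "hit")   # exact match ranks first
  expect_false("miss" %in% res$set_name)     # k = 0 omitted
  expect_equal(res$p_value[res$set_name == "hit"],
               hypergeometricTail(20, 5, 5, 5))
  expect_equal(res$p_value[res$set_name == "part"],
               hypergeometricTail(20, 5, 5, 2))
  # hand enumeration for the partial set: P(X >= 2), m = 5, n = 5, N = 20
  expect_equal(res$p_value[res$set_name == "part"],
               enum_hyper_tail(20, 5, 5, 2))
  expect_error(pathwayEnrichment(character(), sets, 20), "empty gene list")
})

test_that("BH q-values respect the step-up ordering", {
  set.seed(20)
  sets <- lapply(1:30, function(i) sample(paste0("g", 1:200), 25))
  names(sets) <- paste0("set", 1:30)
  res <- pathwayEnrichment(paste0("g", 1:40), sets, universeSize = 500)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_false(is.unsorted(res$q_value[order(res$p_value)]))
})

test_that("pair list union deduplicates while preserving first-seen order", {
  a <- paste0("p", 1:33)
  b <- paste0("p", c(1:8, 100:392))
  u <- combinePairLists(a, b)
  expect_equal(length(u), 33 + 301 - 8)
  expect_identical(u[1:33], a)

  expect_equal(length(combinePairLists(paste0("a", 1:2),
                                       paste0("b", 1:3))), 5L)
  expect_identical(combinePairLists(a, a), a)

  df_a <- data.frame(gene_a = c("gA", "gB"), gene_b = c("gX", "gY"))
  df_b <- data.frame(gene_a = c("gB", "gC"), gene_b = c("gY", "gZ"))
  u2 <- combinePairLists(df_a, df_b)
  expect_equal(pairKeys(u2), c("gA|gX", "gB|gY", "gC|gZ"))
})
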