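#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic case/control
#' generator. The generator emulates the statistical structure the
#' REO analysis assumes: two phenotypes with planted reversal-ordered gene
#' pairs on disjoint gene sets, several "platforms" measuring overlapping
#' gene subsets, and per-sample strictly monotone batch distortions.
#'
#' Gene means live on a latent log-like scale laid out so the planted truth
#' is unambiguous: each planted pair occupies its own band of width
#' \code{logGap} (the two member means at the band edges), bands are
#' separated by guard zones, and all non-planted genes fall inside guard
#' zones, never inside a band. The cancer phenotype swaps the two means of
#' every planted pair and changes nothing else, so the only mean-order
#' differences between phenotypes are the planted pairs themselves; without
#' this reservation, any gene whose mean landed inside a band would
#' necessarily be stably reversed against the pair members too, and
#' recall/contamination against the planted truth would be ill-defined.
#'
#' Per-sample noise of total standard deviation \code{noiseSd} is split into
#' two equal-variance components: an array-level shift shared by all genes
#' of a sample (the dominant technical effect in array data, and itself a
#' strictly monotone transform) and an independent gene-level residual. Only
#' the residual can flip a within-sample ordering, so a planted pair flips
#' in a given sample with probability \code{pnorm(-logGap / noiseSd)}.
#' Values are emitted through a softplus (strictly increasing, so every
#' rank-based quantity is unaffected), guaranteeing positive intensities on
#' a platform-arbitrary scale.
#'
#' @param nGenes total number of genes.
#' @param nPlantedPairs number of planted reversal pairs; the pairs use
#'   disjoint genes, so \code{2 * nPlantedPairs <= nGenes}.
#' @param nSamplesPerGroup samples per phenotype per platform.
#' @param logGap latent-scale separation between the two genes of a planted
#'   pair.
#' @param noiseSd total per-sample latent-scale noise standard deviation
#'   (>= 0; 0 gives the noise-free limit).
#' @param platforms numeric vector of gene-subset fractions in (0, 1], one
#'   per platform.
#' @param distortion logical; apply a random strictly monotone per-sample
#'   distortion to every generated matrix.
#' @param keepPlantedOnPlatforms logical; platforms always retain all
#'   planted-pair genes (set \code{FALSE} to exercise missing-gene score
#'   handling).
#' @param seed integer seed; every generator is bit-reproducible from it.
#' @return a validated list of class \code{reosigSimConfig}.
#' @export
simConfig <- function(nGenes = 1000L, nPlantedPairs = 200L,
                      nSamplesPerGroup = 50L, logGap = 2, noiseSd = 1,
                      platforms = c(1, 1), distortion = TRUE,
                      keepPlantedOnPlatforms = TRUE, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              nPlantedPairs = as.integer(nPlantedPairs),
              nSamplesPerGroup = as.integer(nSamplesPerGroup),
              logGap = logGap, noiseSd = noiseSd, platforms = platforms,
              distortion = isTRUE(distortion),
              keepPlantedOnPlatforms = isTRUE(keepPlantedOnPlatforms),
              seed = as.integer(seed))
  if (cfg$nGenes < 1L || cfg$nPlantedPairs < 1L || cfg$nSamplesPerGroup < 1L)
    stop("all counts must be >= 1")
  if (2L * cfg$nPlantedPairs > cfg$nGenes)
    stop("planted pairs use disjoint genes: need 2*nPlantedPairs <= nGenes")
  if (!is.numeric(cfg$logGap) || cfg$logGap <= 0)
    stop("logGap must be positive")
  if (!is.numeric(cfg$noiseSd) || cfg$noiseSd < 0)
    stop("noiseSd must be >= 0")
  if (!length(cfg$platforms) || any(cfg$platforms <= 0 | cfg$platforms > 1))
    stop("platform fractions must lie in (0, 1]")
  class(cfg) <- "reosigSimConfig"
  cfg
}

.gene_ids <- function(n) sprintf(paste0("g%0", nchar(n), "d"), seq_len(n))

# numerically stable softplus: strictly increasing map onto (0, Inf), so it
# changes no within-sample ordering while guaranteeing positive output
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# latent mean layout: planted pair k occupies band [centre_k - logGap/2,
# centre_k + logGap/2]; guard zones of width 1 + noiseSd separate the bands
# and hold all bystander genes (uniformly placed), so no non-planted gene
# mean ever falls inside a band. Gene roles are assigned at random. Returns
# normal-phenotype means plus the planted index vectors.
.pair_layout <- function(nGenes, nPairs, logGap, noiseSd, start = 4) {
  z <- 1 + noiseSd
  idx <- sample.int(nGenes, 2L * nPairs)
  a_idx <- idx[seq_len(nPairs)]
  b_idx <- idx[nPairs + seq_len(nPairs)]
  centres <- start + z + logGap / 2 + (sample.int(nPairs) - 1L) *
    (logGap + z)
  mu <- numeric(nGenes)
  mu[a_idx] <- centres - logGap / 2    # normal phenotype: A below B
  mu[b_idx] <- centres + logGap / 2
  bystander <- setdiff(seq_len(nGenes), idx)
  if (length(bystander)) {
    zone <- sample.int(nPairs + 1L, length(bystander), replace = TRUE)
    mu[bystander] <- start + (zone - 1L) * (logGap + z) +
      runif(length(bystander), 0, z)
  }
  list(mu = mu, a_idx = a_idx, b_idx = b_idx)
}

# one noisy expression matrix on the latent scale, mapped through softplus;
# noise is an equal-variance split of array-level shift and gene-level
# residual
.sim_matrix <- function(mu, n, noiseSd, prefix) {
  G <- length(mu)
  comp <- noiseSd / sqrt(2)
  eps <- matrix(rnorm(G * n, 0, comp), G, n)
  shift <- matrix(rnorm(n, 0, comp), G, n, byrow = TRUE)
  x <- .softplus(mu + eps + shift)
  dimnames(x) <- list(names(mu), sprintf("%s_s%03d", prefix, seq_len(n)))
  x
}

# strictly increasing per-column map x -> a * x^b + c, a,b > 0, c >= 0,
# drawn from the current RNG stream
.distort <- function(x) {
  for (j in seq_len(ncol(x))) {
    a <- runif(1, 0.5, 2)
    b <- runif(1, 0.5, 2)
    cc <- runif(1, 0, 1)
    x[, j] <- a * x[, j]^b + cc
  }
  x
}

#' Simulate a multi-platform case/control cohort with planted reversal pairs
#'
#' For each planted pair (A, B), the normal phenotype places A's mean
#' \code{logGap} below B's (ordering A < B) and the cancer phenotype swaps
#' the two means (A > B); non-planted genes are identically distributed in
#' both phenotypes. Each platform measures its own gene subset and draws its
#' own independent samples for both phenotypes; when \code{distortion} is on,
#' every matrix additionally receives random strictly monotone per-sample
#' transforms, which change values but no within-sample ordering.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{platforms} (per platform, a list with
#'   one positive expression matrix per phenotype, named \code{normal} and
#'   \code{cancer}), \code{annotation} (data.frame: sample_id, phenotype,
#'   stage, dataset_id), \code{truth} (canonical data.frame: gene_a, gene_b,
#'   normal_direction) and \code{config}.
#' @examples
#' cc <- simulateCaseControl(simConfig(nGenes = 40, nPlantedPairs = 5,
#'                                     nSamplesPerGroup = 10, seed = 3))
#' dim(cc$platforms[[1]]$normal)
#' @export
simulateCaseControl <- function(config) {
  stopifnot(inherits(config, "reosigSimConfig"))
  set.seed(config$seed)
  G <- config$nGenes
  P <- config$nPlantedPairs
  ids <- .gene_ids(G)
  lay <- .pair_layout(G, P, config$logGap, config$noiseSd)
  a_idx <- lay$a_idx
  b_idx <- lay$b_idx
  planted_idx <- c(a_idx, b_idx)
  mu_normal <- lay$mu                              # normal: A < B
  names(mu_normal) <- ids
  mu_cancer <- mu_normal
  mu_cancer[a_idx] <- mu_normal[b_idx]             # cancer: swapped
  mu_cancer[b_idx] <- mu_normal[a_idx]

  truth <- .canonicalizePairs(
    data.frame(gene_a = ids[a_idx], gene_b = ids[b_idx],
               normal_direction = "a_lt_b", stringsAsFactors = FALSE),
    "normal_direction")
  rownames(truth) <- NULL

  platforms <- vector("list", length(config$platforms))
  ann <- list()
  for (k in seq_along(config$platforms)) {
    f <- config$platforms[k]
    n_keep <- max(1L, round(f * G))
    subset_idx <- sort(sample.int(G, n_keep))
    if (config$keepPlantedOnPlatforms)
      subset_idx <- sort(union(subset_idx, planted_idx))
    sub <- ids[subset_idx]
    mats <- list()
    for (ph in c("normal", "cancer")) {
      mu_ph <- if (ph == "normal") mu_normal else mu_cancer
      m <- .sim_matrix(mu_ph[sub], config$nSamplesPerGroup, config$noiseSd,
                       sprintf("plat%d_%s", k, ph))
      if (config$distortion) m <- .distort(m)
      mats[[ph]] <- m
      ann[[length(ann) + 1L]] <- data.frame(
        sample_id = colnames(m), phenotype = ph, stage = NA_character_,
        dataset_id = sprintf("sim_platform_%d", k), stringsAsFactors = FALSE)
    }
    platforms[[k]] <- mats
  }
  list(platforms = platforms, annotation = do.call(rbind, ann),
       truth = truth, config = config)
}

#' Apply a random strictly monotone distortion to each sample
#'
#' Emulates batch/scanner effects: every column is transformed by its own
#' strictly increasing map \code{x -> a * x^b + c} with \code{a, b > 0} and
#' \code{c >= 0}, drawn from \code{seed}. Values change; within-sample rank
#' order is exactly preserved, so every REO-based quantity is invariant.
#'
#' @param x positive expression matrix.
#' @param seed integer seed for the per-column coefficients.
#' @return distorted matrix of the same shape and dimnames.
#' @export
applyMonotoneDistortion <- function(x, seed) {
  x <- .asExprMatrix(x)
  if (any(x <= 0)) stop("monotone distortion requires a strictly positive matrix")
  set.seed(as.integer(seed))
  .distort(x)
}

#' Simulate an ordinal-stage cohort
#'
#' Generates one cohort of a single (disease) phenotype whose samples carry
#' an ordinal stage label (e.g. moderate < severe). A designated subset of
#' the planted pairs is stage-related: in a sample of stage s, such a pair
#' shows the cancer-like ordering with probability \code{flipProb[s]}
#' (nondecreasing in stage); all other planted pairs use the lowest-stage
#' probability throughout. The drawn orientation is imposed exactly, so the
#' per-pair indicator is an exact Bernoulli draw at the stated probability.
#'
#' @param config a \code{\link{simConfig}}; \code{nGenes},
#'   \code{nPlantedPairs}, noise and baseline settings are reused.
#' @param stageLevels character vector of ordinal stage labels, low to high.
#' @param nPerStage integer vector, samples per stage.
#' @param flipProb per-stage probability of the cancer-like ordering for
#'   stage-related pairs; must be nondecreasing.
#' @param stageFraction fraction of planted pairs that are stage-related.
#' @return list with \code{matrix} (positive expression), \code{annotation},
#'   \code{stages} (ordered factor per sample), \code{truth} (all planted
#'   pairs), \code{truth_stage_pairs} (the stage-related subset),
#'   \code{flip_probabilities} and \code{config}.
#' @export
simulateStageCohort <- function(config, stageLevels = c("moderate", "severe"),
                                nPerStage = c(50L, 50L),
                                flipProb = c(0.2, 0.8),
                                stageFraction = 0.5) {
  stopifnot(inherits(config, "reosigSimConfig"),
            length(stageLevels) >= 2L,
            length(nPerStage) == length(stageLevels),
            length(flipProb) == length(stageLevels))
  if (any(diff(flipProb) < 0))
    stop("flip probabilities must be nondecreasing in stage")
  if (any(flipProb < 0 | flipProb > 1)) stop("flip probabilities must be in [0, 1]")
  set.seed(config$seed)
  G <- config$nGenes
  P <- config$nPlantedPairs
  ids <- .gene_ids(G)
  lay <- .pair_layout(G, P, config$logGap, config$noiseSd)
  a_idx <- lay$a_idx
  b_idx <- lay$b_idx
  n_stage_pairs <- max(1L, round(stageFraction * P))
  stage_pair <- seq_len(P) <= n_stage_pairs

  mu <- lay$mu
  names(mu) <- ids
  lo <- mu[a_idx]
  hi <- mu[b_idx]

  n_total <- sum(nPerStage)
  stages <- factor(rep(stageLevels, nPerStage), levels = stageLevels,
                   ordered = TRUE)
  comp <- config$noiseSd / sqrt(2)
  shift <- rnorm(n_total, 0, comp)
  logx <- mu + matrix(rnorm(G * n_total, 0, comp), G, n_total)
  logx <- logx + matrix(shift, G, n_total, byrow = TRUE)
  # planted pairs: draw the orientation indicator, then impose it exactly by
  # assigning the larger of the two drawn values to the gene meant to be high
  for (p in seq_len(P)) {
    pr <- if (stage_pair[p]) flipProb[as.integer(stages)] else
      rep(flipProb[1L], n_total)
    cancer_like <- rbinom(n_total, 1L, pr) == 1L   # cancer-like: A > B
    va <- lo[p] + shift + rnorm(n_total, 0, comp)
    vb <- hi[p] + shift + rnorm(n_total, 0, comp)
    hi_v <- pmax(va, vb)
    lo_v <- pmin(va, vb)
    logx[a_idx[p], ] <- ifelse(cancer_like, hi_v, lo_v)
    logx[b_idx[p], ] <- ifelse(cancer_like, lo_v, hi_v)
  }
  dimnames(logx) <- list(ids, sprintf("stage_s%03d", seq_len(n_total)))
  x <- .softplus(logx)
  if (config$distortion) x <- .distort(x)

  truth <- data.frame(gene_a = ids[a_idx], gene_b = ids[b_idx],
                      normal_direction = "a_lt_b",
                      stage_related = stage_pair, stringsAsFactors = FALSE)
  truth <- .canonicalizePairs(truth, "normal_direction")
  rownames(truth) <- NULL
  ann <- data.frame(sample_id = colnames(x), phenotype = "copd",
                    stage = as.character(stages), dataset_id = "sim_stage",
                    stringsAsFactors = FALSE)
  list(matrix = x, annotation = ann, stages = stages, truth = truth,
       truth_stage_pairs = truth[truth$stage_related, , drop = FALSE],
       flip_probabilities = stats::setNames(flipProb, stageLevels),
       config = config)
}

#' Simulate a multi-group treatment study
#'
#' Emulates a control / disease-model / treatments design with a fixed number
#' of replicates per group (default 6). A set of genes is differentially
#' expressed in the model versus control by \code{effectSize} on the log2
#' scale (random sign per gene); for each treatment, a random subset of
#' those genes is pulled back toward the control mean by
#' \code{reversalFraction} of the effect, while the remaining genes keep the
#' model mean. All groups share the gene set and replicate count.
#'
#' @param nGenes number of genes.
#' @param nDeGenes number of genes differentially expressed in model vs
#'   control (0 allowed for null calibration).
#' @param nReplicates replicates per group.
#' @param effectSize log2 shift of DE genes in the model group (0 gives the
#'   global null).
#' @param reversalFraction fraction of the effect removed in reversed genes
#'   (1 restores the control mean exactly).
#' @param reversedPerTreatment fraction of DE genes reversed by each
#'   treatment.
#' @param noiseSd log2-scale residual standard deviation (>= 0).
#' @param treatments character vector of treatment group names.
#' @param baselineMean,baselineSd log2-scale baseline mean distribution.
#' @param seed integer seed.
#' @return list with \code{control}, \code{model} (positive matrices),
#'   \code{treatments} (named list of matrices), \code{truth_de_genes},
#'   \code{truth_de_effect} (signed log2 shifts), \code{truth_reversed}
#'   (named list per treatment) and the generating parameters.
#' @export
simulateTreatmentStudy <- function(nGenes = 2000L, nDeGenes = 100L,
                                   nReplicates = 6L, effectSize = 1,
                                   reversalFraction = 0.8,
                                   reversedPerTreatment = 0.5,
                                   noiseSd = 0.5,
                                   treatments = c("BYF", "BJF", "YZF", "APL"),
                                   baselineMean = 8, baselineSd = 2,
                                   seed = 1L) {
  nGenes <- as.integer(nGenes)
  nDeGenes <- as.integer(nDeGenes)
  nReplicates <- as.integer(nReplicates)
  stopifnot(nGenes >= 1L, nDeGenes >= 0L, nDeGenes <= nGenes,
            nReplicates >= 2L, noiseSd >= 0,
            reversalFraction >= 0, reversalFraction <= 1,
            reversedPerTreatment >= 0, reversedPerTreatment <= 1)
  set.seed(as.integer(seed))
  ids <- .gene_ids(nGenes)
  mu <- rnorm(nGenes, baselineMean, baselineSd)
  names(mu) <- ids
  de_idx <- if (nDeGenes > 0L) sort(sample.int(nGenes, nDeGenes)) else integer()
  delta <- numeric(nGenes)
  delta[de_idx] <- effectSize * sample(c(-1, 1), length(de_idx),
                                       replace = TRUE)
  names(delta) <- ids

  # iid residual noise only: a shared array shift would correlate the genes'
  # test statistics and is irrelevant to the per-gene t contracts here
  draw <- function(m, prefix) {
    logx <- m + matrix(rnorm(nGenes * nReplicates, 0, noiseSd),
                       nGenes, nReplicates)
    dimnames(logx) <- list(ids, sprintf("%s_r%d", prefix, seq_len(nReplicates)))
    2^logx
  }
  control <- draw(mu, "control")
  model <- draw(mu + delta, "model")
  reversed <- list()
  treat <- list()
  for (tr in treatments) {
    rev_idx <- if (length(de_idx))
      sort(sample(de_idx, round(reversedPerTreatment * length(de_idx))))
    else integer()
    mu_tr <- mu + delta
    mu_tr[rev_idx] <- mu[rev_idx] + (1 - reversalFraction) * delta[rev_idx]
    treat[[tr]] <- draw(mu_tr, tr)
    reversed[[tr]] <- ids[rev_idx]
  }
  list(control = control, model = model, treatments = treat,
       truth_de_genes = ids[de_idx], truth_de_effect = delta[de_idx],
       truth_reversed = reversed,
       params = list(nGenes = nGenes, nDeGenes = nDeGenes,
                     nReplicates = nReplicates, effectSize = effectSize,
                     reversalFraction = reversalFraction,
                     reversedPerTreatment = reversedPerTreatment,
                     noiseSd = noiseSd, seed = as.integer(seed)))
}
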