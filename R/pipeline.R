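#' Default pipeline configuration
#'
#' Thresholds and simulation settings of \code{\link{runPipeline}}; any
#' subset can be overridden through the \code{config} argument or a
#' YAML/JSON file.
#'
#' @return named list of defaults.
#' @export
pipelineDefaults <- function() {
  list(
    seed = 1L,
    simulation = list(nGenes = 300L, nPlantedPairs = 50L,
                      nSamplesPerGroup = 30L, logGap = 2, noiseSd = 1,
                      platforms = c(1, 1, 1), distortion = TRUE),
    stability_threshold = 0.9, stability_inclusive = TRUE,
    consistency_threshold = 0.9, consistency_strict = TRUE,
    coverage_floor = 0.5, classification_cutoff = 0.5, fdr = 0.05,
    stage = list(levels = c("moderate", "severe"), n_per_stage = c(30L, 30L),
                 flip_prob = c(0.2, 0.8)))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.write_tsv_with_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' One call that exercises every stage on seeded synthetic cohorts:
#' simulate a multi-platform case/control cohort, build the reversal-pair
#' signature on all but the last platform (the last platform's reference
#' samples serve as the consistency-filter cohort and both of its groups as
#' the held-out evaluation cohort), score the held-out samples, classify
#' and compute the AUC, then simulate a stage cohort and identify
#' stage-correlated signature pairs. Identical config and seed give
#' identical outputs.
#'
#' @param config named list overriding \code{\link{pipelineDefaults}}, or a
#'   path to a YAML/JSON file of overrides.
#' @param outDir optional directory; when given, writes
#'   \code{signature.tsv}, \code{scores.tsv}, \code{stage_pairs.tsv} (all
#'   with '#' metadata headers) and \code{manifest.json} (full config,
#'   seed, package version, stage counts).
#' @return (invisibly) list: \code{config}, \code{signature},
#'   \code{scores} (with \code{label} column), \code{auc},
#'   \code{comparison} (reference vs case score test), \code{stage_pairs},
#'   \code{counts} (per-stage pair bookkeeping).
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
    else yaml::read_yaml(config)
  }
  cfg <- .merge_config(pipelineDefaults(), config)
  if (cfg$coverage_floor <= 0 || cfg$coverage_floor > 1)
    stop("coverage_floor must be in (0, 1]")
  if (length(cfg$simulation$platforms) < 2L)
    stop("need at least 2 platforms (>=1 discovery + 1 filter/evaluation)")

  sim_cfg <- do.call(simConfig, c(cfg$simulation, list(seed = cfg$seed)))
  cohort <- simulateCaseControl(sim_cfg)
  n_plat <- length(cohort$platforms)
  discovery <- cohort$platforms[-n_plat]
  holdout <- cohort$platforms[[n_plat]]

  sig <- buildSignature(discovery, holdout$normal,
                        stabilityThreshold = cfg$stability_threshold,
                        stabilityInclusive = cfg$stability_inclusive,
                        consistencyThreshold = cfg$consistency_threshold,
                        consistencyStrict = cfg$consistency_strict)

  eval_mat <- cbind(holdout$normal, holdout$cancer)
  scores <- scoreCohort(eval_mat, sig, coverageFloor = cfg$coverage_floor)
  truth_label <- rep(c("normal", "cancer"),
                     c(ncol(holdout$normal), ncol(holdout$cancer)))
  scores$label <- classifyScores(scores$score, cfg$classification_cutoff)
  auc <- rocAuc(scores$score, truth_label, positive = "cancer",
                seed = cfg$seed)
  comparison <- compareScoreGroups(
    scores$score[truth_label == "cancer"],
    scores$score[truth_label == "normal"],
    labels = c("cancer", "normal"))

  stage_sim <- simulateStageCohort(
    sim_cfg, stageLevels = cfg$stage$levels,
    nPerStage = cfg$stage$n_per_stage, flipProb = cfg$stage$flip_prob)
  ind <- suppressMessages(reoIndicatorMatrix(stage_sim$matrix, sig))
  stage_pairs <- suppressMessages(
    stageCorrelatedPairs(ind, stage_sim$stages, fdr = cfg$fdr))

  br <- buildReport(sig)
  counts <- list(
    n_reversal_per_platform = vapply(br$platforms, `[[`, 0L, "n_reversal"),
    n_consistent = br$n_consistent,
    n_signature = br$n_signature,
    n_signature_genes = length(signatureGenes(sig)),
    n_stage_significant = sum(stage_pairs$significant))
  message(sprintf(
    "pipeline: reversal per platform [%s] -> consistent %d -> signature %d (%d genes); stage-related %d",
    paste(counts$n_reversal_per_platform, collapse = ", "),
    counts$n_consistent, counts$n_signature, counts$n_signature_genes,
    counts$n_stage_significant))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(package = "reosig",
                 version = as.character(utils::packageVersion("reosig")),
                 seed = cfg$seed)
    writeSignature(sig, file.path(outDir, "signature.tsv"))
    .write_tsv_with_meta(scores, file.path(outDir, "scores.tsv"), meta)
    .write_tsv_with_meta(stage_pairs, file.path(outDir, "stage_pairs.tsv"),
                         meta)
    jsonlite::write_json(
      list(config = cfg, counts = counts, auc = auc$auc,
           comparison_p = comparison$p_value, version = meta$version),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(list(config = cfg, signature = sig, scores = scores, auc = auc,
                 comparison = comparison, stage_pairs = stage_pairs,
                 counts = counts))
}
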