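## End-to-end pipeline orchestration: simulate or load a cohort, compute
## gait features, fit the PCA index, run the correlation analysis and the
## baseline summaries, and write every artifact with a manifest.

#' Run the full gait-variability analysis pipeline
#'
#' Orchestrates the four analysis stages over either a simulated cohort
#' (give `cohort_config`) or existing inputs (give `keypoint_dir` +
#' `cohort_csv`; keypoint files must be named `<subject_id>_test2_<j>.json`).
#' Writes, under `out_dir`: `cohort.csv`, `features.csv` (gait feature
#' vectors with appended PC1/PC2 scores), `pca_loadings.csv`,
#' `pca_summary.csv`, `correlation.csv`, `baseline.csv`,
#' `scores_durations.csv`, a `pipeline.log`, and a `manifest.json` listing
#' every artifact with its MD5 checksum. Outputs carry no timestamps, so a
#' rerun with the same inputs and seed is bit-identical.
#'
#' @param out_dir output directory (created if absent)
#' @param cohort_config a [CohortSimConfig-class] to simulate inputs, or
#'   `NULL` when reading from disk
#' @param keypoint_dir directory of per-trial keypoint JSON files
#' @param cohort_csv path to a cohort table CSV
#' @param min_confidence foot-keypoint confidence threshold
#' @param smooth,f LOWESS settings for the correlation stage
#' @param heatmap logical; also render `correlation_heatmap.png`
#' @return invisible list with the in-memory results (`cohort`, `features`,
#'   `pca`, `correlations`, `baseline`, `scores_durations`) and the
#'   `manifest`
#' @examples
#' \donttest{
#' res <- runPipeline(tempfile("gaitvar"),
#'                    cohort_config = cohortSimConfig(n_subjects = 8, seed = 11))
#' res$manifest$files$name
#' }
#' @export
runPipeline <- function(out_dir,
                        cohort_config = NULL,
                        keypoint_dir = NULL, cohort_csv = NULL,
                        min_confidence = 0.3,
                        smooth = FALSE, f = 0.5,
                        heatmap = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s",
                   stage, conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(cohort_config)) {
    sim <- withStage("simulate", simulateCohort(cohort_config,
                                                min_confidence = min_confidence))
    cohort <- sim$cohort
    features <- sim$features
    note("simulate", sprintf("simulated %d subjects (seed %d)",
                             nrow(cohort), cohort_config@seed))
  } else {
    if (is.null(keypoint_dir) || is.null(cohort_csv))
      stop("supply either cohort_config or both keypoint_dir and cohort_csv",
           call. = FALSE)
    cohort <- withStage("load", utils::read.csv(cohort_csv))
    trials <- withStage("load", .readTrialDir(keypoint_dir, cohort$subject_id))
    features <- withStage("features",
                          gaitFeatures(trials, min_confidence = min_confidence))
    note("load", sprintf("read %d subjects from %s", nrow(cohort), cohort_csv))
  }

  pca <- withStage("pca", fitPCAIndex(features))
  labels <- interpretComponents(pca)
  features$PC1 <- pcaScores(pca)[, 1L]
  features$PC2 <- pcaScores(pca)[, 2L]
  note("pca", sprintf("explained ratios %.4f / %.4f; PC1 '%s', PC2 '%s'",
                      explainedRatio(pca)[1L], explainedRatio(pca)[2L],
                      labels[1L], labels[2L]))

  merged <- merge(cohort, features, by = "subject_id", sort = TRUE)
  cm <- withStage("correlation",
                  correlationMatrix(merged, smooth = smooth, f = f))
  note("correlation", sprintf("%d variables, %d defined pairs",
                              length(cm@variables),
                              sum(!is.na(cm@p_raw[upper.tri(cm@p_raw)]))))

  baseline <- withStage("baseline", summarizeBaseline(cohort))
  sd_sum <- withStage("baseline", summarizeScoresDurations(cohort))

  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    name
  }
  loadings_df <- data.frame(feature = rownames(pcaLoadings(pca)),
                            pcaLoadings(pca))
  pca_summary <- data.frame(
    component = c("PC1", "PC2"),
    explained_ratio = explainedRatio(pca),
    label = unname(labels))
  files <- c(
    wcsv(cohort, "cohort.csv"),
    wcsv(features, "features.csv"),
    wcsv(loadings_df, "pca_loadings.csv"),
    wcsv(pca_summary, "pca_summary.csv"),
    wcsv(exportCorrelations(cm), "correlation.csv"),
    wcsv(baseline, "baseline.csv"),
    wcsv(sd_sum$per_trial, "scores_durations.csv"))
  if (heatmap) {
    plotCorrelationHeatmap(cm, file = file.path(out_dir, "correlation_heatmap.png"))
    files <- c(files, "correlation_heatmap.png")
  }

  log_path <- file.path(out_dir, "pipeline.log")
  writeLines(log_lines, log_path)
  files <- c(files, "pipeline.log")

  manifest <- list(
    package = "gaitvar",
    n_subjects = nrow(cohort),
    seed = if (!is.null(cohort_config)) cohort_config@seed else NA,
    files = data.frame(
      name = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, features = features, pca = pca,
                 correlations = cm, baseline = baseline,
                 scores_durations = sd_sum, manifest = manifest,
                 out_dir = out_dir))
}

## Read `<subject>_test2_<j>.json` trial files for the given subjects.
.readTrialDir <- function(dir, subject_ids) {
  trials <- list()
  for (sid in as.character(subject_ids)) {
    tr <- list()
    for (j in 1:2) {
      path <- file.path(dir, sprintf("%s_test2_%d.json", sid, j))
      if (file.exists(path)) tr[[paste0("test2_", j)]] <- readKeypointJSON(path)
    }
    trials[[sid]] <- tr
  }
  trials
}

#' Write a simulated cohort to disk as pipeline-ready inputs
#'
#' Materializes a simulated cohort the way a capture session would: one
#' canonical keypoint JSON per trial (named `<subject>_test2_<j>.json`) plus
#' the cohort CSV.
#'
#' @param config a [CohortSimConfig-class]
#' @param dir output directory (created if absent)
#' @return invisible character vector of the written file paths
#' @seealso [runPipeline()]
#' @export
writeSimulatedCohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateCohort(config, keep_trials = TRUE)
  paths <- character()
  for (sid in names(sim$trials)) {
    for (tname in names(sim$trials[[sid]])) {
      p <- file.path(dir, sprintf("%s_%s.json", sid, tname))
      writeKeypointJSON(sim$trials[[sid]][[tname]], p)
      paths <- c(paths, p)
    }
  }
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(sim$cohort, csv, row.names = FALSE)
  invisible(c(paths, csv))
}
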