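#' Run the full synthetic-to-evaluation pipeline
#'
#' Executes, in order: cohort simulation (or reading a user-supplied cohort
#' directory in the documented CSV/JSON dialect), per-subject preprocessing,
#' channel selection, windowing and feature extraction, pooled Pearson
#' association, and nested LOSO model evaluation. Writes the channel-stats,
#' association and evaluation tables plus a run manifest with content
#' hashes, and returns everything invisibly.
#'
#' @param config an [fnirs_config()]; ignored when `cohort_dir` is given.
#' @param outdir output directory.
#' @param cohort_dir optional directory with a serialized cohort.
#' @param params preprocessing parameters; the pipeline default keeps slow
#'   trends (`band = c(0, 0.1)`) and references OD to the fasting baseline.
#' @param window_s feature window length, s.
#' @param ttest_window_s window length for the channel-selection t-test, s.
#' @param reducers,models,d_values evaluation grid (see [run_evaluation()]).
#' @param alpha channel-selection significance level.
#' @param seed root seed; overrides `config$rng_seed` when given.
#' @param write_cohort_files also serialize the simulated cohort (large).
#' @return invisible list with `cohort`, `hemo`, `channel_stats`,
#'   `selected_channels`, `features`, `association`, `evaluation`,
#'   `baseline`, `manifest`.
#' @export
run_pipeline <- function(config = fnirs_config(), outdir = tempfile("fnirs_run_"),
                         cohort_dir = NULL, params = preprocess_params(),
                         window_s = config$glucose_sample_interval,
                         ttest_window_s = 60,
                         reducers = c("drpca", "pca"), models = "knn",
                         d_values = 1:6, alpha = 0.05, seed = NULL,
                         write_cohort_files = FALSE) {
  t_start <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  if (!is.null(seed)) {
    cfgl <- unclass(config); cfgl$rng_seed <- as.integer(seed)
    config <- do.call(fnirs_config, cfgl)
  }
  cohort <- if (is.null(cohort_dir))
    stage("simulate", generate_cohort(config))
  else
    stage("read_cohort", read_cohort(cohort_dir))
  config <- cohort$config

  hemo <- stage("preprocess", lapply(cohort$subjects, preprocess_subject,
                                     params = params, optics = cohort$optics))
  stats_tbl <- stage("channel_selection",
                     channel_state_stats(hemo, window_s = ttest_window_s,
                                         alpha = alpha))
  selected <- select_channels(stats_tbl, alpha = alpha)
  if (length(selected) == 0) {
    warning("no significant channels; falling back to all channels",
            call. = FALSE)
    selected <- seq_len(config$n_channels)
  }
  features <- stage("features", {
    wins <- lapply(seq_along(cohort$subjects), function(i)
      segment_windows(hemo[[i]], selected, window_s,
                      cohort$subjects[[i]]$glucose_refs,
                      subject_id = cohort$subjects[[i]]$subject_id))
    feature_table(do.call(c, wins))
  })
  assoc <- stage("association", association_table(features))
  evaluation <- stage("evaluate",
                      run_evaluation(features, reducers = reducers,
                                     models = models, d_values = d_values,
                                     seed = config$rng_seed))
  baseline <- baseline_metrics(features)

  paths <- c(channel_stats = file.path(outdir, "channel_stats.csv"),
             association = file.path(outdir, "association.csv"),
             evaluation = file.path(outdir, "evaluation.csv"),
             features = file.path(outdir, "features.csv"),
             predictions = file.path(outdir, "fold_predictions.csv"))
  utils::write.csv(stats_tbl, paths["channel_stats"], row.names = FALSE)
  utils::write.csv(assoc, paths["association"], row.names = FALSE)
  utils::write.csv(evaluation$results, paths["evaluation"], row.names = FALSE)
  utils::write.csv(features, paths["features"], row.names = FALSE)
  all_folds <- do.call(rbind, lapply(names(evaluation$folds), function(nm)
    cbind(cell = nm, evaluation$folds[[nm]])))
  utils::write.csv(all_folds, paths["predictions"], row.names = FALSE)
  if (write_cohort_files)
    paths <- c(paths, cohort = write_cohort(cohort, file.path(outdir, "cohort"))[1])

  manifest <- list(
    package_version = as.character(utils::packageVersion("fnirsglucose")),
    seed = config$rng_seed,
    config = unclass(config),
    selected_channels = selected,
    n_windows = nrow(features),
    stage_timings_s = as.list(timings),
    total_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    files = lapply(as.list(paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(cohort = cohort, hemo = hemo, channel_stats = stats_tbl,
                 selected_channels = selected, features = features,
                 association = assoc, evaluation = evaluation,
                 baseline = baseline, manifest = manifest,
                 outdir = outdir))
}
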