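#' Features for one simulated patient-week
#'
#' Convenience chain used by the drivers and tests: simulate each movement
#' session, apply notch and bandpass, extract guard-trimmed contraction
#' epochs, window them, and build the labelled feature table.
#'
#' @param profile Patient profile from [make_cohort()].
#' @param week Assessment week.
#' @param protocol An [acquisition_protocol()].
#' @param pre_cfg A [preprocess_config()].
#' @param spec A [feature_spec()].
#' @param movements Movement subset (default: all in the protocol).
#' @param guard_ms Epoch guard trim (ms).
#' @return A `feature_table`.
#' @export
patient_week_features <- function(profile, week,
                                  protocol = acquisition_protocol(),
                                  pre_cfg = preprocess_config(),
                                  spec = feature_spec(),
                                  movements = protocol$movements,
                                  guard_ms = 250) {
  wsets <- list()
  for (m in movements) {
    rec <- simulate_emg_session(profile, week, m, protocol)
    rec <- apply_bandpass(apply_notch(rec, pre_cfg), pre_cfg)
    for (ep in extract_epochs(rec, protocol, guard_ms))
      wsets[[length(wsets) + 1]] <- make_windows(ep, pre_cfg)
  }
  build_feature_table(wsets, spec)
}

#' Feature table from an on-disk dataset
#'
#' Reads every EMG file listed in a dataset manifest, preprocesses it and
#' builds one combined feature table.
#'
#' @param dataset_dir Directory holding `manifest.json` and the files.
#' @param protocol,pre_cfg,spec,guard_ms As in [patient_week_features()].
#' @return A `feature_table`.
#' @export
dataset_features <- function(dataset_dir, protocol = acquisition_protocol(),
                             pre_cfg = preprocess_config(),
                             spec = feature_spec(), guard_ms = 250) {
  manifest <- read_manifest(dataset_dir)
  f <- manifest$files
  emg <- f$path[f$role == "emg"]
  wsets <- list()
  for (path in emg) {
    rec <- read_emg(file.path(dataset_dir, path),
                    file.path(dataset_dir, sub("\\.csv$", ".json", path)))
    rec <- apply_bandpass(apply_notch(rec, pre_cfg), pre_cfg)
    for (ep in extract_epochs(rec, protocol, guard_ms))
      wsets[[length(wsets) + 1]] <- make_windows(ep, pre_cfg)
  }
  build_feature_table(wsets, spec)
}

#' Cross-validated accuracies for every patient-week in a feature table
#'
#' @param tab A `feature_table` (any number of patient-weeks).
#' @param classifiers List of [classifier_spec()]s.
#' @param cv A [cv_spec()].
#' @return data.frame as from [reports_df()].
#' @export
cohort_accuracy <- function(tab,
                            classifiers = list(classifier_spec("knn"),
                                               classifier_spec("random_forest"),
                                               classifier_spec("svm")),
                            cv = cv_spec(folds = 3)) {
  cells <- split(tab, list(tab$patient_id, tab$week), drop = TRUE)
  reports <- list()
  for (cell in cells) for (clf in classifiers)
    reports[[length(reports) + 1]] <- crossval_accuracy(cell, clf, cv)
  reports_df(reports)
}

#' Full run configuration
#'
#' Bundles every stage's configuration plus the master seed. The config
#' hash (MD5 of the canonical JSON form) is embedded in every persisted
#' artifact so that intermediates from different configurations are never
#' mixed.
#'
#' @param cohort A [cohort_config()].
#' @param preprocess A [preprocess_config()].
#' @param features A [feature_spec()].
#' @param classifiers List of [classifier_spec()]s.
#' @param cv A [cv_spec()] (3 folds by default: the default protocol has
#'   3 repetitions per movement and folds are repetition-grouped).
#' @param stats A [stats_config()].
#' @param mcid An [mcid_thresholds()].
#' @param guard_ms Epoch guard trim (ms).
#' @param weeks,movements Optional scaled-down subsets.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       preprocess = preprocess_config(),
                       features = feature_spec(),
                       classifiers = list(classifier_spec("knn"),
                                          classifier_spec("random_forest"),
                                          classifier_spec("svm")),
                       cv = cv_spec(folds = 3),
                       stats = stats_config(),
                       mcid = mcid_thresholds(),
                       guard_ms = 250,
                       weeks = cohort$weeks,
                       movements = cohort$protocol$movements) {
  structure(list(cohort = cohort, preprocess = preprocess,
                 features = features, classifiers = classifiers, cv = cv,
                 stats = stats, mcid = mcid, guard_ms = guard_ms,
                 weeks = weeks, movements = movements),
            class = "run_config")
}

#' MD5 hash of a configuration
#' @param config A [run_config()] (or any serialisable list).
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_done <- function(out_dir, stage, hash) {
  sf <- file.path(out_dir, paste0(".", stage, ".json"))
  if (!file.exists(sf)) return(FALSE)
  st <- jsonlite::read_json(sf)
  if (!identical(st$config_hash, hash))
    stop_config("stage '", stage, "' intermediates were produced under a ",
                "different configuration (hash mismatch); refusing to mix")
  TRUE
}

mark_stage <- function(out_dir, stage, hash, n_records) {
  jsonlite::write_json(list(stage = stage, config_hash = hash,
                            n_records = n_records,
                            wall_s = NA),
                       file.path(out_dir, paste0(".", stage, ".json")),
                       auto_unbox = TRUE)
}

#' Run the full assessment pipeline
#'
#' Executes simulate -> preprocess/features -> classify -> correlate ->
#' clinical -> report, persisting each stage's product under `out_dir`
#' (dataset/, features.csv, accuracy.csv, correlations.csv,
#' progression.csv, classifier_summary.csv, outcomes.csv, bundle.json).
#' Stages are idempotent: a stage whose output exists under the same
#' config hash is skipped, so a run can resume after deleted
#' intermediates; artifacts from a different hash are refused.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage messages.
#' @return The report bundle (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  counts <- list()
  tic <- function() proc.time()[["elapsed"]]

  cohort <- make_cohort(config$cohort)
  protocol <- config$cohort$protocol

  ds_dir <- file.path(out_dir, "dataset")
  t0 <- tic()
  if (!stage_done(out_dir, "simulate", hash)) {
    manifest <- generate_dataset(cohort, protocol, ds_dir,
                                 weeks = config$weeks,
                                 movements = config$movements)
    mark_stage(out_dir, "simulate", hash, manifest$n_files)
  }
  manifest <- read_manifest(ds_dir)
  counts$files <- manifest$n_files
  timings$simulate <- tic() - t0
  say("[simulate] %d files (%.1fs)", counts$files, timings$simulate)

  feat_path <- file.path(out_dir, "features.csv")
  t0 <- tic()
  if (!stage_done(out_dir, "features", hash)) {
    tab <- dataset_features(ds_dir, protocol, config$preprocess,
                            config$features, config$guard_ms)
    write_feature_table(tab, feat_path)
    mark_stage(out_dir, "features", hash, nrow(tab))
  }
  tab <- read_feature_table(feat_path)
  counts$windows <- nrow(tab)
  n_rec <- length(unique(paste(tab$patient_id, tab$week, tab$movement)))
  if (n_rec != sum(manifest$files$role == "emg"))
    stop_data("record-count mismatch between dataset (",
              sum(manifest$files$role == "emg"), " recordings) and feature ",
              "table (", n_rec, "): records were dropped")
  timings$features <- tic() - t0
  say("[features] %d windows (%.1fs)", counts$windows, timings$features)

  acc_path <- file.path(out_dir, "accuracy.csv")
  t0 <- tic()
  if (!stage_done(out_dir, "classify", hash)) {
    acc <- cohort_accuracy(tab, config$classifiers, config$cv)
    write.csv(acc, acc_path, row.names = FALSE)
    mark_stage(out_dir, "classify", hash, nrow(acc))
  }
  acc <- read.csv(acc_path)
  counts$reports <- nrow(acc)
  timings$classify <- tic() - t0
  say("[classify] %d reports (%.1fs)", counts$reports, timings$classify)

  clin <- read_clinical(file.path(ds_dir, "clinical_scores.csv"))
  t0 <- tic()
  corr <- correlation_table(tab, clin,
                            weeks = intersect(c(0, 6, 9), config$weeks),
                            cfg = config$stats)
  write.csv(corr, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  timings$correlate <- tic() - t0

  t0 <- tic()
  outc <- outcome_summary(clin, config$mcid, config$stats)
  write.csv(outc, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  summ <- classifier_mean_summary(acc)
  write.csv(summ, file.path(out_dir, "classifier_summary.csv"),
            row.names = FALSE)
  prog <- if (length(config$weeks) >= 2) progression_table(acc) else NULL
  if (!is.null(prog))
    write.csv(prog, file.path(out_dir, "progression.csv"), row.names = FALSE)
  timings$clinical <- tic() - t0

  bundle <- list(config_hash = hash, seed = config$cohort$seed,
                 counts = counts, timings = timings,
                 classifier_summary = summ, outcomes = outc,
                 progression = prog)
  jsonlite::write_json(bundle, file.path(out_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("[report] bundle written (%s)", file.path(out_dir, "bundle.json"))
  invisible(bundle)
}
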