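#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's settings. A run is a pure function of its config:
#' all stochastic stages draw from sub-streams of `seed` (via
#' [derive_seed()]), so the same config produces bit-identical artifacts.
#'
#' @param subjects list of [subject_spec()] objects to synthesize, or
#'   `NULL` when loading from `dataset_dir`.
#' @param dataset_dir directory written by [write_dataset()]; ignored when
#'   `subjects` is given.
#' @param filter a [filter_spec()].
#' @param estimator an [estimator_spec()].
#' @param window_length_s analysis window length in seconds.
#' @param band analysis band in Hz.
#' @param alpha significance level for the predictability map.
#' @param aggregate channel aggregation for the global ANOVA.
#' @param mlp an [mlp_config()].
#' @param train_features features to train classifiers on.
#' @param split_fractions train/validation/test fractions.
#' @param out_dir output directory for artifacts.
#' @param seed global seed.
#' @param write_heatmaps also emit PNG heatmaps of the predictability map.
#' @return an object of class `run_config`.
#' @export
run_config <- function(subjects = NULL, dataset_dir = NULL,
                       filter = filter_spec(), estimator = estimator_spec(),
                       window_length_s = 30, band = c(0.5, 180),
                       alpha = 0.05, aggregate = "mean",
                       mlp = mlp_config(),
                       train_features = c("mave", "p1", "p2"),
                       split_fractions = c(0.4, 0.3, 0.3),
                       out_dir = tempfile("preictal_run_"),
                       seed = 1L, write_heatmaps = FALSE) {
  if (is.null(subjects) && is.null(dataset_dir)) {
    stop_param("provide subjects to synthesize or a dataset_dir to load")
  }
  if (!is.null(subjects)) {
    if (inherits(subjects, "subject_spec")) subjects <- list(subjects)
    stopifnot(all(vapply(subjects, inherits, TRUE, "subject_spec")))
  }
  if (2 * band[2L] >= min_fs_of(subjects, dataset_dir)) {
    stop_param("band_high (%g Hz) must lie below half the sampling rate",
               band[2L])
  }
  structure(
    list(subjects = subjects, dataset_dir = dataset_dir, filter = filter,
         estimator = estimator, window_length_s = window_length_s,
         band = band, alpha = alpha, aggregate = aggregate, mlp = mlp,
         train_features = train_features,
         split_fractions = split_fractions,
         out_dir = out_dir, seed = as.integer(seed),
         write_heatmaps = isTRUE(write_heatmaps)),
    class = "run_config"
  )
}

min_fs_of <- function(subjects, dataset_dir) {
  if (!is.null(subjects)) {
    min(vapply(subjects, `[[`, numeric(1), "fs"))
  } else {
    Inf  # checked against the loaded data at run time
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_with("preictal_stage_error", "pipeline stage '%s' failed: %s",
              name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Synthesize or load the dataset, extract bispectral features, run the
#' global ANOVA and the per-seizure Mann-Whitney tests, build the
#' predictability map, train one MLP per subject and feature under a
#' seizure-wise split, and write every artifact plus a `MANIFEST.json`
#' with SHA-256 checksums to the output directory. Identical config and
#' seed reproduce identical artifacts; on a stage failure the error names
#' the stage and partial outputs are preserved.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the output directory, the feature
#'   table, test tables, the predictability map and the training reports.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_param("config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(fmt, ...) message(sprintf(paste0("[preictal] ", fmt), ...))

  records <- run_stage("data", {
    if (!is.null(config$subjects)) {
      unlist(lapply(config$subjects, generate_subject), recursive = FALSE)
    } else {
      read_dataset(config$dataset_dir)
    }
  })
  fs <- records[[1L]]$fs
  if (2 * config$band[2L] >= fs) {
    stop_with("preictal_stage_error",
              "pipeline stage 'preprocess' failed: band_high %g Hz at fs %g Hz",
              config$band[2L], fs)
  }
  log_line("data: %d seizure records, %d channels, fs=%g Hz",
           length(records), nrow(records[[1L]]$preictal), fs)

  features <- run_stage("features", {
    extract_features_dataset(records, config$filter, config$estimator,
                             config$window_length_s, config$band)
  })
  log_line("features: %d rows (%d windows x channels)", nrow(features),
           nrow(unique(features[c("subject_id", "seizure_id", "state",
                                  "window_index")])))
  feat_path <- file.path(config$out_dir, "features.csv")
  write_feature_csv(features, config, feat_path)

  anova_tab <- run_stage("stats", {
    global_anova(features, aggregate = config$aggregate)
  })
  mwu_tab <- run_stage("stats", per_seizure_tests(features))
  pmap <- run_stage("stats", predictability_map(mwu_tab, config$alpha))
  write.csv(anova_tab, file.path(config$out_dir, "anova_results.csv"),
            row.names = FALSE)
  write.csv(mwu_tab, file.path(config$out_dir, "mwu_results.csv"),
            row.names = FALSE)
  write.csv(pmap, file.path(config$out_dir, "predictability_map.csv"),
            row.names = FALSE)
  if (config$write_heatmaps) {
    for (sid in unique(pmap$subject_id)) {
      plot_predictability_map(
        pmap, sid, file.path(config$out_dir,
                             sprintf("predictability_map_%s.png", sid))
      )
    }
  }
  log_line("stats: %d ANOVA rows, %d MWU tests", nrow(anova_tab), nrow(mwu_tab))

  reports <- run_stage("classifier", {
    out <- list()
    for (sid in unique(features$subject_id)) {
      sub <- features[features$subject_id == sid, , drop = FALSE]
      plan <- split_by_seizure(sort(unique(sub$seizure_id)),
                               config$split_fractions,
                               seed = derive_seed(config$seed, "split", sid))
      for (f in config$train_features) {
        cfg <- config$mlp
        cfg$seed <- derive_seed(config$seed, "mlp", sid, f)
        fit <- train_mlp(sub, plan, f, cfg)
        tag <- sprintf("%s_%s", sid, f)
        write_mlp_model(fit$model,
                        file.path(config$out_dir, sprintf("model_%s.json", tag)))
        rep_small <- fit$report
        rep_small$confusion <- as.data.frame(rep_small$confusion)
        jsonlite::write_json(
          rep_small,
          file.path(config$out_dir, sprintf("training_report_%s.json", tag)),
          auto_unbox = TRUE, digits = NA, force = TRUE
        )
        out[[tag]] <- fit$report
        log_line("classifier %s/%s: test acc %.3f (checkpoint epoch %d)",
                 sid, f, fit$report$test_accuracy,
                 fit$report$selected_checkpoint_epoch)
      }
    }
    out
  })

  manifest <- run_stage("manifest", {
    arts <- setdiff(list.files(config$out_dir), "MANIFEST.json")
    list(
      artifacts = lapply(arts, function(a) {
        list(file = a,
             sha256 = digest::digest(file.path(config$out_dir, a),
                                     algo = "sha256", file = TRUE))
      }),
      seed = config$seed
    )
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("run complete: %s", config$out_dir)

  invisible(list(out_dir = config$out_dir, features = features,
                 anova = anova_tab, mwu = mwu_tab, predictability = pmap,
                 reports = reports))
}

# Tidy CSV with a header comment block recording the run configuration.
write_feature_csv <- function(features, config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# preictal feature table",
    sprintf("# estimator: seg_len=%d taper=%s overlap=%g mean_subtract=%s",
            config$estimator$seg_len, config$estimator$taper,
            config$estimator$overlap_fraction,
            config$estimator$mean_subtract),
    sprintf("# filter: notch=%g Hz (Q=%g), band=[%g, %g] Hz, order=%d",
            config$filter$notch_freq, config$filter$notch_q,
            config$filter$band_low, config$filter$band_high,
            config$filter$bp_order),
    sprintf("# window: %g s non-overlapping", config$window_length_s)
  ), con)
  write.csv(features, con, row.names = FALSE)
  invisible(path)
}
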