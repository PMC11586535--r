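# End-to-end workflow: configuration, spectrogram batching, pretraining,
# nested evaluation, metric pooling, and the staging report.

#' Default run configuration
#'
#' Nested sections for every pipeline stage, with a single global seed from
#' which each stage derives its own sub-seed.  The defaults describe a
#' small demonstration run.
#'
#' @param seed Global seed.
#' @return A nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthesis = list(n_dogs = 60, duration = 15, sample_rate = 4000,
                     ambient_noise_rms = 0.02),
    features = list(window_length = 200, hop_length = 80, fft_size = 256,
                    frequency_min = 20, frequency_max = 800),
    model = list(hidden_size = 24, num_layers = 1, learning_rate = 3e-3,
                 batch_size = 32, max_epochs = 12,
                 early_stopping_patience = 4, time_pool = 6),
    pretrain = list(n_dogs = 40, max_epochs = 12),
    evaluation = list(n_repeats = 3, n_bootstrap = 100, ci_level = 0.95,
                      folds = 5),
    staging = list(threshold = 0.5)
  )
}

.KNOWN_CONFIG_KEYS <- list(
  top = c("seed", "synthesis", "features", "model", "pretrain",
          "evaluation", "staging"),
  synthesis = c("n_dogs", "duration", "sample_rate", "ambient_noise_rms"),
  features = c("window_length", "hop_length", "fft_size", "frequency_min",
               "frequency_max"),
  model = c("hidden_size", "num_layers", "learning_rate", "batch_size",
            "max_epochs", "early_stopping_patience", "time_pool"),
  pretrain = c("n_dogs", "max_epochs"),
  evaluation = c("n_repeats", "n_bootstrap", "ci_level", "folds"),
  staging = c("threshold"))

#' Validate a run configuration
#'
#' Unknown keys are rejected with their location; stage parameters are
#' range-checked before any compute starts.
#'
#' @param config Nested configuration list (see [default_run_config()]).
#' @return The validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  check_keys <- function(x, section) {
    known <- .KNOWN_CONFIG_KEYS[[section]]
    unknown <- setdiff(names(x), known)
    if (length(unknown) > 0) {
      where <- if (section == "top") "top level" else paste0("section '",
                                                            section, "'")
      stop("unknown configuration key(s) at ", where, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  check_keys(config, "top")
  for (s in intersect(names(config), names(.KNOWN_CONFIG_KEYS))) {
    if (s != "top") check_keys(config[[s]], s)
  }
  if (config$evaluation$n_repeats < 1) {
    stop("evaluation n_repeats must be >= 1")
  }
  if (config$synthesis$n_dogs < 1) stop("synthesis n_dogs must be >= 1")
  invisible(config)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_run_config` returns the validated configuration.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.features_config <- function(fc) {
  spectrogram_config(window_length = fc$window_length,
                     hop_length = fc$hop_length, fft_size = fc$fft_size,
                     frequency_range = c(fc$frequency_min,
                                         fc$frequency_max))
}

#' Compute spectrograms for every recording of a cohort
#'
#' @param cohort_obj A `pcg_cohort`.
#' @param spec_config A [spectrogram_config()].
#' @return Named list of `pcg_spectrogram`, names matching the recording
#'   ids.
#' @export
cohort_spectrograms <- function(cohort_obj,
                                spec_config = spectrogram_config()) {
  lapply(cohort_obj$recordings, compute_log_spectrogram,
         config = spec_config)
}

#' Pretrain a base model on a dedicated synthetic binary cohort
#'
#' Generates an independent synthetic cohort, labels each recording as
#' murmur-present or murmur-absent, and pretrains the 2-class base model on
#' it.  This is the fixed starting point for every fine-tuning repeat.
#'
#' @param config Run configuration (see [default_run_config()]).
#' @return The pretrained 2-class `murmur_model`.
#' @export
pretrain_base_model <- function(config = default_run_config()) {
  validate_run_config(config)
  sc <- .features_config(config$features)
  co <- synthesize_cohort(config$pretrain$n_dogs,
                          seed = derive_seed(config$seed, "pretrain"),
                          duration = config$synthesis$duration,
                          sample_rate = config$synthesis$sample_rate,
                          ambient_noise_rms =
                            config$synthesis$ambient_noise_rms)
  specs <- cohort_spectrograms(co, sc)
  labels <- cohort_recording_labels(co$cohort)
  y <- as.integer(labels$grade[match(names(specs),
                                     labels$recording_id)] != "none")
  mc <- model_config(hidden_size = config$model$hidden_size,
                     num_layers = config$model$num_layers,
                     learning_rate = config$model$learning_rate,
                     batch_size = config$model$batch_size,
                     max_epochs = config$pretrain$max_epochs,
                     early_stopping_patience =
                       config$model$early_stopping_patience,
                     time_pool = config$model$time_pool,
                     seed = derive_seed(config$seed, "init"))
  base <- build_base_model(ncol(specs[[1]]$values), mc, 2L)
  surrogate_pretrain(base, specs, y)
}

#' Run the full pipeline
#'
#' Synthesizes a cohort, pretrains the base model on an independent
#' synthetic binary set, runs the repeated split/fine-tune/evaluate
#' protocol, pools grading and murmur-detection metrics with bootstrap
#' intervals, and writes the staging report.  Re-running with the same
#' configuration reproduces all outputs.
#'
#' @param config Run configuration (see [default_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.  Artifacts: `cohort.csv`,
#'   `predictions.csv`, `metrics.json`, `roc_summary.csv`, `staging.csv`,
#'   `log.txt`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    cat(sprintf(...), "\n", file = logf, append = TRUE, sep = "")
  }
  cat("", file = logf)
  run_stage <- function(stage, expr) {
    log_line("stage=%s seed=%d", stage, derive_seed(config$seed, stage))
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed (seed ",
           derive_seed(config$seed, stage), "): ",
           conditionMessage(e))
    })
  }

  co <- run_stage("synth", synthesize_cohort(
    config$synthesis$n_dogs, seed = derive_seed(config$seed, "synth"),
    duration = config$synthesis$duration,
    sample_rate = config$synthesis$sample_rate,
    ambient_noise_rms = config$synthesis$ambient_noise_rms))
  write_cohort(co$cohort, file.path(out_dir, "cohort.csv"))
  log_line("stage=synth dogs=%d recordings=%d", nrow(co$cohort),
           length(co$recordings))

  sc <- .features_config(config$features)
  specs <- run_stage("features", cohort_spectrograms(co, sc))
  base <- run_stage("pretrain", pretrain_base_model(config))
  labels <- cohort_recording_labels(co$cohort)
  ec <- evaluation_config(n_repeats = config$evaluation$n_repeats,
                          n_bootstrap = config$evaluation$n_bootstrap,
                          ci_level = config$evaluation$ci_level,
                          seed = derive_seed(config$seed, "evaluation"))
  runs <- run_stage("evaluation", nested_repeated_evaluation(
    co$cohort, specs, labels, base, ec, k = config$evaluation$folds))

  preds <- do.call(rbind, lapply(runs, function(r) {
    cbind(repeat_index = r$repeat_index, r$predictions)
  }))
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  gm <- grading_metrics(preds$predicted_grade, preds$expert_grade)
  curves <- lapply(runs, function(r) {
    pr <- r$predictions
    roc_curve(binary_murmur_probability(
      as.matrix(pr[, grade_levels()])), pr$expert_grade != "none")
  })
  rs <- vertical_average(curves, ci_level = config$evaluation$ci_level)
  acc_ci <- bootstrap_ci(function(ids) {
    sel <- preds$patient_id %in% ids
    mean(preds$predicted_grade[sel] == preds$expert_grade[sel])
  }, preds$patient_id, config$evaluation$n_bootstrap,
  config$evaluation$ci_level, seed = derive_seed(config$seed, "boot"))
  metrics <- list(
    grading_accuracy = gm$accuracy,
    grading_accuracy_ci = c(acc_ci$lower, acc_ci$upper),
    grading_within_one = gm$within_one,
    murmur_auc_mean = rs$auc_mean,
    murmur_auc_ci = rs$auc_ci)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(fpr = rs$fpr, tpr_mean = rs$tpr_mean,
               tpr_lower = rs$tpr_lower, tpr_upper = rs$tpr_upper),
    file.path(out_dir, "roc_summary.csv"), row.names = FALSE)
  log_line("stage=evaluation repeats=%d recordings_scored=%d",
           length(runs), nrow(preds))

  staging <- run_stage("staging", .staging_report(co$cohort, preds,
                                                  config$staging$threshold))
  utils::write.csv(staging, file.path(out_dir, "staging.csv"),
                   row.names = FALSE)
  n_excl <- sum(staging$partition == "excluded")
  log_line("stage=staging excluded=%d clean=%d confounded=%d", n_excl,
           sum(staging$partition == "clean"),
           sum(staging$partition == "confounded"))
  invisible(out_dir)
}

# Average each patient's out-of-sample left-apex grade distribution over
# repeats and apply the staging layer.
.staging_report <- function(cohort, preds, threshold) {
  part <- partition_preclinical(cohort)
  apex <- preds[preds$site == "left_apex", ]
  score <- rep(NA_real_, nrow(cohort))
  stage_pred <- rep(NA_character_, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rows <- apex[apex$patient_id == cohort$patient_id[i], grade_levels()]
    if (nrow(rows) == 0) next
    dist <- colMeans(as.matrix(rows))
    dist <- dist / sum(dist)
    cls <- classify_b1_b2(dist, threshold)
    score[i] <- cls$score
    stage_pred[i] <- cls$stage
  }
  data.frame(patient_id = cohort$patient_id,
             stage = cohort$mmvd_stage,
             partition = part$partition,
             exclusion_reason = part$exclusion_reason,
             loud_or_greater_score = score,
             predicted_stage = stage_pred,
             stringsAsFactors = FALSE)
}
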