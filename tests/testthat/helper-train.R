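# Shared trained artifacts for the expensive end-to-end checks.  The
# grading ensemble is trained once per test session and reused by every
# test that needs out-of-sample grade predictions.

.train_cache <- new.env(parent = emptyenv())

# Model scale used for the end-to-end experiments: a single bidirectional
# layer of 24 units over 6x-pooled spectrogram frames separates the
# synthetic grades cleanly and fine-tunes in well under a minute per fold
# set on one CPU.
recovery_model_config <- function(seed = 5L) {
  model_config(hidden_size = 24, num_layers = 1, max_epochs = 40,
               early_stopping_patience = 6, learning_rate = 3e-3,
               batch_size = 32, time_pool = 6, seed = seed)
}

# Full parameter-recovery experiment: synthesize a 200-dog cohort, pretrain
# the binary base on an independent 40-dog cohort, minimization-split,
# fine-tune with 5-fold cross-validation on the training arm, and predict
# the held-out arm.  Returns predictions and the trained artifacts.
recovery_experiment <- function(seed = 2024L) {
  key <- paste0("recovery-", seed)
  if (!is.null(.train_cache[[key]])) return(.train_cache[[key]])
  co <- synthesize_cohort(200, seed = derive_seed(seed, "cohort"))
  specs <- cohort_spectrograms(co)
  labs <- cohort_recording_labels(co$cohort)
  ord <- match(names(specs), labs$recording_id)
  grade <- labs$grade[ord]
  pid <- labs$patient_id[ord]

  mc <- recovery_model_config(seed = derive_seed(seed, "model"))
  pco <- synthesize_cohort(40, seed = derive_seed(seed, "pretrain"))
  pspecs <- cohort_spectrograms(pco)
  plabs <- cohort_recording_labels(pco$cohort)
  py <- as.integer(plabs$grade[match(names(pspecs),
                                     plabs$recording_id)] != "none")
  base <- build_base_model(ncol(specs[[1]]$values), mc, 2L)
  pretrained <- surrogate_pretrain(base, pspecs, py)

  split <- minimization_split(co$cohort, seed = derive_seed(seed, "split"))
  arm <- stats::setNames(split$assignment$arm, split$assignment$patient_id)
  tr <- arm[pid] == "train"
  ens <- finetune_crossval(transfer_head_surgery(pretrained, 5L),
                           specs[tr], grade[tr], pid[tr], k = 5,
                           seed = derive_seed(seed, "finetune"))
  probs <- predict_grade(ens, specs[!tr])
  res <- list(cohort = co, pretrained = pretrained, ensemble = ens,
              test_probs = probs, test_grade = grade[!tr],
              test_pid = pid[!tr],
              predicted = grade_levels()[max.col(probs)])
  .train_cache[[key]] <- res
  res
}
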