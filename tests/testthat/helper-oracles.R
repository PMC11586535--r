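# Independent oracles and shared fixtures for the test suite.

# Exhaustive pair-counting AUC: over all positive-negative pairs, a pair
# contributes 1 if the positive scores higher, 1/2 on a tie.  Independent of
# the package's trapezoidal ROC construction.
pair_count_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# A small deterministic spectrogram-like matrix (time x freq)
toy_spec <- function(t = 12, f = 6, seed = 1) {
  set.seed(seed)
  matrix(rnorm(t * f), t, f)
}

# Tiny model config used where only mechanics (not accuracy) are under test
tiny_model_config <- function(seed = 1L, ...) {
  model_config(hidden_size = 6, num_layers = 1, max_epochs = 3,
               early_stopping_patience = 2, batch_size = 8,
               time_pool = 1, seed = seed, ...)
}
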