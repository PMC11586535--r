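# Murmur grading network: construction, surrogate pretraining on a binary
# murmur task, transfer-learning head surgery, cross-validated fine-tuning
# with early stopping, and the prediction/aggregation rules.

#' Model configuration
#'
#' @param hidden_size Hidden units per direction of each GRU layer.
#' @param num_layers Number of stacked bidirectional GRU layers.
#' @param num_output_classes Output classes of the grading head; 5 for the
#'   reduced-grade task (none, soft, moderate, loud, thrilling).
#' @param learning_rate,batch_size,max_epochs Adam optimizer settings.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before training stops (best parameters are restored).
#' @param time_pool Integer factor by which adjacent spectrogram frames are
#'   average-pooled before the recurrent stack (1 = none); shortens
#'   sequences without changing the band-energy information the grading
#'   task depends on.
#' @param bidirectional Logical; the grading network is bidirectional.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_size = 64, num_layers = 2,
                         num_output_classes = 5, learning_rate = 1e-3,
                         batch_size = 32, max_epochs = 30,
                         early_stopping_patience = 10, time_pool = 1,
                         bidirectional = TRUE, seed = 1L) {
  stopifnot(hidden_size > 0, num_layers > 0, num_output_classes > 0,
            learning_rate > 0, batch_size > 0, max_epochs >= 1,
            time_pool >= 1, isTRUE(bidirectional))
  structure(list(recurrent_cell = "gru", bidirectional = TRUE,
                 hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers),
                 num_output_classes = as.integer(num_output_classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 time_pool = as.integer(time_pool),
                 seed = as.integer(seed)),
            class = "model_config")
}

.init_dir <- function(input_dim, hidden) {
  k <- 1 / sqrt(hidden)
  ru <- function(r, c) matrix(stats::runif(r * c, -k, k), r, c)
  list(Wi = ru(3 * hidden, input_dim), Wh = ru(3 * hidden, hidden),
       bi = stats::runif(3 * hidden, -k, k),
       bh = stats::runif(3 * hidden, -k, k))
}

#' Build a freshly initialized GRU grading model
#'
#' Constructs the bidirectional GRU stack with a linear head over the
#' temporal mean of the top layer's outputs.  Initialization is uniform in
#' \[-1/sqrt(H), 1/sqrt(H)\] and fully determined by `config$seed`.  The base
#' (pretraining) model uses a 2-class murmur-present head; the grading head
#' is attached later by [transfer_head_surgery()].
#'
#' @param input_dim Number of frequency bins of the input spectrograms
#'   (after any temporal pooling; pooling does not change the bin count).
#' @param config A [model_config()].
#' @param num_output_classes Head size; defaults to 2 for the binary
#'   murmur-detection base task.
#' @return A `murmur_model`: list with `config`, `input_dim`, `n_classes`,
#'   `params`.
#' @export
build_base_model <- function(input_dim, config = model_config(),
                             num_output_classes = 2L) {
  stopifnot(input_dim > 0, num_output_classes > 0)
  params <- with_seed(config$seed, {
    layers <- lapply(seq_len(config$num_layers), function(l) {
      d <- if (l == 1) input_dim else 2 * config$hidden_size
      list(fwd = .init_dir(d, config$hidden_size),
           bwd = .init_dir(d, config$hidden_size))
    })
    k <- 1 / sqrt(2 * config$hidden_size)
    head <- list(
      W = matrix(stats::runif(num_output_classes * 2 * config$hidden_size,
                              -k, k),
                 num_output_classes, 2 * config$hidden_size),
      b = stats::runif(num_output_classes, -k, k))
    list(layers = layers, head = head)
  })
  structure(list(config = config, input_dim = as.integer(input_dim),
                 n_classes = as.integer(num_output_classes),
                 params = params, trained = FALSE),
            class = "murmur_model")
}

# Stack a list of spectrograms into the (freq x batch x time) array consumed
# by the C++ kernels.  All spectrograms must share dimensions.
.spec_array <- function(specs, time_pool = 1L) {
  vals <- lapply(specs, function(s) {
    v <- if (inherits(s, "pcg_spectrogram")) s$values else s
    pool_time(v, time_pool)
  })
  d <- dim(vals[[1]])
  ok <- vapply(vals, function(v) identical(dim(v), d), logical(1))
  if (!all(ok)) stop("all spectrograms in a batch must share dimensions")
  arr <- array(0, dim = c(d[2], length(vals), d[1]))
  for (i in seq_along(vals)) arr[, i, ] <- t(vals[[i]])
  arr
}

.softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

#' Forward pass: class logits for a list of spectrograms
#'
#' @param model A `murmur_model`.
#' @param specs List of `pcg_spectrogram` (or plain time-by-frequency
#'   matrices).
#' @return Matrix (recordings x classes) of logits.
#' @export
model_logits <- function(model, specs) {
  X <- .spec_array(specs, model$config$time_pool)
  if (dim(X)[1] != model$input_dim) {
    stop("spectrogram has ", dim(X)[1], " frequency bins; model expects ",
         model$input_dim)
  }
  out <- .gru_forward_cpp(model$params$layers, model$params$head$W,
                          model$params$head$b, X)
  out$logits
}

# --- Adam on the nested parameter list ------------------------------------

.map2_params <- function(p, g, f) {
  if (is.list(p)) {
    out <- Map(function(pp, gg) .map2_params(pp, gg, f), p, g)
    return(out)
  }
  f(p, g)
}

.zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, .zeros_like))
  p * 0
}

# One Adam step over the whole parameter tree; returns updated (params, m, v).
.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$m <- .map2_params(state$m, grads, function(m, g) beta1 * m +
                            (1 - beta1) * g)
  state$v <- .map2_params(state$v, grads, function(v, g) beta2 * v +
                            (1 - beta2) * g^2)
  mhat_scale <- 1 / (1 - beta1^t)
  vhat_scale <- 1 / (1 - beta2^t)
  upd <- .map2_params(state$m, state$v, function(m, v) {
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
  })
  params <- .map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# grads from the C++ kernel reshaped to mirror the parameter tree
.grad_tree <- function(out) {
  list(layers = out$layer_grads,
       head = list(W = out$headW, b = as.numeric(out$headb)))
}

.batch_loss <- function(params, X, y) {
  .gru_loss_grad_cpp(params$layers, params$head$W, params$head$b, X,
                     as.integer(y))
}

#' Train a model with Adam and optional early stopping
#'
#' Minibatch Adam on the softmax cross-entropy.  When validation data is
#' supplied, the validation loss is monitored each epoch and training stops
#' after `early_stopping_patience` epochs without improvement; the
#' best-validation parameters are restored.
#'
#' @param model A `murmur_model`.
#' @param specs,labels Training spectrograms and 0-based integer class
#'   labels (or grade labels for the 5-class task).
#' @param val_specs,val_labels Optional held-out data for early stopping.
#' @param seed Seed for batch shuffling (defaults to the model config seed).
#' @return The trained model, with a `history` element (per-epoch train /
#'   validation losses, `best_epoch`, `converged`).
#' @export
train_model <- function(model, specs, labels, val_specs = NULL,
                        val_labels = NULL, seed = NULL) {
  cfg <- model$config
  y <- .as_class_index(labels, model$n_classes)
  X <- .spec_array(specs, cfg$time_pool)
  has_val <- !is.null(val_specs) && length(val_specs) > 0
  if (has_val) {
    Xv <- .spec_array(val_specs, cfg$time_pool)
    yv <- .as_class_index(val_labels, model$n_classes)
  }
  params <- model$params
  state <- list(m = .zeros_like(params), v = .zeros_like(params))
  n <- dim(X)[2]
  tstep <- 0
  train_hist <- val_hist <- numeric(0)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  with_seed(seed %||% cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        out <- .batch_loss(params, X[, idx, , drop = FALSE], y[idx])
        tstep <- tstep + 1
        st <- .adam_step(params, .grad_tree(out), state, cfg$learning_rate,
                         tstep)
        params <- st$params
        state <- st$state
        ep_loss <- ep_loss + out$loss * length(idx)
      }
      train_hist[epoch] <- ep_loss / n
      if (has_val) {
        vout <- .gru_forward_cpp(params$layers, params$head$W,
                                 params$head$b, Xv)
        val_hist[epoch] <- .ce_loss(vout$logits, yv)
        if (val_hist[epoch] < best$loss - 1e-6) {
          best <- list(loss = val_hist[epoch], params = params,
                       epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$early_stopping_patience) break
        }
      }
    }
  })
  if (has_val && is.finite(best$loss)) {
    params <- best$params
  } else {
    best$epoch <- length(train_hist)
  }
  converged <- if (has_val) {
    length(val_hist) > 0 && best$loss <= val_hist[1] + 1e-9
  } else {
    length(train_hist) > 1 && train_hist[length(train_hist)] < train_hist[1]
  }
  if (!converged) {
    warning("training did not reduce the monitored loss within max_epochs")
  }
  model$params <- params
  model$trained <- TRUE
  model$history <- list(train_loss = train_hist, val_loss = val_hist,
                        best_epoch = best$epoch, converged = converged)
  model
}

.ce_loss <- function(logits, y) {
  p <- .softmax_rows(logits)
  -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
}

.as_class_index <- function(labels, n_classes) {
  if (is.numeric(labels)) {
    y <- as.integer(labels)
  } else {
    y <- grade_index(labels)
  }
  if (any(y < 0 | y >= n_classes)) stop("label outside 0..", n_classes - 1)
  y
}

#' Pretrain the base model on a synthetic binary murmur-detection task
#'
#' Stands in for the human-data pretraining stage: the 2-class base model is
#' trained to separate murmur-present from murmur-absent synthetic
#' recordings, giving the recurrent layers murmur-sensitive features that
#' the grading head is later fine-tuned on.  A fraction of the data is held
#' out for early stopping.
#'
#' @param model A 2-class `murmur_model` from [build_base_model()].
#' @param specs Spectrograms of the binary-labeled synthetic set.
#' @param labels Binary labels (0 = no murmur, 1 = murmur).
#' @param val_fraction Fraction of recordings held out for early stopping.
#' @return The pretrained model (with training history; non-convergence is
#'   reported as a warning by [train_model()]).
#' @export
surrogate_pretrain <- function(model, specs, labels, val_fraction = 0.2) {
  stopifnot(model$n_classes == 2L)
  y <- .as_class_index(labels, 2L)
  n <- length(specs)
  idx_val <- with_seed(derive_seed(model$config$seed, "pretrain-val"),
                      sample.int(n, max(1L, round(val_fraction * n))))
  train_model(model, specs[-idx_val], y[-idx_val], specs[idx_val],
              y[idx_val])
}

#' Replace the classification head for transfer to the grading task
#'
#' All recurrent parameters are copied verbatim; the final linear layer is
#' replaced by a zero-initialized head with `num_output_classes` outputs, so
#' that immediately after surgery the model emits the uniform grade
#' distribution for any input.
#'
#' @param model A pretrained `murmur_model`.
#' @param num_output_classes Size of the new head (5 for reduced grades).
#' @return A fine-tunable `murmur_model` with the new head.
#' @export
transfer_head_surgery <- function(model, num_output_classes = 5L) {
  stopifnot(inherits(model, "murmur_model"), num_output_classes > 0)
  h2 <- 2 * model$config$hidden_size
  model$params$head <- list(W = matrix(0, num_output_classes, h2),
                            b = numeric(num_output_classes))
  model$n_classes <- as.integer(num_output_classes)
  model$config$num_output_classes <- as.integer(num_output_classes)
  model$trained <- FALSE
  model$history <- NULL
  model
}

#' Fine-tune with patient-level k-fold cross-validation
#'
#' Patients (not recordings) are partitioned into k folds, stratified by
#' each patient's maximum grade so every fold sees all grade classes.  Each
#' member model trains on k-1 folds with early stopping monitored on its
#' held-out fold.  The k fine-tuned models form the prediction ensemble.
#'
#' @param model A 5-class `murmur_model` (after [transfer_head_surgery()]).
#' @param specs List of spectrograms (one per recording).
#' @param labels Reduced grade per recording (labels or 0-4 integers).
#' @param patient_ids Patient identifier per recording.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and training shuffles.
#' @return A `murmur_ensemble`: list of k trained members plus the fold
#'   assignment.
#' @export
finetune_crossval <- function(model, specs, labels, patient_ids, k = 5,
                              seed = NULL) {
  seed <- seed %||% model$config$seed
  y <- .as_class_index(labels, model$n_classes)
  patients <- unique(patient_ids)
  if (length(patients) < k) stop("fewer patients (", length(patients),
                                 ") than folds (", k, ")")
  pat_max <- vapply(patients, function(p) max(y[patient_ids == p]),
                    integer(1))
  folds <- with_seed(derive_seed(seed, "folds"), {
    f <- integer(length(patients))
    for (g in unique(pat_max)) {
      sel <- which(pat_max == g)
      f[sel] <- sample(rep_len(seq_len(k), length(sel)))
    }
    f
  })
  names(folds) <- patients
  members <- lapply(seq_len(k), function(fold) {
    hold_pat <- patients[folds == fold]
    hold <- patient_ids %in% hold_pat
    train_model(model, specs[!hold], y[!hold], specs[hold], y[hold],
                seed = derive_seed(seed, "fold", fold))
  })
  structure(list(members = members, folds = folds, k = k,
                 config = model$config), class = "murmur_ensemble")
}

#' Predict the grade distribution for recordings
#'
#' The ensemble prediction is the mean of the member models' softmax
#' outputs, a valid probability distribution over the five reduced grades.
#'
#' @param ensemble A `murmur_ensemble` (a single trained `murmur_model` is
#'   also accepted).
#' @param specs List of spectrograms, or a single `pcg_spectrogram`.
#' @return Matrix (recordings x 5) of grade probabilities, columns named by
#'   [grade_levels()].
#' @export
predict_grade <- function(ensemble, specs) {
  if (inherits(specs, "pcg_spectrogram") || is.matrix(specs)) {
    specs <- list(specs)
  }
  members <- if (inherits(ensemble, "murmur_ensemble")) {
    ensemble$members
  } else if (inherits(ensemble, "murmur_model")) {
    if (!isTRUE(ensemble$trained)) stop("model has not been trained")
    list(ensemble)
  } else {
    stop("ensemble must be a murmur_ensemble or trained murmur_model")
  }
  probs <- lapply(members, function(m) .softmax_rows(model_logits(m, specs)))
  out <- Reduce(`+`, probs) / length(probs)
  colnames(out) <- grade_levels()[seq_len(ncol(out))]
  out
}

.check_dist <- function(dist) {
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1)
  if (ncol(dist) != 5) stop("grade distribution must have 5 entries")
  if (any(dist < -1e-9) || any(abs(rowSums(dist) - 1) > 1e-6)) {
    stop("grade distribution entries must be non-negative and sum to 1")
  }
  dist
}

#' Probability that a murmur of any grade is present
#'
#' @param dist Length-5 grade probability vector, or a matrix with one row
#'   per recording.
#' @return `1 - P(none)` per row.
#' @export
binary_murmur_probability <- function(dist) {
  d <- .check_dist(dist)
  unname(1 - d[, 1])
}

#' Probability that the murmur is loud or greater
#'
#' The continuous test variable for B1-vs-B2 staging: the summed predicted
#' probability that the murmur is loud or thrilling.
#'
#' @inheritParams binary_murmur_probability
#' @return `P(loud) + P(thrilling)` per row.
#' @export
loud_or_greater_probability <- function(dist) {
  d <- .check_dist(dist)
  unname(d[, 4] + d[, 5])
}

#' Aggregate per-site grade distributions into a patient-level prediction
#'
#' A murmur is predicted for the patient if any site's predicted grade
#' (argmax of its distribution) is not `"none"`; the maximal-grade site set
#' contains every site attaining the maximum predicted grade (shared maxima
#' are kept).
#'
#' @param site_dists Named list (or 5-column matrix with rownames) of
#'   per-site grade distributions; 1-3 sites.
#' @return List with `site_grades` (named grade labels), `murmur_flag`,
#'   `maximal_sites` (character; empty when no murmur predicted).
#' @export
aggregate_patient <- function(site_dists) {
  if (is.matrix(site_dists)) {
    site_dists <- stats::setNames(
      lapply(seq_len(nrow(site_dists)), function(i) site_dists[i, ]),
      rownames(site_dists))
  }
  if (length(site_dists) < 1) stop("at least one site distribution required")
  grades <- vapply(site_dists, function(d) {
    d <- .check_dist(d)
    grade_levels()[which.max(d)]
  }, character(1))
  gi <- grade_index(grades)
  flag <- any(gi > 0)
  maximal <- if (flag) names(grades)[gi == max(gi)] else character(0)
  list(site_grades = grades, murmur_flag = flag, maximal_sites = maximal)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the format version,
#' the model (or ensemble) configuration, and all parameters.
#'
#' @param model A `murmur_model` or `murmur_ensemble`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("murmur_model", "murmur_ensemble")))
  saveRDS(list(format_version = 1L, class = class(model)[1],
               object = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format_version, 1L)) {
    stop("unsupported checkpoint format version")
  }
  ck$object
}
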