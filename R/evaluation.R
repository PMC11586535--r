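# Evaluation protocol: repeated minimization-split fine-tuning with strictly
# out-of-sample prediction, empirical ROC curves with trapezoidal AUC,
# vertical averaging across curves, percentile bootstrap confidence
# intervals, and the ordinal grading metric suite.

#' Evaluation configuration
#'
#' @param n_repeats Number of independent split/fine-tune/evaluate repeats.
#' @param n_bootstrap Bootstrap iterations per run.
#' @param ci_level Confidence level for percentile intervals.
#' @param seed Global evaluation seed.
#' @return An `evaluation_config` list.
#' @export
evaluation_config <- function(n_repeats = 50, n_bootstrap = 1000,
                              ci_level = 0.95, seed = 1L) {
  stopifnot(n_repeats >= 1, n_bootstrap >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_bootstrap = as.integer(n_bootstrap),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "evaluation_config")
}

#' Nested repeated evaluation
#'
#' For each repeat: a fresh seeded minimization split of the cohort, head
#' surgery from the fixed pretrained base, k-fold fine-tuning on the
#' training arm, and prediction on the test arm only.  No test-arm
#' recording influences any training step of its repeat.
#'
#' @param cohort Cohort data frame (one row per patient).
#' @param specs Named list of spectrograms; names are
#'   `<patient_id>_<site>` recording ids.
#' @param labels Data frame from [cohort_recording_labels()] (recording id,
#'   patient, site, grade).
#' @param pretrained Pretrained 2-class base `murmur_model`.
#' @param eval_config An [evaluation_config()].
#' @param k Folds for fine-tuning within each repeat.
#' @return List of evaluation runs; each has `repeat_index`, `assignment`,
#'   and `predictions` (one row per test-arm recording: probabilities,
#'   predicted and expert grade).
#' @export
nested_repeated_evaluation <- function(cohort, specs, labels, pretrained,
                                       eval_config = evaluation_config(),
                                       k = 5) {
  runs <- vector("list", eval_config$n_repeats)
  for (r in seq_len(eval_config$n_repeats)) {
    rseed <- derive_seed(eval_config$seed, "repeat", r)
    split <- minimization_split(cohort, seed = rseed)
    arm_of <- stats::setNames(split$assignment$arm,
                              split$assignment$patient_id)
    lab <- labels[labels$recording_id %in% names(specs), ]
    train_ids <- lab$recording_id[arm_of[lab$patient_id] == "train"]
    test_ids <- lab$recording_id[arm_of[lab$patient_id] == "test"]
    model <- transfer_head_surgery(pretrained, 5L)
    ens <- finetune_crossval(model, specs[train_ids],
                             lab$grade[match(train_ids, lab$recording_id)],
                             lab$patient_id[match(train_ids,
                                                  lab$recording_id)],
                             k = k, seed = rseed)
    probs <- predict_grade(ens, specs[test_ids])
    ti <- match(test_ids, lab$recording_id)
    runs[[r]] <- list(
      repeat_index = r,
      assignment = split$assignment,
      train_recordings = train_ids,
      predictions = data.frame(
        patient_id = lab$patient_id[ti], site = lab$site[ti],
        recording_id = test_ids, probs,
        predicted_grade = grade_levels()[max.col(probs)],
        expert_grade = lab$grade[ti],
        stringsAsFactors = FALSE))
  }
  runs
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Thresholds sweep the unique score values; tied scores move along the
#' curve together, so the trapezoidal AUC equals the pair-counting AUC with
#' ties contributing 1/2.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (logical, or 0/1).
#' @return A `roc_points` data frame with `fpr`, `tpr`, `threshold` and an
#'   `auc` attribute.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(y) != length(scores)) stop("length mismatch")
  if (length(unique(y)) < 2) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(1 - y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- data.frame(fpr = fpr, tpr = tpr,
                    threshold = c(Inf, s[last]))
  attr(out, "auc") <- auc
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under a ROC curve
#' @param roc A `roc_points` object from [roc_curve()].
#' @return The trapezoidal AUC.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

# linear interpolation of a ROC curve's TPR at given FPRs
.interp_tpr <- function(roc, fpr_grid) {
  stats::approx(roc$fpr, roc$tpr, xout = fpr_grid, ties = max,
                rule = 2)$y
}

#' Vertically average ROC curves
#'
#' At each false-positive rate on the grid, the true-positive rates of the
#' individual curves (linearly interpolated) are averaged and given a
#' percentile confidence band; the AUC summary is the mean and percentile
#' interval of the per-curve AUCs.
#'
#' @param curves List of `roc_points`.
#' @param fpr_grid Grid of false-positive rates (default 101 points).
#' @param ci_level Confidence level for the percentile band.
#' @return A `roc_summary` list: `fpr`, `tpr_mean`, `tpr_lower`,
#'   `tpr_upper`, `auc_mean`, `auc_ci`.
#' @export
vertical_average <- function(curves, fpr_grid = seq(0, 1, length.out = 101),
                             ci_level = 0.95) {
  if (length(curves) == 0) stop("no ROC curves supplied")
  tprs <- vapply(curves, .interp_tpr, numeric(length(fpr_grid)),
                 fpr_grid = fpr_grid)
  tprs <- matrix(tprs, nrow = length(fpr_grid))
  alpha <- (1 - ci_level) / 2
  aucs <- vapply(curves, roc_auc, numeric(1))
  structure(list(
    fpr = fpr_grid,
    tpr_mean = rowMeans(tprs),
    tpr_lower = apply(tprs, 1, stats::quantile, probs = alpha),
    tpr_upper = apply(tprs, 1, stats::quantile, probs = 1 - alpha),
    auc_mean = mean(aucs),
    auc_ci = unname(stats::quantile(aucs, c(alpha, 1 - alpha)))),
    class = "roc_summary")
}

#' Percentile bootstrap confidence interval of a patient-level statistic
#'
#' Patients are resampled with replacement within each run and the statistic
#' recomputed on each resample; the interval is the percentile interval of
#' the pooled draws, making no normality assumption.  Degenerate resamples
#' (statistic `NA`) are redrawn.
#'
#' @param stat_fn Function mapping a vector of patient ids (a resample,
#'   possibly with duplicates) to a single number.
#' @param patient_ids Patient identifiers of one run.
#' @param n_bootstrap Number of bootstrap draws.
#' @param ci_level Confidence level.
#' @param seed Integer seed.
#' @return List `mean`, `lower`, `upper`, `draws`.
#' @export
bootstrap_ci <- function(stat_fn, patient_ids, n_bootstrap = 1000,
                         ci_level = 0.95, seed = 1L) {
  ids <- unique(patient_ids)
  draws <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      for (attempt in 1:100) {
        res <- stat_fn(sample(ids, length(ids), replace = TRUE))
        if (!is.na(res)) return(res)
      }
      stop("bootstrap statistic degenerate in 100 consecutive resamples")
    }, numeric(1))
  })
  alpha <- (1 - ci_level) / 2
  list(mean = mean(draws),
       lower = unname(stats::quantile(draws, alpha)),
       upper = unname(stats::quantile(draws, 1 - alpha)),
       draws = draws)
}

#' Ordinal grading metrics
#'
#' Micro-averaged exact-match accuracy, the proportion of predictions
#' within one grade of the expert label, and the column-normalized 5x5
#' confusion matrix (columns = expert grade; each non-empty column sums
#' to 1).
#'
#' @param predicted,expert Aligned grade label vectors.
#' @return List `accuracy`, `within_one`, `confusion`.
#' @export
grading_metrics <- function(predicted, expert) {
  if (length(predicted) != length(expert)) stop("length mismatch")
  p <- as_grade(predicted)
  e <- as_grade(expert)
  acc <- mean(p == e)
  within1 <- mean(abs(as.integer(p) - as.integer(e)) <= 1)
  tab <- table(predicted = p, expert = e)
  cs <- colSums(tab)
  conf <- sweep(tab, 2, ifelse(cs == 0, 1, cs), "/")
  list(accuracy = acc, within_one = within1,
       confusion = unclass(conf))
}

#' Per-group diagnostic sensitivity of binary murmur detection
#'
#' For each group (e.g., disease), the proportion of patients with a
#' predicted murmur (any site's predicted grade above none), with a
#' patient-level percentile bootstrap interval, plus the distribution of
#' maximal-predicted-grade locations among flagged patients (a patient with
#' shared maxima counts toward each shared site).
#'
#' @param patient_preds Data frame with one row per patient: `patient_id`,
#'   `murmur_flag` (logical), `maximal_sites` (list column of site sets),
#'   and the grouping column.
#' @param group Name of the grouping column.
#' @param n_bootstrap,ci_level,seed Bootstrap settings.
#' @return Data frame per group: `n`, `sensitivity` (+ CI), and per-site
#'   maximal-location percentages.
#' @export
sensitivity_by_group <- function(patient_preds, group, n_bootstrap = 1000,
                                 ci_level = 0.95, seed = 1L) {
  groups <- unique(patient_preds[[group]])
  rows <- lapply(groups, function(g) {
    sub <- patient_preds[patient_preds[[group]] == g, ]
    if (nrow(sub) == 0) stop("empty group: ", g)
    flag_of <- stats::setNames(sub$murmur_flag, sub$patient_id)
    ci <- bootstrap_ci(function(ids) 100 * mean(flag_of[ids]),
                       sub$patient_id, n_bootstrap, ci_level,
                       seed = derive_seed(seed, "sens", g))
    flagged <- sub[sub$murmur_flag, ]
    site_pct <- vapply(site_levels(), function(s) {
      if (nrow(flagged) == 0) return(NA_real_)
      100 * mean(vapply(flagged$maximal_sites, function(ms) s %in% ms,
                        logical(1)))
    }, numeric(1))
    data.frame(group = g, n = nrow(sub),
               sensitivity = 100 * mean(sub$murmur_flag),
               sens_lower = ci$lower, sens_upper = ci$upper,
               max_left_apex = site_pct[["left_apex"]],
               max_left_base = site_pct[["left_base"]],
               max_right_side = site_pct[["right_side"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
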