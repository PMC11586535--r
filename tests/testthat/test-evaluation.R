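test_that("ROC handles separable, toy, and degenerate inputs", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc_auc(perfect), 1.0)
  toy <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(roc_auc(toy), 0.75)   # pair count: 3 of 4 pairs ordered
  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)), "both classes")
  expect_error(roc_curve(c(0.1), c(1, 0)), "length mismatch")
})

test_that("trapezoidal AUC equals the exhaustive pair-counting oracle", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    # coarse score grid induces frequent ties, including cross-class ties
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(roc_auc(roc_curve(scores, labels)),
                 pair_count_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- stats::runif(60)
  labels <- stats::rbinom(60, 1, plogis(3 * scores - 1.5))
  if (length(unique(labels)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(roc_curve(scores, labels)), ref,
                 tolerance = 1e-10)
  }
})

test_that("vertical averaging interpolates, mirrors, and collapses correctly", {
  set.seed(8)
  scores <- stats::runif(40)
  labels <- stats::rbinom(40, 1, plogis(4 * scores - 2))
  curve <- roc_curve(scores, labels)
  grid <- seq(0, 1, length.out = 101)
  single <- vertical_average(list(curve), grid)
  expect_equal(single$tpr_mean,
               stats::approx(curve$fpr, curve$tpr, grid, ties = max)$y)
  expect_equal(single$auc_mean, roc_auc(curve))

  # two curves vertically mirrored about the diagonal average onto it
  mk_curve <- function(fpr, tpr) {
    out <- data.frame(fpr = fpr, tpr = tpr)
    attr(out, "auc") <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    class(out) <- c("roc_points", "data.frame")
    out
  }
  up <- mk_curve(c(0, 0.5, 1), c(0, 0.9, 1))
  down <- mk_curve(c(0, 0.5, 1), c(0, 0.1, 1))   # 2x - up(x)
  mirrored <- vertical_average(list(up, down), grid)
  expect_equal(mirrored$auc_mean, 0.5)
  expect_equal(mirrored$tpr_mean, grid, tolerance = 1e-12)

  same <- vertical_average(rep(list(curve), 10), grid)
  expect_equal(same$tpr_lower, same$tpr_upper)
  expect_equal(diff(same$auc_ci), 0)

  shuffled <- vertical_average(list(down, up), grid)
  expect_equal(shuffled$tpr_mean, mirrored$tpr_mean)
  expect_error(vertical_average(list()), "no ROC curves")
})

test_that("bootstrap CI behaves on constant and Gaussian statistics", {
  ids <- sprintf("P%03d", 1:50)
  const <- bootstrap_ci(function(s) 7, ids, n_bootstrap = 100, seed = 1)
  expect_equal(const$lower, 7)
  expect_equal(const$upper, 7)

  set.seed(99)
  vals <- stats::setNames(stats::rnorm(1000), sprintf("Q%04d", 1:1000))
  ci <- bootstrap_ci(function(s) mean(vals[s]), names(vals),
                     n_bootstrap = 400, seed = 2)
  width <- ci$upper - ci$lower
  expect_lt(abs(width - 2 * 1.96 / sqrt(1000)) / (2 * 1.96 / sqrt(1000)),
            0.2)
})

test_that("grading metrics: identity, off-by-one, and hand-counted toys", {
  g <- c("none", "soft", "moderate", "loud", "thrilling")
  ident <- grading_metrics(g, g)
  expect_equal(ident$accuracy, 1)
  expect_equal(unname(diag(ident$confusion)), rep(1, 5))

  off <- grading_metrics(c("soft", "moderate", "loud", "thrilling",
                           "loud"), g)
  expect_equal(off$accuracy, 0)
  expect_equal(off$within_one, 1)

  toy <- grading_metrics(c("none", "soft", "loud"),
                         c("none", "moderate", "loud"))
  expect_equal(toy$accuracy, 2 / 3)
  expect_equal(toy$within_one, 1)

  set.seed(4)
  pred <- sample(g, 100, replace = TRUE)
  exp_ <- sample(g, 100, replace = TRUE)
  conf <- grading_metrics(pred, exp_)$confusion
  nonempty <- table(factor(exp_, levels = g)) > 0
  expect_equal(unname(colSums(conf)[nonempty]),
               rep(1, sum(nonempty)), tolerance = 1e-9)
  expect_error(grading_metrics(pred[1:5], exp_), "length mismatch")
})

test_that("per-group sensitivity and maximal-site tallies are exact", {
  pp <- data.frame(patient_id = sprintf("P%02d", 1:8),
                   disease = rep(c("PS", "MMVD"), each = 4),
                   murmur_flag = c(TRUE, TRUE, TRUE, TRUE,
                                   TRUE, TRUE, TRUE, FALSE))
  pp$maximal_sites <- list(
    "left_base", "left_base", c("left_base", "left_apex"), "left_base",
    "left_apex", "left_apex", "left_apex", character(0))
  out <- sensitivity_by_group(pp, "disease", n_bootstrap = 50, seed = 1)
  ps <- out[out$group == "PS", ]
  expect_equal(ps$sensitivity, 100)
  expect_equal(ps$max_left_base, 100)
  expect_equal(ps$max_left_apex, 25)
  mm <- out[out$group == "MMVD", ]
  expect_equal(mm$sensitivity, 75)
})
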