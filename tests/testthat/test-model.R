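test_that("model construction is seed-deterministic with the right shapes", {
  cfg <- tiny_model_config(seed = 7)
  m1 <- build_base_model(6, cfg, 2L)
  m2 <- build_base_model(6, cfg, 2L)
  expect_identical(m1$params, m2$params)
  m3 <- build_base_model(6, tiny_model_config(seed = 8), 2L)
  expect_false(identical(m1$params, m3$params))
  logits <- model_logits(m1, list(toy_spec(f = 6)))
  expect_equal(dim(logits), c(1L, 2L))
})

test_that("head surgery zeroes the head, keeps the rest bit-exact", {
  cfg <- tiny_model_config(seed = 3)
  base <- build_base_model(6, cfg, 2L)
  base$trained <- TRUE
  cut <- transfer_head_surgery(base, 5L)
  expect_identical(cut$params$layers, base$params$layers)
  expect_true(all(cut$params$head$W == 0) && all(cut$params$head$b == 0))
  # zero logits -> exactly uniform grade distribution for any input
  cut$trained <- TRUE
  for (s in 1:3) {
    p <- predict_grade(cut, toy_spec(seed = s))
    expect_equal(unname(as.numeric(p)), rep(0.2, 5))
  }
})

test_that("copied layers receive non-zero gradients during fine-tuning", {
  cfg <- tiny_model_config(seed = 3)
  m <- transfer_head_surgery(build_base_model(6, cfg, 2L), 5L)
  specs <- lapply(1:8, function(s) toy_spec(seed = s))
  y <- rep(0:3, 2)
  trained <- suppressWarnings(train_model(m, specs, y))
  # after training the recurrent weights moved, i.e. were not frozen
  expect_false(identical(trained$params$layers, m$params$layers))
  # and the gradient itself is non-zero once the head is away from zero
  X <- caninemurmur:::.spec_array(specs, 1L)
  g <- caninemurmur:::.gru_loss_grad_cpp(trained$params$layers,
                                         trained$params$head$W,
                                         trained$params$head$b, X,
                                         as.integer(y))
  expect_gt(max(abs(g$layer_grads[[1]]$fwd$Wi)), 0)
})

test_that("training reduces the loss and is reproducible", {
  cfg <- model_config(hidden_size = 8, num_layers = 1, max_epochs = 6,
                      batch_size = 4, seed = 11)
  m <- build_base_model(5, cfg, 2L)
  set.seed(42)
  specs <- lapply(1:12, function(i) {
    base <- matrix(rnorm(10 * 5), 10, 5)
    if (i %% 2 == 0) base[, 3] <- base[, 3] + 3
    base
  })
  y <- rep(c(0L, 1L), 6)
  t1 <- train_model(m, specs, y)
  t2 <- train_model(m, specs, y)
  expect_lt(tail(t1$history$train_loss, 1), t1$history$train_loss[1])
  expect_identical(t1$params, t2$params)
})

test_that("cross-validation folds partition patients, never recordings", {
  cfg <- tiny_model_config(seed = 1)
  m <- transfer_head_surgery(build_base_model(4, cfg, 2L), 5L)
  n_pat <- 50
  pid <- rep(sprintf("P%02d", seq_len(n_pat)), each = 2)
  specs <- lapply(seq_along(pid), function(s) toy_spec(t = 8, f = 4,
                                                       seed = s))
  y <- rep(rep(2L, n_pat), each = 2)  # same stratum -> exact fold balance
  m$config$max_epochs <- 1L
  ens <- suppressWarnings(
    finetune_crossval(m, specs, y, pid, k = 5, seed = 2))
  expect_s3_class(ens, "murmur_ensemble")
  expect_length(ens$members, 5)
  expect_equal(unname(table(ens$folds)), rep(10L, 5), ignore_attr = TRUE)
  expect_setequal(names(ens$folds), unique(pid))
  expect_error(finetune_crossval(m, specs[1:4], y[1:4], pid[1:4], k = 5),
               "fewer patients")
})

test_that("ensemble prediction averages members and is order-invariant", {
  cfg <- tiny_model_config(seed = 9)
  mk <- function(seed) {
    m <- build_base_model(4, tiny_model_config(seed = seed), 5L)
    m$trained <- TRUE
    m
  }
  members <- lapply(1:3, mk)
  ens <- structure(list(members = members, k = 3, config = cfg),
                   class = "murmur_ensemble")
  s <- list(toy_spec(t = 9, f = 4, seed = 5))
  p1 <- predict_grade(ens, s)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  ens_rev <- ens
  ens_rev$members <- rev(members)
  expect_equal(predict_grade(ens_rev, s), p1, tolerance = 1e-12)
  # identical members collapse to the single-member prediction
  ens_same <- ens
  ens_same$members <- list(members[[1]], members[[1]])
  expect_equal(predict_grade(ens_same, s),
               predict_grade(members[[1]], s), tolerance = 1e-12)
})

test_that("probability reductions are correct and monotone under upward mass shifts", {
  expect_equal(binary_murmur_probability(c(1, 0, 0, 0, 0)), 0)
  expect_equal(binary_murmur_probability(c(0.3, 0.3, 0.2, 0.1, 0.1)), 0.7)
  expect_equal(binary_murmur_probability(c(0, 0.25, 0.25, 0.25, 0.25)), 1)
  expect_equal(loud_or_greater_probability(c(0, 0, 0, 0.6, 0.4)), 1)
  expect_equal(loud_or_greater_probability(rep(0.2, 5)), 0.4)
  expect_equal(loud_or_greater_probability(c(1, 0, 0, 0, 0)), 0)
  expect_error(binary_murmur_probability(c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "sum to 1")
  set.seed(31)
  for (i in 1:50) {
    d <- as.numeric(stats::rgamma(5, 1))
    d <- d / sum(d)
    from <- sample(1:4, 1)
    higher <- (from + 1):5
    to <- higher[sample.int(length(higher), 1)]
    eps <- stats::runif(1, 0, d[from])
    d2 <- d
    d2[from] <- d2[from] - eps
    d2[to] <- d2[to] + eps
    expect_gte(binary_murmur_probability(d2) + 1e-12,
               binary_murmur_probability(d))
    expect_gte(loud_or_greater_probability(d2) + 1e-12,
               loud_or_greater_probability(d))
  }
})

test_that("patient aggregation flags murmurs and shares maximal sites", {
  mk <- function(grade) {
    d <- rep(0.05, 5)
    d[grade_index(grade) + 1] <- 0.8
    d / sum(d)
  }
  agg <- aggregate_patient(list(left_apex = mk("loud"),
                                left_base = mk("loud"),
                                right_side = mk("soft")))
  expect_true(agg$murmur_flag)
  expect_setequal(agg$maximal_sites, c("left_apex", "left_base"))
  none <- aggregate_patient(list(left_apex = mk("none"),
                                 left_base = mk("none"),
                                 right_side = mk("none")))
  expect_false(none$murmur_flag)
  expect_length(none$maximal_sites, 0)
  single <- aggregate_patient(list(left_base = mk("soft")))
  expect_true(single$murmur_flag)
  expect_equal(single$maximal_sites, "left_base")
  expect_error(aggregate_patient(list()), "at least one")
})

test_that("checkpoints round-trip models and ensembles", {
  m <- build_base_model(4, tiny_model_config(seed = 2), 2L)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(class(m2), "murmur_model")
})
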