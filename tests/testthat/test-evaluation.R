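# Cross-trial splits, accuracy reporting and the Wilcoxon signed-rank test.

test_that("split presets reproduce the conventional trial lists verbatim", {
  p1 <- split_preset("db1")
  expect_identical(p1$training_trials, c(1L, 3L, 4L, 6L, 7L, 8L, 9L))
  expect_identical(p1$test_trials, c(2L, 5L, 10L))
  for (nm in c("db2", "db3", "db4", "db5", "db7")) {
    p <- split_preset(nm)
    expect_identical(p$training_trials, c(1L, 3L, 4L, 6L))
    expect_identical(p$test_trials, c(2L, 5L))
  }
  p6 <- split_preset("db6")
  expect_identical(p6$training_trials, c(1L, 3L, 5L, 7L, 9L))
  expect_identical(p6$test_trials, c(2L, 4L, 6L, 8L, 10L))
  expect_error(split_preset("db9"), "unknown")
  expect_error(split_spec(c(1, 2), c(2, 3)), "disjoint")
})

test_that("cross-trial splitting is a true partition", {
  ds <- generate_dataset(tiny_sim(n_trials = 10L, n_gestures = 2L, seed = 101L))
  ws <- prepare_windows(ds)
  parts <- cross_trial_split(ws, split_preset("db1"))
  ns <- asNamespace("semgpose")
  expect_equal(ns$n_windows(parts$train) + ns$n_windows(parts$test),
               ns$n_windows(ws))
  expect_true(all(parts$test$meta$trial_index %in% c(2L, 5L, 10L)))
  expect_true(all(parts$train$meta$trial_index %in% c(1, 3, 4, 6, 7, 8, 9)))
  expect_length(intersect(
    paste(parts$train$meta$trial_index, parts$train$meta$time_step,
          parts$train$meta$gesture_id),
    paste(parts$test$meta$trial_index, parts$test$meta$time_step,
          parts$test$meta$gesture_id)), 0)
  expect_error(cross_trial_split(ws, split_spec(1:3, 4:5)), "outside")
})

test_that("accuracy is per-subject and unweighted-mean across subjects", {
  ds <- generate_dataset(tiny_sim(n_subjects = 2L, seed = 102L))
  ws <- prepare_windows(ds)
  set.seed(103)
  m <- semgxcm_new(tiny_model_config())
  preds <- predict_windows(m, ws)
  # oracle labels: force a perfect predictor
  perfect <- ws
  perfect$meta$gesture_id <- preds
  rep1 <- evaluate_model(m, perfect)
  expect_equal(rep1$mean_accuracy, 1.0)
  # the mean equals the unweighted mean of per-subject accuracies
  rep2 <- evaluate_model(m, ws)
  expect_equal(rep2$mean_accuracy, mean(rep2$per_subject_accuracy),
               tolerance = 1e-12)
  expect_true(all(rep2$per_subject_accuracy >= 0 & rep2$per_subject_accuracy <= 1))
})

test_that("accuracy against independent uniform labels concentrates at 1/N", {
  # labels drawn independently of the predictions: accuracy ~ Binomial(n, 1/N)
  ds <- generate_dataset(tiny_sim(n_subjects = 1L, n_gestures = 2L,
                                  n_trials = 2L, trial_duration = 3,
                                  seed = 104L))
  ws <- prepare_windows(ds, stride_ms = 10)
  N <- 8L
  reps <- 10L   # reuse the forward pass; each relabeling is a fresh draw
  set.seed(105)
  m <- semgxcm_new(tiny_model_config(N = N))
  preds <- predict_windows(m, ws)
  n_total <- length(preds) * reps
  set.seed(106)
  hits <- sum(vapply(seq_len(reps), function(r) {
    sum(preds == sample.int(N, length(preds), replace = TRUE))
  }, numeric(1)))
  p_hat <- hits / n_total
  se <- sqrt((1 / N) * (1 - 1 / N) / n_total)
  expect_lt(abs(p_hat - 1 / N), 3 * se)
})

test_that("Wilcoxon signed-rank matches exact enumeration and the reference test", {
  # all-positive differences, n = 5: one-sided p = 1/32
  a <- c(0.9, 0.8, 0.85, 0.7, 0.95)
  b <- a - c(0.05, 0.04, 0.03, 0.02, 0.01)
  res <- wilcoxon_signed_rank(a, b, alternative = "greater")
  expect_equal(res$p_value, 1 / 32, tolerance = 1e-12)
  expect_equal(res$statistic, 15)
  # degenerate comparison
  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
  # swapping a and b leaves the two-sided p unchanged
  set.seed(107)
  x <- runif(8); y <- runif(8)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(y, x)$p_value, tolerance = 1e-12)
  # brute-force enumeration oracle for random no-tie inputs, n <= 8
  for (s in 1:5) {
    set.seed(200 + s)
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- wilcoxon_signed_rank(x, y)
    d <- x - y
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    all_sums <- apply(as.matrix(expand.grid(rep(list(c(0, 1)), n))), 1L,
                      function(sg) sum(r * sg))
    p_oracle <- min(1, 2 * min(mean(all_sums >= v_obs), mean(all_sums <= v_obs)))
    expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
    # reference implementation agrees when there are no ties
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
  # normal approximation branch for larger n
  set.seed(210)
  x <- rnorm(20) + 0.5
  y <- rnorm(20)
  res <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("the ablation harness runs all four schemes on shared splits", {
  ds <- generate_dataset(tiny_sim(n_gestures = 2L, seed = 108L))
  mc <- tiny_model_config(N = 2L)
  csv <- tempfile(fileext = ".csv")
  res <- run_ablation(ds, mc, split = split_spec(c(1, 3), c(2, 4)),
                      stage1 = stage1_config(epochs = 1L, batch_size = 32L),
                      distill = distill_config(epochs = 1L, batch_size = 32L),
                      seeds = 1L, out_csv = csv)
  expect_equal(nrow(res), 4L)
  expect_setequal(res$scheme, c("scratch", "stage1_only", "stage2_only", "two_stage"))
  expect_true(all(res$mean_accuracy >= 0 & res$mean_accuracy <= 1))
  # the stage-1-only scheme never executes the distillation loss
  used <- attr(res, "losses_used")
  expect_identical(used$stage1_only, "ce")
  expect_identical(used$scratch, "ce")
  expect_true("kl" %in% used$two_stage)
  expect_true("kl" %in% used$stage2_only)
  expect_equal(nrow(utils::read.csv(csv)), 4L)
  diag <- attr(res, "stage1_diagnostics")
  expect_true(all(is.finite(diag$cosine_init)), all(is.finite(diag$cosine_stage1)))
})
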