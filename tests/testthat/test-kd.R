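# Distillation losses and stage-2 training.

test_that("cross-entropy matches closed-form values", {
  expect_equal(cross_entropy_loss(c(0, 0), 1L), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(0, 0), 2L), log(2), tolerance = 1e-12)
  expect_lt(cross_entropy_loss(c(30, -30), 1L), 1e-9)
  z <- c(1, 2, 3)
  expect_equal(cross_entropy_loss(z, 3L), -log(exp(3) / sum(exp(z))),
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(matrix(0, 2, 3), c(1L, 4L)), "labels")
  expect_gte(cross_entropy_loss(matrix(rnorm(12), 4, 3), c(1L, 2L, 3L, 1L)), 0)
})

test_that("tempered softmax is normalized, shift-invariant and uniform at high T", {
  expect_equal(tempered_softmax(c(0, 0), 1), c(0.5, 0.5))
  expect_equal(tempered_softmax(c(1, 0), 1), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  z <- rnorm(7)
  expect_lt(max(abs(tempered_softmax(z, 1e6) - 1 / 7)), 1e-6)
  expect_lt(max(abs(tempered_softmax(z + 5, 2) - tempered_softmax(z, 2))), 1e-9)
  zm <- matrix(rnorm(12), 3, 4)
  expect_equal(rowSums(tempered_softmax(zm, 3)), rep(1, 3), tolerance = 1e-12)
  expect_error(tempered_softmax(z, 0), "temperature")
})

test_that("distillation KL is nonnegative, zero at identity and asymmetric", {
  z <- matrix(rnorm(10), 2, 5)
  expect_lt(kd_kl_loss(z, z, 1), 1e-9)
  expect_lt(kd_kl_loss(z, z, 3), 1e-9)
  # p = (0.5, 0.5) vs q = (0.9, 0.1) via logit construction
  zp <- c(0, 0)
  zq <- log(c(0.9, 0.1))
  expect_equal(kd_kl_loss(zp, zq, 1),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1), tolerance = 1e-12)
  # asymmetry on a non-equal pair, nonnegativity everywhere
  set.seed(91)
  a <- matrix(rnorm(8), 2, 4)
  b <- matrix(rnorm(8), 2, 4)
  expect_gt(kd_kl_loss(a, b, 1), 0)
  expect_false(isTRUE(all.equal(kd_kl_loss(a, b, 1), kd_kl_loss(b, a, 1))))
  expect_error(kd_kl_loss(matrix(0, 2, 3), matrix(0, 2, 4)), "shape")
})

test_that("the overall objective is the exact convex combination", {
  expect_identical(overall_loss(2, 4, 0), 2)
  expect_identical(overall_loss(2, 4, 1), 4)
  expect_identical(overall_loss(2, 4, 0.5), 3)
  # linearity in (ce, kl) at fixed alpha
  a <- 0.3
  expect_equal(overall_loss(1, 2, a) + overall_loss(3, 5, a),
               overall_loss(4, 7, a), tolerance = 1e-12)
  expect_error(overall_loss(1, 1, 1.2), "alpha")
})

pose_fixture <- function(seed = 92L) {
  ds <- generate_dataset(tiny_sim(seed = seed))
  prep <- preprocess_trials(ds)
  semgpose:::prepare_windows_from_preprocessed(prep, 200, 100)
}

test_that("the pose teacher separates synthetic gestures quickly and deterministically", {
  ws <- pose_fixture()
  cfg <- distill_config(epochs = 10L, batch_size = 32L)
  fit <- train_teacher(ws, config = cfg, filters = 4L, seed = 1L)
  expect_lt(fit$history$ce[10], fit$history$ce[1])
  # training accuracy on the (deterministic slerp) pose windows
  lg <- pose_teacher_forward(fit$model, ws$pose)$logits
  acc <- mean(max.col(lg, ties.method = "first") == ws$meta$gesture_id)
  expect_gt(acc, 0.95)
  # 0 epochs returns the initialization; seeded rerun is identical
  f0 <- train_teacher(ws, config = distill_config(epochs = 0L), filters = 4L, seed = 2L)
  set.seed(2L)
  ref <- pose_teacher_new(dim(ws$pose)[2], max(ws$meta$gesture_id), filters = 4L)
  expect_identical(flat_params(f0$model), flat_params(ref))
  fit2 <- train_teacher(ws, config = cfg, filters = 4L, seed = 1L)
  expect_identical(fit$history, fit2$history)
  # single-class data is rejected
  one <- ws
  one$meta$gesture_id <- 1L
  expect_error(train_teacher(one, config = cfg), "two gesture classes")
})

test_that("stage-2 with alpha = 0 is exactly plain cross-entropy fine-tuning", {
  ws <- pose_fixture(seed = 93L)
  mc <- tiny_model_config()
  cfg0 <- distill_config(alpha = 0, epochs = 2L, batch_size = 32L)
  teacher <- train_teacher(ws, config = distill_config(epochs = 1L, batch_size = 32L),
                           filters = 4L, seed = 5L)
  with_teacher <- train_student_stage2(ws, mc, teacher = teacher, init = NULL,
                                       config = cfg0, seed = 6L)
  without <- train_student_stage2(ws, mc, teacher = NULL, init = NULL,
                                  config = cfg0, seed = 6L)
  expect_identical(flat_params(with_teacher$model), flat_params(without$model))
  expect_identical(with_teacher$losses_used, "ce")

  # alpha = 1: pure distillation reduces the KL term over epochs
  cfg1 <- distill_config(alpha = 1, epochs = 4L, batch_size = 32L, lr = 0.05)
  distilled <- train_student_stage2(ws, mc, teacher = teacher, init = NULL,
                                    config = cfg1, seed = 7L)
  h <- distilled$history
  expect_lt(h$kl[nrow(h)], h$kl[1])
  expect_identical(distilled$losses_used, c("ce", "kl"))

  # seeded rerun reproduces final losses exactly
  rerun <- train_student_stage2(ws, mc, teacher = teacher, init = NULL,
                                config = cfg1, seed = 7L)
  expect_identical(distilled$history, rerun$history)

  # guards: alpha > 0 without teacher or pose windows
  expect_error(train_student_stage2(ws, mc, teacher = NULL, init = NULL,
                                    config = distill_config(alpha = 0.5)),
               "teacher")
  nopose <- ws
  nopose$pose <- NULL
  expect_error(train_student_stage2(nopose, mc, teacher = teacher,
                                    config = distill_config(alpha = 0.5)),
               "pose")
})

test_that("the learning-rate schedule steps down at the configured epochs", {
  cfg <- distill_config(lr = 0.1, lr_drop_epochs = c(16L, 24L), lr_factor = 0.1)
  ns <- asNamespace("semgpose")
  expect_equal(ns$lr_at_epoch(cfg, 1), 0.1)
  expect_equal(ns$lr_at_epoch(cfg, 15), 0.1)
  expect_equal(ns$lr_at_epoch(cfg, 16), 0.01)
  expect_equal(ns$lr_at_epoch(cfg, 24), 0.001)
  expect_equal(ns$lr_at_epoch(cfg, 28), 0.001)
})
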