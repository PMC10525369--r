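# Mutual-information estimators and the stage-1 objective.

test_that("InfoNCE is bounded by log B and calibrated at the extremes", {
  set.seed(51)
  # never exceeds log B
  for (r in 1:20) {
    B <- sample(2:64, 1)
    a <- matrix(rnorm(B * 8), B, 8)
    b <- matrix(rnorm(B * 8), B, 8)
    expect_lte(infonce_bound(a, b), log(B) + 1e-6)
  }
  # anchors equal to positives and mutually orthogonal, temperature -> 0:
  # the bound attains log B
  eye <- diag(4)
  expect_equal(infonce_bound(eye, eye, temperature = 1e-3), log(4),
               tolerance = 1e-6)
  # independence: InfoNCE lower-bounds MI = 0, so the estimate must not be
  # significantly positive, and at unit temperature (mild critic variance)
  # it concentrates near zero from below (Monte-Carlo over 20 seeds)
  ests <- vapply(1:20, function(s) {
    set.seed(s)
    a <- matrix(rnorm(128 * 8), 128, 8)
    b <- matrix(rnorm(128 * 8), 128, 8)
    infonce_bound(a, b, temperature = 1)
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(mean(ests), 3 * se)
  expect_gt(mean(ests), -0.25)
  expect_error(infonce_bound(matrix(1, 1, 2), matrix(1, 1, 2)), "batch")
})

gaussian_pair <- function(n, d, rho, seed) {
  set.seed(seed)
  u <- matrix(rnorm(n * d), n, d)
  v <- rho * u + sqrt(1 - rho^2) * matrix(rnorm(n * d), n, d)
  list(u = u, v = v)
}

club_se <- function(u, v, q, shuffle) {
  pred <- likelihood_estimator_q(q, u)
  pos <- gaussian_log_density(v, pred$mean, pred$logvar)
  neg <- gaussian_log_density(v[shuffle, , drop = FALSE], pred$mean, pred$logvar)
  sqrt(stats::var(pos - neg) / length(pos))
}

test_that("CLUB vanishes for independent factors under a u-free Gaussian", {
  dat <- gaussian_pair(10000, 2, 0, seed = 52)
  q <- q_net_new(2L, hidden = 8L)
  for (p in semgpose:::collect_params(q)) p$value[] <- 0  # q(v|u) = N(0, I), u-free
  set.seed(53)
  shuffle <- sample.int(10000)
  est <- club_upper_bound(dat$u, dat$v, q, shuffle)
  se <- club_se(dat$u, dat$v, q, shuffle)
  expect_lt(abs(est), 3 * se + 1e-9)
})

test_that("trained CLUB upper-bounds the closed-form Gaussian MI", {
  d <- 2L
  for (rho in c(0, 0.8)) {
    dat <- gaussian_pair(4000, d, rho, seed = 60 + round(10 * rho))
    set.seed(61)
    q <- q_net_new(d, hidden = 16L)
    q_fit(dat$u, dat$v, q, iters = 250L, lr = 0.05)
    set.seed(62)
    shuffle <- sample.int(nrow(dat$u))
    est <- club_upper_bound(dat$u, dat$v, q, shuffle)
    se <- club_se(dat$u, dat$v, q, shuffle)
    true_mi <- -d / 2 * log(1 - rho^2)
    expect_gte(est, true_mi - 3 * se)
    if (rho == 0) expect_lt(abs(est), 3 * se + 0.02)
  }
})

test_that("Q recovers a linear-Gaussian conditional", {
  # v = 0.7 u + noise in one dimension; the fitted mean should have slope
  # ~0.7 (least-squares oracle)
  set.seed(63)
  n <- 10000
  u <- matrix(rnorm(n), n, 1)
  v <- 0.7 * u + 0.3 * matrix(rnorm(n), n, 1)
  q <- q_net_new(1L, hidden = 8L)
  q_fit(u, v, q, iters = 400L, lr = 0.05)
  pred <- likelihood_estimator_q(q, u)
  slope <- stats::coef(stats::lm(pred$mean ~ u))[2]
  oracle <- stats::coef(stats::lm(v ~ u))[2]
  expect_equal(unname(slope), unname(oracle), tolerance = 0.05)
})

test_that("Q's fitting loss attains the Gaussian NLL optimum", {
  # with mean = v and zero log-variance the NLL is (d/2) ln(2 pi)
  d <- 4L
  v <- matrix(rnorm(20 * d), 20, d)
  nll0 <- -mean(gaussian_log_density(v, v, matrix(0, 20, d)))
  expect_equal(nll0, d / 2 * log(2 * pi), tolerance = 1e-12)
  # inflating the variance away from the MLE variance increases the loss
  resid <- matrix(rnorm(500 * d, 0, 0.5), 500, d)
  mle_lv <- log(mean(resid^2))
  nll <- function(lv) -mean(gaussian_log_density(resid, 0 * resid,
                                                 matrix(lv, 500, d)))
  expect_lt(nll(mle_lv), nll(mle_lv + 0.5))
  expect_lt(nll(mle_lv), nll(mle_lv - 0.5))
})

test_that("stage-1 total reduces correctly and descends on a fixed batch", {
  ds <- generate_dataset(tiny_sim(seed = 71L))
  prep <- preprocess_trials(ds)
  pairs <- sample_pairs(prep, 200, 100, seed = 71L)
  idx <- seq_len(min(64L, nrow(pairs$meta)))
  batch <- list(anchor = pairs$anchor[, , idx, drop = FALSE],
                positive = pairs$positive[, , idx, drop = FALSE])
  mc <- tiny_model_config()
  set.seed(72)
  m <- semgxcm_new(mc)
  q <- q_net_new(mc$representation_dim)
  # lambda1 = lambda2 = 0: total is exactly -mi_self
  cfg0 <- stage1_config(lambda1 = 0, lambda2 = 0, augment_sd = 0)
  set.seed(73)
  res <- stage1_total_loss(m, q, batch, cfg0)
  expect_equal(res$total, -res$losses$mi_self, tolerance = 1e-12)
  # all components finite on a random batch
  cfg <- stage1_config(augment_sd = 0.01)
  set.seed(74)
  res <- stage1_total_loss(m, q, batch, cfg)
  expect_true(all(is.finite(unlist(res$losses))), is.finite(res$total))
  expect_error(stage1_config(lambda1 = -1), "lambda")

  # one SGD step decreases the loss on a fixed batch (majority of 5 seeds)
  ns <- asNamespace("semgpose")
  wins <- 0L
  for (s in 1:5) {
    set.seed(80 + s)
    m2 <- semgxcm_new(mc)
    q2 <- q_net_new(mc$representation_dim)
    cfgd <- stage1_config(augment_sd = 0, lambda1 = 1, lambda2 = 0.1)
    set.seed(180 + s)  # same CLUB shuffle for every evaluation below
    before <- stage1_total_loss(m2, q2, batch, cfgd)$total
    Xa <- ns$batch_to_rows(batch$anchor)
    Xp <- ns$batch_to_rows(batch$positive)
    ns$ag_reset()
    set.seed(180 + s)
    nodes <- ns$stage1_batch_nodes(m2, q2, Xa, Xp, cfgd)
    mp <- ns$collect_params(m2)
    ns$ag_zero_grad(mp)
    ns$ag_backward(nodes$total)
    ns$ag_sgd_step(mp, 1e-3)
    ns$ag_reset()
    set.seed(180 + s)
    after <- stage1_total_loss(m2, q2, batch, cfgd)$total
    if (after < before) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("stage-1 training is a seeded, resumable-free deterministic procedure", {
  ds <- generate_dataset(tiny_sim(seed = 75L))
  prep <- preprocess_trials(ds)
  mc <- tiny_model_config()
  # 0 epochs returns the Xavier initialization untouched
  f0 <- train_stage1(prep, mc, stage1_config(epochs = 0L), seed = 9L)
  set.seed(9L)
  ref <- semgxcm_new(mc)
  expect_identical(flat_params(f0$model), flat_params(ref))
  # seeded reruns give identical final losses and parameters
  cfg <- stage1_config(epochs = 1L, batch_size = 32L)
  f1 <- train_stage1(prep, mc, cfg, seed = 10L)
  f2 <- train_stage1(prep, mc, cfg, seed = 10L)
  expect_identical(f1$history, f2$history)
  expect_identical(flat_params(f1$model), flat_params(f2$model))
})
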