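# Architecture contracts: shapes, determinism, attention parameter scaling,
# projection heads, likelihood estimator, pose teacher and initialization.

test_that("classifier forward satisfies its shape and softmax contracts", {
  cfg <- tiny_model_config(C = 4L, W = 12L, N = 8L)
  set.seed(31)
  m <- semgxcm_new(cfg)
  batch <- array(rnorm(12 * 4 * 5), dim = c(12, 4, 5))
  out <- semgxcm_forward(m, batch)
  expect_equal(dim(out$logits), c(5L, 8L))
  probs <- tempered_softmax(out$logits, 1)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  # evaluation mode is deterministic
  expect_identical(out$logits, semgxcm_forward(m, batch)$logits)
  # batch permutation equivariance
  perm <- c(3L, 5L, 1L, 2L, 4L)
  out2 <- semgxcm_forward(m, batch[, , perm])
  expect_equal(out2$logits, out$logits[perm, ], tolerance = 1e-10)
  # shape mismatch errors
  expect_error(semgxcm_forward(m, array(0, dim = c(12, 3, 5))))
})

test_that("self-attention parameter count grows with the electrode count", {
  c16 <- model_config(16L, 20L, 8L, temporal_filters = 8L, spatial_filters = 4L)
  c10 <- model_config(10L, 20L, 8L, temporal_filters = 8L, spatial_filters = 4L)
  expect_gt(attention_n_params(c16), attention_n_params(c10))
  # the count matches the layer actually built
  set.seed(32)
  m <- semgxcm_new(c10)
  expect_equal(semgpose:::n_parameters(m$attn), attention_n_params(c10))
  # heads divide the attention embedding dimension by construction
  expect_equal((c10$attention_heads * c10$head_dim) %% c10$attention_heads, 0L)
})

test_that("projection heads emit two length-d representations", {
  cfg <- tiny_model_config()
  set.seed(33)
  m <- semgxcm_new(cfg)
  d <- cfg$representation_dim
  f0 <- matrix(0, 1, cfg$temporal_filters)
  # zero feature with zero-initialized heads gives zero u and v
  for (p in semgpose:::collect_params(list(m$head_u, m$head_v))) p$value[] <- 0
  z <- projection_heads(m, f0)
  expect_equal(z$u, matrix(0, 1, d))
  expect_equal(z$v, matrix(0, 1, d))
  # distinct parameters give u != v on random features
  set.seed(34)
  m2 <- semgxcm_new(cfg)
  feats <- matrix(rnorm(100 * cfg$temporal_filters), 100)
  out <- projection_heads(m2, feats)
  expect_equal(dim(out$u), c(100L, d))
  expect_equal(dim(out$v), c(100L, d))
  expect_true(all(rowSums(abs(out$u - out$v)) > 0))
})

test_that("likelihood estimator Q predicts a proper diagonal Gaussian", {
  set.seed(35)
  q <- q_net_new(6L)
  u <- matrix(rnorm(5 * 6), 5, 6)
  pred <- likelihood_estimator_q(q, u)
  expect_equal(dim(pred$mean), c(5L, 6L))
  expect_equal(dim(pred$logvar), c(5L, 6L))
  expect_true(all(is.finite(pred$mean)), all(is.finite(pred$logvar)))
  # log density at mean = v with zero log-variance is -(d/2) ln(2 pi)
  v <- matrix(rnorm(5 * 6), 5, 6)
  ld <- gaussian_log_density(v, v, matrix(0, 5, 6))
  expect_equal(ld, rep(-3 * log(2 * pi), 5), tolerance = 1e-12)
  # gradient of the NLL w.r.t. the mean vanishes at mean = v
  ns <- asNamespace("semgpose")
  mu_p <- ns$ag_param(v)
  ns$ag_reset()
  mu_node <- ns$ag_leaf(mu_p)
  nll <- ns$ag_neg(ns$ag_mean(ns$gaussian_logq_nodes(mu_node, ns$ag_const(matrix(0, 5, 6)),
                                                     ns$ag_const(v))))
  ns$ag_zero_grad(list(mu_p))
  ns$ag_backward(nll)
  expect_equal(max(abs(mu_p$grad)), 0)
  ns$ag_reset()
})

test_that("pose teacher obeys shape, independence and parameter-count contracts", {
  set.seed(36)
  tm <- pose_teacher_new(16L, 8L, filters = 3L)
  batch <- array(rnorm(10 * 16 * 5), dim = c(10, 16, 5))
  out <- pose_teacher_forward(tm, batch)
  expect_equal(dim(out$logits), c(5L, 8L))
  # permuting the batch permutes logits (no cross-item leakage)
  perm <- c(4L, 1L, 5L, 2L, 3L)
  expect_equal(pose_teacher_forward(tm, batch[, , perm])$logits,
               out$logits[perm, ], tolerance = 1e-10)
  # analytic parameter count matches the built model, and depth doubling
  # adds exactly the per-block increment predicted by the layer formula
  expect_equal(semgpose:::n_parameters(list(tm$blocks, tm$cls)),
               pose_teacher_n_params(16L, 8L, filters = 3L))
  p2 <- pose_teacher_n_params(16L, 8L, filters = 3L, n_blocks = 2L)
  p4 <- pose_teacher_n_params(16L, 8L, filters = 3L, n_blocks = 4L)
  width <- 9L
  per_block <- sum(c(3, 5, 7) * width * 3L + 3L) + 2L * width
  expect_equal(p4 - p2, 2L * per_block)
  set.seed(37)
  tm4 <- pose_teacher_new(16L, 8L, filters = 3L, n_blocks = 4L)
  expect_equal(semgpose:::n_parameters(list(tm4$blocks, tm4$cls)), p4)
  expect_error(pose_teacher_forward(tm, array(0, dim = c(10, 12, 5))))
})

test_that("initial affine weights follow the Xavier-uniform variance", {
  set.seed(38)
  ns <- asNamespace("semgpose")
  W <- ns$xavier_uniform(120L, 90L)
  expect_gte(length(W), 1e4)
  expect_equal(var(as.numeric(W)), 2 / (120 + 90), tolerance = 0.2)
  lim <- sqrt(6 / 210)
  expect_true(all(abs(W) <= lim))
})

test_that("checkpoints round-trip parameters and running statistics", {
  cfg <- tiny_model_config()
  set.seed(39)
  m <- semgxcm_new(cfg)
  batch <- array(rnorm(20 * 4 * 6), dim = c(20, 4, 6))
  invisible(semgxcm_forward(m, batch, training = TRUE))  # move BN stats
  ref <- semgxcm_forward(m, batch)$logits
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  set.seed(40)
  m2 <- semgxcm_new(cfg)
  expect_false(isTRUE(all.equal(semgxcm_forward(m2, batch)$logits, ref)))
  load_checkpoint(m2, path)
  expect_identical(semgxcm_forward(m2, batch)$logits, ref)
  expect_error(load_checkpoint(m2, {
    p <- tempfile(); saveRDS(list(a = 1), p); p
  }), "checkpoint")
})
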