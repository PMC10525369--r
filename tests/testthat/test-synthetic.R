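# Synthetic sEMG/pose simulator: determinism, counts, envelope structure,
# pose dictionary and slerp geometry, and class separability.

test_that("identical configs give bitwise-identical datasets of the right size", {
  cfg <- tiny_sim(seed = 7L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_length(d1$trials, 1 * 3 * 4)

  big <- sim_config(n_subjects = 2L, n_gestures = 8L, n_trials = 6L,
                    n_channels = 3L, trial_duration = 0.3, joint_count = 2L)
  expect_length(generate_dataset(big)$trials, 96L)

  tr <- d1$trials[[1]]
  expect_true(all(is.finite(tr$samples)))
  expect_equal(dim(tr$pose$frames)[1], nrow(tr$samples))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_subjects = 0), "counts")
  expect_error(sim_config(phase_fractions = c(0.5, 0.5, 0.1)), "phase_fractions")
  expect_error(sim_config(phase_fractions = c(0.5, 0.5, 0)), "phase_fractions")
  expect_error(sim_config(electrode_shift_prob = 1.5), "electrode_shift_prob")
  expect_error(sim_config(noise_sd = -1), "must be >= 0")
})

test_that("with zero nuisance, same-gesture trials share their envelope", {
  cfg <- tiny_sim(trial_gain_sd = 0, electrode_shift_prob = 0, noise_sd = 0,
                  duration_jitter = 0, n_trials = 2L, seed = 5L)
  ds <- generate_dataset(cfg)
  g1 <- Filter(function(tr) tr$gesture_id == 1L, ds$trials)
  a <- g1[[1]]$samples
  b <- g1[[2]]$samples
  # rectified moving-average envelopes agree up to carrier-noise fluctuation
  env_est <- function(x, w = 21L) {
    apply(abs(x), 2L, function(ch) as.numeric(stats::filter(ch, rep(1 / w, w))))
  }
  ea <- env_est(a); eb <- env_est(b)
  ok <- stats::complete.cases(ea[, 1])
  rel_diff <- mean(abs(ea[ok, ] - eb[ok, ])) / mean(abs(ea[ok, ]))
  expect_lt(rel_diff, 0.5)

  # Monte-Carlo oracle: mean |difference| between two trials never exceeds
  # the pure-carrier baseline (the envelope only attenuates the carriers)
  set.seed(99)
  ns <- asNamespace("semgpose")
  baseline <- replicate(100, {
    n1 <- ns$band_limited_noise(nrow(a), 1L)
    n2 <- ns$band_limited_noise(nrow(a), 1L)
    mean(abs(n1 - n2))
  })
  expect_lt(mean(abs(a - b)), mean(baseline))
})

test_that("gesture ending poses are deterministic, unit-norm and distinct", {
  p1 <- gesture_ending_pose(1L, 6L)
  p1b <- gesture_ending_pose(1L, 6L)
  expect_identical(p1, p1b)
  expect_equal(dim(p1), c(6L, 4L))
  expect_true(all(abs(sqrt(rowSums(p1^2)) - 1) < 1e-6))
  # distinctness across the dictionary: positive pairwise geodesic distance
  poses <- lapply(1:6, gesture_ending_pose, joint_count = 6L)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gt(max(vapply(1:6, function(k) {
      quat_geodesic(poses[[i]][k, ], poses[[j]][k, ])
    }, numeric(1))), 0)
  }
  expect_error(gesture_ending_pose(0L), "gesture_id")
  expect_error(gesture_ending_pose(2.5), "gesture_id")
})

test_that("pose synthesis follows slerp through make/hold/end phases", {
  fr <- c(0.25, 0.5, 0.25)
  ps <- synthesize_pose_sequence(2L, 40L, fr, joint_count = 3L)
  expect_s3_class(ps, "pose_sequence")
  expect_equal(dim(ps$frames), c(40L, 3L, 4L))
  # all frames unit norm
  norms <- apply(ps$frames, c(1, 2), function(q) sqrt(sum(q^2)))
  expect_true(all(abs(norms - 1) < 1e-6))
  # first frame is the identity for every joint
  for (j in 1:3) expect_equal(ps$frames[1, j, ], c(1, 0, 0, 0))
  # end of the make phase reaches the ending pose exactly
  ending <- gesture_ending_pose(2L, 3L)
  nm <- unname(semgpose:::phase_lengths(40L, fr)["make"])
  for (j in 1:3) expect_equal(ps$frames[nm, j, ], ending[j, ], tolerance = 1e-12)
  # hold phase keeps the ending pose; final frame returns to neutral
  expect_equal(ps$frames[nm + 2L, , ], ending, tolerance = 1e-12)
  expect_equal(ps$frames[40L, 1, ], c(1, 0, 0, 0), tolerance = 1e-9)
  expect_error(synthesize_pose_sequence(1L, 1L), "n_frames")
})

test_that("slerp matches the closed-form axis-angle solution", {
  # neutral -> 90 degree rotation about z, halfway: 45/2 degrees about z
  q0 <- c(1, 0, 0, 0)
  q1 <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  half <- quat_slerp(q0, q1, 0.5)
  expect_equal(half, c(cos(pi / 8), 0, 0, sin(pi / 8)), tolerance = 1e-12)
  expect_equal(half[1], 0.92388, tolerance = 1e-4)
  expect_equal(half[4], 0.38268, tolerance = 1e-4)
  expect_equal(quat_slerp(q0, q1, 0), q0)
  expect_equal(quat_slerp(q0, q1, 1), q1)
})

test_that("a window-RMS nearest-centroid classifier beats chance across trials", {
  ds <- generate_dataset(sim_config())
  ws <- prepare_windows(ds)
  feats <- t(apply(ws$values, 3L, function(w) sqrt(colMeans(w^2))))
  train <- ws$meta$trial_index %in% c(1, 3, 4, 6)
  test <- !train
  lab <- ws$meta$gesture_id
  cents <- do.call(rbind, lapply(sort(unique(lab)), function(g) {
    colMeans(feats[train & lab == g, , drop = FALSE])
  }))
  d2 <- as.matrix(stats::dist(rbind(cents, feats[test, ])))
  pred <- apply(d2[-(1:nrow(cents)), 1:nrow(cents)], 1L, which.min)
  acc <- mean(pred == lab[test])
  n <- sum(test)
  chance <- 1 / length(unique(lab))
  se <- sqrt(chance * (1 - chance) / n)
  expect_gt(acc, chance + 3 * se)
})
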