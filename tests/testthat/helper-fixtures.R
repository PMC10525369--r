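# Shared fixtures: compact configurations and datasets small enough for
# fast unit tests, built in code at test time.

tiny_sim <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 1L, n_gestures = 3L, n_trials = 4L, n_channels = 4L,
         sampling_rate = 100, trial_duration = 1, joint_count = 4L,
         seed = 42L),
    list(...))
  do.call(sim_config, args)
}

tiny_model_config <- function(C = 4L, W = 20L, N = 3L, ...) {
  args <- utils::modifyList(
    list(n_channels = C, window_len = W, n_gestures = N,
         representation_dim = 8L, attention_heads = 2L,
         temporal_filters = 4L, spatial_filters = 2L, dropout = 0),
    list(...))
  do.call(model_config, args)
}

# compact study configuration used for the training-scheme checks
study_model_config <- function() {
  model_config(10L, 20L, 8L, representation_dim = 16L, attention_heads = 4L,
               temporal_filters = 8L, spatial_filters = 4L, dropout = 0.1)
}

# nudge all parameters away from zero so ReLU inputs sit off the kink
# (finite differences disagree with the subgradient convention exactly there)
perturb_params <- function(obj, sd = 0.05) {
  for (p in semgpose:::collect_params(obj)) {
    p$value <- p$value + stats::rnorm(length(p$value), 0, sd)
  }
  invisible(obj)
}

# maximum absolute difference between analytic and central-difference
# gradients over a selection of parameters
max_grad_err <- function(build_loss, params, h = 1e-5) {
  ag <- asNamespace("semgpose")
  ag$ag_reset()
  loss <- build_loss()
  ag$ag_zero_grad(params)
  ag$ag_backward(loss)
  grads <- lapply(params, function(p) p$grad)
  fn <- function() {
    ag$ag_reset()
    v <- build_loss()$value[1]
    ag$ag_reset()
    v
  }
  errs <- vapply(seq_along(params), function(i) {
    fd <- ag$ag_fd_grad(fn, params[[i]], h = h)
    max(abs(grads[[i]] - fd))
  }, numeric(1))
  ag$ag_reset()
  max(errs)
}

flat_params <- function(model) {
  unlist(lapply(semgpose:::collect_params(model), function(p) as.numeric(p$value)))
}
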