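#' Fit a cross-trial sEMG gesture recognizer with the two-stage scheme
#'
#' The main fitting interface. Runs the full pipeline on a trial collection:
#' preprocessing (filter, mu-law normalization), alignment, sliding-window
#' segmentation and a cross-trial split; stage 1, cross-trial
#' mutual-information pretraining of the encoder on the training trials;
#' stage 2, supervised hand-pose teacher training followed by knowledge
#' distillation into the stage-1-initialized student; and evaluation of
#' cross-trial accuracy on the held-out trials. Inference uses sEMG windows
#' only — pose streams are consumed solely during training.
#'
#' @param dataset a `semg_dataset` (from [generate_dataset()] or
#'   [read_ninapro_mat()] trials wrapped in a list).
#' @param model_config a [model_config()]; a compact one is derived from the
#'   data when `NULL`.
#' @param split a [split_spec()] or preset name (see [split_preset()]).
#' @param stage1 a [stage1_config()].
#' @param distill a [distill_config()].
#' @param window_ms,stride_ms segmentation parameters (milliseconds).
#' @param filter `"rms"` (default), `"butterworth"` or `"none"`.
#' @param teacher_filters pose-teacher convolution width.
#' @param seed integer seed; the whole fit is deterministic given it.
#' @param verbose print training progress.
#' @return an object of class `semg_pose_mim` with components `model` (the
#'   trained student), `teacher`, `stage1`, `stage2`, `report` (held-out
#'   [evaluate_model()] report) and the configurations used.
#' @examples
#' \donttest{
#' ds <- generate_dataset(sim_config(n_subjects = 1, n_gestures = 3,
#'                                   n_trials = 4, n_channels = 4,
#'                                   trial_duration = 1, seed = 7))
#' fit <- semg_pose_mim(ds,
#'   model_config = model_config(4, 20, 3, representation_dim = 8,
#'                               temporal_filters = 4, spatial_filters = 2,
#'                               dropout = 0),
#'   split = split_spec(c(1, 3), c(2, 4)),
#'   stage1 = stage1_config(epochs = 1, batch_size = 32),
#'   distill = distill_config(epochs = 2, batch_size = 32), seed = 1)
#' print(fit)
#' }
#' @export
semg_pose_mim <- function(dataset, model_config = NULL,
                          split = split_preset("db2"),
                          stage1 = stage1_config(),
                          distill = distill_config(),
                          window_ms = 200, stride_ms = 100,
                          filter = "rms", teacher_filters = 8L,
                          seed = 1L, verbose = FALSE) {
  trials <- if (inherits(dataset, "semg_dataset")) dataset$trials else dataset
  if (is.character(split)) split <- split_preset(split)
  prep <- preprocess_trials(trials, filter)
  if (is.null(model_config)) model_config <- default_model_config(prep, window_ms)
  windows <- prepare_windows_from_preprocessed(prep, window_ms, stride_ms)
  parts <- cross_trial_split(windows, split)
  train_trials <- Filter(function(tr) tr$trial_index %in% split$training_trials,
                         prep)
  s1 <- train_stage1(train_trials, model_config, stage1, window_ms, stride_ms,
                     seed = seed, verbose = verbose)
  teacher <- train_teacher(parts$train, config = distill,
                           n_gestures = model_config$n_gestures,
                           filters = teacher_filters, seed = seed)
  s2 <- train_student_stage2(parts$train, model_config, teacher = teacher,
                             init = s1, config = distill, seed = seed,
                             verbose = verbose)
  report <- evaluate_model(s2$model, parts$test)
  structure(list(model = s2$model, teacher = teacher, stage1 = s1,
                 stage2 = s2, report = report, model_config = model_config,
                 split = split, window_ms = window_ms, stride_ms = stride_ms,
                 filter = filter, seed = seed),
            class = "semg_pose_mim")
}

#' @export
print.semg_pose_mim <- function(x, ...) {
  cat("Two-stage cross-trial sEMG gesture recognizer\n")
  cat(sprintf("  %d gestures, %d electrodes, %d-sample windows; %s parameters\n",
              x$model_config$n_gestures, x$model_config$n_channels,
              x$model_config$window_len,
              format(n_parameters(x$model), big.mark = ",")))
  cat(sprintf("  stage 1: %d epochs (MI pretraining); stage 2: %d epochs (distillation, alpha = %g, T = %g)\n",
              x$stage1$config$epochs, x$stage2$config$epochs,
              x$stage2$config$alpha, x$stage2$config$temperature))
  cat(sprintf("  held-out cross-trial accuracy: %.1f%% (trials %s)\n",
              100 * x$report$mean_accuracy,
              paste(x$split$test_trials, collapse = ",")))
  invisible(x)
}

#' @export
summary.semg_pose_mim <- function(object, ...) {
  print(object)
  cat("\nPer-subject held-out accuracy:\n")
  for (s in names(object$report$per_subject_accuracy)) {
    cat(sprintf("  subject %s: %.1f%%\n", s,
                100 * object$report$per_subject_accuracy[[s]]))
  }
  h <- object$stage2$history
  cat(sprintf("\nFinal stage-2 losses: CE %.4f, KL %.4f (train acc %.1f%%)\n",
              h$ce[nrow(h)], h$kl[nrow(h)], 100 * h$acc[nrow(h)]))
  invisible(object)
}

#' Predict gesture labels from sEMG data
#'
#' @param object a fitted `semg_pose_mim`.
#' @param newdata a `window_set`, a `semg_dataset`, or a list of raw
#'   `emg_trial` (preprocessed and segmented with the fit's settings).
#' @param ... unused.
#' @return integer vector of predicted gesture labels.
#' @export
predict.semg_pose_mim <- function(object, newdata, ...) {
  ws <- if (inherits(newdata, "window_set")) newdata else {
    prepare_windows(newdata, object$window_ms, object$stride_ms,
                    filter = object$filter, align = FALSE)
  }
  predict_windows(object$model, ws)
}

#' Plot training curves of a fitted recognizer
#'
#' @param x a `semg_pose_mim`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.semg_pose_mim <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  h1 <- x$stage1$history
  if (nrow(h1) > 0) {
    graphics::plot(h1$epoch, h1$total, type = "b", xlab = "epoch",
                   ylab = "stage-1 total loss",
                   main = "MI pretraining", ...)
  }
  h2 <- x$stage2$history
  if (nrow(h2) > 0) {
    ylim <- range(c(h2$ce, h2$kl, h2$overall))
    graphics::plot(h2$epoch, h2$overall, type = "b", xlab = "epoch",
                   ylab = "loss", ylim = ylim, main = "Distillation", ...)
    graphics::lines(h2$epoch, h2$ce, type = "b", lty = 2)
    graphics::lines(h2$epoch, h2$kl, type = "b", lty = 3)
    graphics::legend("topright", c("overall", "CE", "KL"), lty = 1:3, bty = "n")
  }
  invisible(x)
}
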