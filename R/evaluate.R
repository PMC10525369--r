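# Cross-trial evaluation: trial-index splits, per-subject window accuracy,
# exact Wilcoxon signed-rank comparison and the per-stage ablation harness.

#' Cross-trial split specification
#'
#' @param training_trials,test_trials disjoint nonempty integer sets of
#'   trial indices whose union covers the declared trial range.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(training_trials, test_trials) {
  training_trials <- sort(unique(as.integer(training_trials)))
  test_trials <- sort(unique(as.integer(test_trials)))
  if (length(training_trials) == 0 || length(test_trials) == 0) {
    stop("both trial sets must be nonempty")
  }
  if (length(intersect(training_trials, test_trials)) > 0) {
    stop("training and test trial sets must be disjoint")
  }
  structure(list(training_trials = training_trials, test_trials = test_trials),
            class = "split_spec")
}

#' Named cross-trial split presets for the NinaPro databases
#'
#' The conventional train/test repetition lists: DB1 trains on repetitions
#' 1,3,4,6,7,8,9 and tests on 2,5,10; DB2-DB5 and DB7 train on 1,3,4,6 and
#' test on 2,5; DB6 trains on odd repetitions 1,3,5,7,9 and tests on the
#' even ones.
#'
#' @param name one of `"db1"` ... `"db7"`.
#' @return a [split_spec()].
#' @export
split_preset <- function(name) {
  presets <- list(
    db1 = list(c(1, 3, 4, 6, 7, 8, 9), c(2, 5, 10)),
    db2 = list(c(1, 3, 4, 6), c(2, 5)),
    db3 = list(c(1, 3, 4, 6), c(2, 5)),
    db4 = list(c(1, 3, 4, 6), c(2, 5)),
    db5 = list(c(1, 3, 4, 6), c(2, 5)),
    db6 = list(c(1, 3, 5, 7, 9), c(2, 4, 6, 8, 10)),
    db7 = list(c(1, 3, 4, 6), c(2, 5))
  )
  p <- presets[[tolower(name)]]
  if (is.null(p)) stop("unknown split preset: ", name)
  split_spec(p[[1]], p[[2]])
}

#' Partition windows into training and test sets by trial index
#'
#' @param windows a `window_set`.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` window sets.
#' @export
cross_trial_split <- function(windows, spec) {
  stopifnot(inherits(windows, "window_set"), inherits(spec, "split_spec"))
  ti <- windows$meta$trial_index
  declared <- c(spec$training_trials, spec$test_trials)
  if (!all(ti %in% declared)) {
    stop("window trial indices outside the split specification: ",
         paste(setdiff(unique(ti), declared), collapse = ", "))
  }
  list(train = subset_windows(windows, which(ti %in% spec$training_trials)),
       test = subset_windows(windows, which(ti %in% spec$test_trials)))
}

#' Predict gesture labels for a window set
#'
#' @param model a `semgxcm_model`.
#' @param windows a `window_set`.
#' @param batch_size forward batch size.
#' @return integer vector of predicted labels (argmax logits).
#' @export
predict_windows <- function(model, windows, batch_size = 256L) {
  n <- n_windows(windows)
  preds <- integer(n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    lg <- semgxcm_forward(model, windows$values[, , idx, drop = FALSE])$logits
    preds[idx] <- max.col(lg, ties.method = "first")
    at <- at + batch_size
  }
  preds
}

#' Evaluate cross-trial gesture-recognition accuracy
#'
#' Per-subject fraction of test windows whose argmax logit equals the true
#' gesture, and the unweighted mean across subjects (the cross-trial
#' accuracy metric). Subjects with zero test windows are excluded with a
#' warning.
#'
#' @param model a `semgxcm_model`.
#' @param windows a `window_set` of test windows.
#' @return object of class `eval_report`: `per_subject_accuracy` (named),
#'   `mean_accuracy`, `n_test_windows`.
#' @export
evaluate_model <- function(model, windows) {
  n <- n_windows(windows)
  if (n == 0) stop("no test windows")
  preds <- predict_windows(model, windows)
  correct <- preds == windows$meta$gesture_id
  subs <- sort(unique(windows$meta$subject_id))
  acc <- vapply(subs, function(s) {
    sel <- windows$meta$subject_id == s
    if (!any(sel)) return(NA_real_)
    mean(correct[sel])
  }, numeric(1))
  names(acc) <- as.character(subs)
  if (anyNA(acc)) {
    warning("subjects without test windows excluded: ",
            paste(names(acc)[is.na(acc)], collapse = ", "))
    acc <- acc[!is.na(acc)]
  }
  structure(list(per_subject_accuracy = acc, mean_accuracy = mean(acc),
                 n_test_windows = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Cross-trial accuracy: %.1f%% (mean over %d subjects, %d test windows)\n",
              100 * x$mean_accuracy, length(x$per_subject_accuracy),
              x$n_test_windows))
  for (s in names(x$per_subject_accuracy)) {
    cat(sprintf("  subject %s: %.1f%%\n", s, 100 * x$per_subject_accuracy[[s]]))
  }
  invisible(x)
}

#' Wilcoxon signed-rank test for paired accuracies
#'
#' Zero differences are dropped; ranks of |differences| use midranks for
#' ties. For n <= 15 remaining pairs the null distribution of the positive
#' rank sum is computed by exact enumeration of all 2^n sign patterns
#' (conditional on the observed ranks, so ties are handled exactly); above
#' that a normal approximation with tie correction is used.
#'
#' @param a,b numeric vectors of paired per-subject accuracies.
#' @param alternative `"two.sided"`, `"greater"` (a > b) or `"less"`.
#' @return list with `statistic` (positive rank sum V), `p_value`, `n_used`,
#'   and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate comparison: all paired differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 15) {
    # exact: distribution of the positive rank sum over all sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.numeric(signs %*% r)
    p_ge <- mean(sums >= v - 1e-9)
    p_le <- mean(sums <= v + 1e-9)
    p <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = v, p_value = p, n_used = n, method = method)
}

#' Run the four-scheme training ablation
#'
#' Trains the window classifier under four schemes on identical splits and
#' shared seeds: from scratch (cross-entropy only, Xavier init), stage 1
#' only (mutual-information pretraining then cross-entropy fine-tuning),
#' stage 2 only (Xavier init with knowledge distillation), and the full
#' two-stage scheme (pretraining plus distillation). Reports mean
#' cross-trial accuracy per scheme, and records stage-1 trial-invariance
#' diagnostics (mean cross-trial cosine similarity of u at initialization
#' and after pretraining) per seed.
#'
#' @param dataset a `semg_dataset` (or list of raw `emg_trial`).
#' @param model_config a [model_config()]; defaults to a compact
#'   configuration derived from the data.
#' @param split a [split_spec()].
#' @param stage1 a [stage1_config()].
#' @param distill a [distill_config()].
#' @param seeds integer vector of shared seeds.
#' @param window_ms,stride_ms,filter segmentation and filtering parameters.
#' @param teacher_filters pose-teacher width.
#' @param out_csv optional path; when given the result table is written as
#'   CSV.
#' @param verbose print progress.
#' @return data.frame with one row per scheme (`scheme`, `mean_accuracy`,
#'   one column per seed); attributes `stage1_diagnostics` (per-seed cosine
#'   similarities) and `losses_used` (per scheme).
#' @export
run_ablation <- function(dataset, model_config = NULL, split = split_preset("db2"),
                         stage1 = stage1_config(epochs = 3L),
                         distill = distill_config(epochs = 8L),
                         seeds = c(1L, 2L, 3L), window_ms = 200, stride_ms = 100,
                         filter = "rms", teacher_filters = 8L,
                         out_csv = NULL, verbose = FALSE) {
  trials <- if (inherits(dataset, "semg_dataset")) dataset$trials else dataset
  prep <- preprocess_trials(trials, filter)
  if (is.null(model_config)) {
    model_config <- default_model_config(prep, window_ms)
  }
  train_trials <- Filter(function(tr) tr$trial_index %in% split$training_trials, prep)
  windows <- prepare_windows_from_preprocessed(prep, window_ms, stride_ms)
  parts <- cross_trial_split(windows, split)
  schemes <- c("scratch", "stage1_only", "stage2_only", "two_stage")
  accs <- matrix(NA_real_, length(schemes), length(seeds),
                 dimnames = list(schemes, paste0("seed", seeds)))
  diag_rows <- list()
  losses_used <- list()
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    if (verbose) message("ablation seed ", seed)
    s1 <- train_stage1(train_trials, model_config, stage1, window_ms,
                       stride_ms, seed = seed, verbose = verbose)
    init_model <- semgxcm_at_init(model_config, seed)
    diag_rows[[si]] <- data.frame(
      seed = seed,
      cosine_init = trial_invariance_score(init_model, train_trials,
                                           window_ms, stride_ms),
      cosine_stage1 = trial_invariance_score(s1$model, train_trials,
                                             window_ms, stride_ms),
      relative_init = trial_invariance_score(init_model, train_trials,
                                             window_ms, stride_ms,
                                             relative = TRUE),
      relative_stage1 = trial_invariance_score(s1$model, train_trials,
                                               window_ms, stride_ms,
                                               relative = TRUE))
    teacher <- train_teacher(parts$train, config = distill,
                             n_gestures = model_config$n_gestures,
                             filters = teacher_filters, seed = seed)
    cfg_ce <- distill
    cfg_ce$alpha <- 0
    fits <- list(
      scratch = train_student_stage2(parts$train, model_config,
                                     teacher = NULL, init = NULL,
                                     config = cfg_ce, seed = seed,
                                     verbose = verbose),
      stage1_only = train_student_stage2(parts$train, model_config,
                                         teacher = NULL, init = s1,
                                         config = cfg_ce, seed = seed,
                                         verbose = verbose),
      stage2_only = train_student_stage2(parts$train, model_config,
                                         teacher = teacher, init = NULL,
                                         config = distill, seed = seed,
                                         verbose = verbose),
      two_stage = train_student_stage2(parts$train, model_config,
                                       teacher = teacher, init = s1,
                                       config = distill, seed = seed,
                                       verbose = verbose))
    for (sc in schemes) {
      accs[sc, si] <- evaluate_model(fits[[sc]]$model, parts$test)$mean_accuracy
      losses_used[[sc]] <- fits[[sc]]$losses_used
    }
  }
  res <- data.frame(scheme = schemes, mean_accuracy = rowMeans(accs),
                    accs, row.names = NULL)
  attr(res, "stage1_diagnostics") <- do.call(rbind, diag_rows)
  attr(res, "losses_used") <- losses_used
  if (!is.null(out_csv)) {
    utils::write.csv(res, out_csv, row.names = FALSE)
  }
  res
}

# encoder parameters exactly at Xavier initialization for a given seed
semgxcm_at_init <- function(model_config, seed) {
  set.seed(seed)
  semgxcm_new(model_config)
}

default_model_config <- function(prep_trials, window_ms) {
  tr <- prep_trials[[1]]
  W <- max(1L, round(window_ms * tr$sampling_rate / 1000))
  N <- max(vapply(prep_trials, `[[`, integer(1), "gesture_id"))
  model_config(n_channels = ncol(tr$samples), window_len = W, n_gestures = N)
}

# segmentation of already-preprocessed trials (with alignment)
prepare_windows_from_preprocessed <- function(prep, window_ms, stride_ms) {
  groups <- split(prep, vapply(prep, function(tr) {
    paste(tr$subject_id, tr$gesture_id)
  }, character(1)))
  trials <- unlist(lapply(groups, function(g) {
    if (length(g) >= 2) align_trials(g) else g
  }), recursive = FALSE)
  combine_window_sets(lapply(trials, segment_windows, window_ms = window_ms,
                             stride_ms = stride_ms))
}
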