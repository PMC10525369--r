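# Stage 2: supervised pose-teacher training and cross-modal knowledge
# distillation into the stage-1-initialized sEMG student.

#' Mean cross-entropy classification loss
#'
#' @param logits numeric matrix (B x N) of pre-softmax scores.
#' @param labels integer vector in `1..N`.
#' @return scalar mean `-log softmax(logits)[label]` (nonnegative).
#' @export
cross_entropy_loss <- function(logits, labels) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  N <- ncol(logits)
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > N)) {
    stop(sprintf("labels must lie in 1..%d", N))
  }
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), labels)])
}

#' Temperature-scaled softmax
#'
#' `p_c = exp(z_c / T) / sum_j exp(z_j / T)`; invariant to adding a constant
#' to all logits, uniform in the limit `T -> Inf`.
#'
#' @param z numeric vector of logits, or a matrix of per-row logits.
#' @param temperature positive temperature T.
#' @return probabilities, same shape as `z`.
#' @export
tempered_softmax <- function(z, temperature = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (is.null(dim(z))) {
    s <- z / temperature
    e <- exp(s - max(s))
    return(e / sum(e))
  }
  s <- z / temperature
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

#' Knowledge-distillation KL divergence loss
#'
#' Mean over the batch of `KL(p || q)` where `p` and `q` are the
#' temperature-scaled softmax distributions of the teacher and student
#' logits. Nonnegative; zero iff the tempered distributions coincide.
#'
#' @param teacher_logits,student_logits numeric matrices (B x N).
#' @param temperature softmax temperature T.
#' @return scalar loss.
#' @export
kd_kl_loss <- function(teacher_logits, student_logits, temperature = 1) {
  if (is.null(dim(teacher_logits))) teacher_logits <- matrix(teacher_logits, nrow = 1L)
  if (is.null(dim(student_logits))) student_logits <- matrix(student_logits, nrow = 1L)
  if (!identical(dim(teacher_logits), dim(student_logits))) {
    stop("teacher and student logits must have identical shapes")
  }
  p <- tempered_softmax(teacher_logits, temperature)
  sq <- student_logits / temperature
  logq <- sq - (apply(sq, 1L, max) + log(rowSums(exp(sq - apply(sq, 1L, max)))))
  logp <- log(pmax(p, 1e-300))
  mean(rowSums(p * (logp - logq)))
}

#' Overall distillation objective
#'
#' Convex combination `(1 - alpha) * ce + alpha * kl`.
#'
#' @param ce classification (cross-entropy) loss.
#' @param kl distillation (KL divergence) loss.
#' @param alpha balance weight in `[0, 1]`.
#' @return scalar.
#' @export
overall_loss <- function(ce, kl, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  (1 - alpha) * ce + alpha * kl
}

#' Distillation configuration
#'
#' @param temperature softmax temperature T (default 1).
#' @param alpha balance weight of the KL term in `[0, 1]`.
#' @param epochs training epochs.
#' @param lr initial SGD learning rate.
#' @param lr_drop_epochs epochs at which the learning rate is multiplied by
#'   `lr_factor`.
#' @param lr_factor multiplicative learning-rate decay.
#' @param batch_size minibatch size.
#' @return list of class `distill_config`.
#' @export
distill_config <- function(temperature = 1, alpha = 0.5, epochs = 28L,
                           lr = 0.1, lr_drop_epochs = c(16L, 24L),
                           lr_factor = 0.1, batch_size = 128L) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  stopifnot(epochs >= 0, lr > 0, batch_size >= 2)
  structure(list(temperature = temperature, alpha = alpha,
                 epochs = as.integer(epochs), lr = lr,
                 lr_drop_epochs = as.integer(lr_drop_epochs),
                 lr_factor = lr_factor, batch_size = as.integer(batch_size)),
            class = "distill_config")
}

lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_factor^sum(epoch >= cfg$lr_drop_epochs)
}

ce_nodes <- function(logits, labels) {
  ls <- ag_log_softmax(logits)
  ag_neg(ag_mean(ag_pick(ls, labels)))
}

# KL(p_const || softmax(logits / T)) as a node in the student's logits
kd_nodes <- function(teacher_probs, student_logits, temperature) {
  logq <- ag_log_softmax(ag_cmul(student_logits, 1 / temperature))
  plogp <- sum(teacher_probs * log(pmax(teacher_probs, 1e-300))) / nrow(teacher_probs)
  cross <- ag_cmul(ag_sum(ag_mul(logq, ag_const(teacher_probs))),
                   1 / nrow(teacher_probs))
  ag_cadd(ag_neg(cross), plogp)
}

#' Train the hand-pose teacher network
#'
#' Supervised training of the reduced XceptionTime-style pose classifier
#' with SGD and the step learning-rate schedule. Deterministic given `seed`.
#'
#' @param windows a `window_set` carrying pose windows (`$pose`), or a
#'   `W x D x n` pose array.
#' @param labels integer gesture labels (1-based); taken from the window
#'   metadata when `windows` is a `window_set`.
#' @param n_gestures number of classes.
#' @param filters filters per convolution branch.
#' @param config a [distill_config()] (its `alpha`/`temperature` are unused
#'   here; the optimizer settings apply).
#' @param seed RNG seed.
#' @param verbose print per-epoch loss.
#' @return object of class `teacher_fit`: `model`, `history`, `seed`.
#' @export
train_teacher <- function(windows, labels = NULL, n_gestures = NULL,
                          filters = 8L, config = distill_config(),
                          seed = 1L, verbose = FALSE) {
  if (inherits(windows, "window_set")) {
    if (is.null(windows$pose)) stop("window_set carries no pose windows")
    labels <- windows$meta$gesture_id
    pose <- windows$pose
  } else {
    pose <- windows
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("teacher training needs at least two gesture classes")
  }
  if (is.null(n_gestures)) n_gestures <- max(labels)
  W <- dim(pose)[1]
  D <- dim(pose)[2]
  n <- dim(pose)[3]
  set.seed(seed)
  model <- pose_teacher_new(D, n_gestures, filters = filters)
  history <- data.frame()
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample.int(n)
    nb <- max(1L, n %/% config$batch_size)
    eploss <- 0
    used <- 0L
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * config$batch_size + 1L):min(n, b * config$batch_size)]
      X <- batch_to_rows(pose[, , idx, drop = FALSE])
      attr(X, "window_len") <- W
      ag_reset()
      out <- pose_teacher_nodes(model, X, training = TRUE)
      loss <- ce_nodes(out$logits, labels[idx])
      ps <- collect_params(model)
      ag_zero_grad(ps)
      ag_backward(loss)
      ag_sgd_step(ps, lr)
      eploss <- eploss + loss$value[1]
      used <- used + 1L
      ag_reset()
    }
    history <- rbind(history, data.frame(epoch = epoch, ce = eploss / used, lr = lr))
    if (verbose) message(sprintf("teacher epoch %d: ce %.4f", epoch, eploss / used))
  }
  structure(list(model = model, history = history, seed = seed),
            class = "teacher_fit")
}

#' Train the sEMG student with cross-modal knowledge distillation
#'
#' Minimizes `(1 - alpha) * CE + alpha * KL` where the KL term compares the
#' frozen teacher's tempered softmax on the pose window covering the same
#' sample interval as each sEMG window against the student's. With
#' `alpha = 0` (or `teacher = NULL`) this reduces exactly to supervised
#' fine-tuning with cross-entropy; with `init = NULL` the encoder starts
#' from Xavier initialization (training from scratch / stage-2-only).
#'
#' @param windows a `window_set` of labelled training windows; must carry
#'   pose windows when `alpha > 0`.
#' @param model_config a [model_config()].
#' @param teacher a `teacher_fit` or `pose_teacher` (frozen), or `NULL`.
#' @param init a `stage1_fit` or `semgxcm_model` providing the initial
#'   encoder parameters, or `NULL` for Xavier initialization.
#' @param config a [distill_config()].
#' @param seed RNG seed.
#' @param verbose print per-epoch losses.
#' @return object of class `stage2_fit`: `model`, `history` (per-epoch mean
#'   ce/kl/overall and training accuracy), `losses_used`, configs, seed.
#' @export
train_student_stage2 <- function(windows, model_config, teacher = NULL,
                                 init = NULL, config = distill_config(),
                                 seed = 1L, verbose = FALSE) {
  stopifnot(inherits(windows, "window_set"))
  alpha <- config$alpha
  if (alpha > 0) {
    if (is.null(teacher)) stop("alpha > 0 requires a trained teacher")
    if (is.null(windows$pose)) {
      stop("alpha > 0 requires pose windows aligned to the sEMG windows")
    }
    if (!identical(dim(windows$pose)[c(1, 3)], dim(windows$values)[c(1, 3)])) {
      stop("pose windows are misaligned with the sEMG windows")
    }
  }
  tmodel <- if (inherits(teacher, "teacher_fit")) teacher$model else teacher
  labels <- as.integer(windows$meta$gesture_id)
  n <- n_windows(windows)
  W <- windows$window_len
  set.seed(seed)
  model <- semgxcm_new(model_config)
  if (!is.null(init)) {
    src <- if (inherits(init, "stage1_fit")) init$model else init
    set_weights(model, get_weights(src))
  }
  history <- data.frame()
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample.int(n)
    nb <- max(1L, n %/% config$batch_size)
    ep <- c(ce = 0, kl = 0, overall = 0, acc = 0)
    used <- 0L
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * config$batch_size + 1L):min(n, b * config$batch_size)]
      X <- batch_to_rows(windows$values[, , idx, drop = FALSE])
      # teacher logits are plain numbers (frozen teacher, evaluation mode);
      # computed before the student graph since the forward clears the tape
      tprobs <- NULL
      if (alpha > 0) {
        tl <- pose_teacher_forward(tmodel,
                                   windows$pose[, , idx, drop = FALSE])$logits
        tprobs <- tempered_softmax(tl, config$temperature)
      }
      ag_reset()
      out <- semgxcm_nodes(model, X, training = TRUE)
      ce <- ce_nodes(out$logits, labels[idx])
      kl_val <- 0
      if (alpha > 0) {
        kl <- kd_nodes(tprobs, out$logits, config$temperature)
        loss <- ag_add(ag_cmul(ce, 1 - alpha), ag_cmul(kl, alpha))
        kl_val <- kl$value[1]
      } else {
        loss <- ce
      }
      ps <- collect_params(model)
      ag_zero_grad(ps)
      ag_backward(loss)
      ag_sgd_step(ps, lr)
      pred <- max.col(out$logits$value, ties.method = "first")
      ep <- ep + c(ce = ce$value[1], kl = kl_val,
                   overall = loss$value[1],
                   acc = mean(pred == labels[idx]))
      used <- used + 1L
      ag_reset()
    }
    ep <- ep / used
    history <- rbind(history, data.frame(epoch = epoch, t(ep), lr = lr))
    if (verbose) {
      message(sprintf("stage2 epoch %d: ce %.4f kl %.4f acc %.3f",
                      epoch, ep["ce"], ep["kl"], ep["acc"]))
    }
  }
  structure(list(model = model, history = history,
                 losses_used = if (alpha > 0) c("ce", "kl") else "ce",
                 model_config = model_config, config = config, seed = seed),
            class = "stage2_fit")
}
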