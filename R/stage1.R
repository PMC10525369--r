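# Stage 1: cross-trial mutual-information maximization with disentanglement.
#
# The encoder is trained to (a) maximize an InfoNCE lower bound between two
# views of the same window (self term) and between the gesture-relevant
# representations of cross-trial pairs (cross-trial term), and (b) minimize
# a CLUB upper bound on I(u; v) so the gesture-relevant and trial-relevant
# factors disentangle. The variational conditional q(v|u) is a diagonal
# Gaussian predicted by the likelihood estimator Q, fitted by maximum
# likelihood in alternation with the encoder.

infonce_logits <- function(a, b, temperature) {
  an <- a / (sqrt(rowSums(a^2)) + 1e-12)
  bn <- b / (sqrt(rowSums(b^2)) + 1e-12)
  (an %*% t(bn)) / temperature
}

#' InfoNCE lower bound on mutual information
#'
#' Contrastive estimate `log B - CE`, where CE is the mean cross-entropy of
#' classifying each anchor's own positive among the batch using
#' cosine-similarity logits scaled by `1/temperature`. The estimate never
#' exceeds `log B`; it is close to 0 when anchors and positives are
#' independent.
#'
#' @param anchor,positive numeric matrices (B x d) of paired representations.
#' @param temperature positive similarity temperature.
#' @return scalar mutual-information lower-bound estimate (in nats).
#' @export
infonce_bound <- function(anchor, positive, temperature = 0.1) {
  B <- nrow(anchor)
  if (is.null(B) || B < 2) stop("infonce_bound needs a batch of size >= 2")
  stopifnot(nrow(positive) == B, temperature > 0)
  lg <- infonce_logits(anchor, positive, temperature)
  mx <- apply(lg, 1L, max)
  lse <- mx + log(rowSums(exp(lg - mx)))
  ce <- mean(lse - diag(lg))
  log(B) - ce
}

# node version: anchor/positive representation nodes -> scalar bound node
infonce_nodes <- function(anchor, positive, temperature) {
  B <- nrow(anchor$value)
  an <- ag_l2normalize_rows(anchor)
  pn <- ag_l2normalize_rows(positive)
  lg <- ag_cmul(ag_mm(an, ag_t(pn)), 1 / temperature)
  ls <- ag_log_softmax(lg)
  diag_ll <- ag_pick(ls, seq_len(B))
  ag_cadd(ag_mean(diag_ll), log(B))
}

#' CLUB upper bound on I(u; v)
#'
#' Contrastive log-ratio upper bound: mean log-likelihood of matched (u, v)
#' pairs under the variational Gaussian q(v|u) minus the mean over mismatched
#' pairs formed by an in-batch index shuffle (self-matches allowed, i.e. an
#' unbiased sample from the product of marginals).
#'
#' @param u,v numeric matrices (B x d).
#' @param q a `q_net` (see [q_net_new()]).
#' @param shuffle optional integer permutation of `1:B` for the mismatched
#'   pairs; drawn uniformly from the current RNG stream when `NULL`.
#' @return scalar estimate of I(u; v) (an upper bound for a well-fitted q).
#' @export
club_upper_bound <- function(u, v, q, shuffle = NULL) {
  B <- nrow(u)
  if (is.null(B) || B < 2) stop("club_upper_bound needs a batch of size >= 2")
  stopifnot(nrow(v) == B)
  if (is.null(shuffle)) shuffle <- sample.int(B)
  pred <- likelihood_estimator_q(q, u)
  pos <- gaussian_log_density(v, pred$mean, pred$logvar)
  neg <- gaussian_log_density(v[shuffle, , drop = FALSE], pred$mean, pred$logvar)
  mean(pos) - mean(neg)
}

# node version with Q frozen (encoder step); gradients flow into u, v only
club_nodes_frozen <- function(u, v, q, shuffle) {
  d <- q$d
  h <- ag_relu(ag_add(ag_mm(u, ag_const(q$f1$W$value)), ag_const(q$f1$b$value)))
  out <- ag_add(ag_mm(h, ag_const(q$f2$W$value)), ag_const(q$f2$b$value))
  mu <- ag_cols(out, seq_len(d))
  lv <- ag_cols(out, d + seq_len(d))
  B <- nrow(v$value)
  dd <- ncol(v$value)
  vshuf <- ag_gather(v, gather_plan(idx_row_shuffle(B, dd, shuffle), B * dd),
                     c(B, dd))
  pos <- gaussian_logq_nodes(mu, lv, v)
  neg <- gaussian_logq_nodes(mu, lv, vshuf)
  ag_sub(ag_mean(pos), ag_mean(neg))
}

idx_row_shuffle <- function(B, d, shuffle) {
  # out[i, j] <- v[shuffle[i], j]
  as.integer(rep(shuffle, d) + (rep(seq_len(d), each = B) - 1L) * B)
}

#' Gaussian negative log-likelihood fitting loss for Q
#'
#' Mean negative log-density of `v` under the diagonal Gaussian `q(v|u)`
#' predicted by Q; minimizing it in Q's parameters is the maximum-likelihood
#' surrogate for minimizing KL(q(v|u) || p(v|u)).
#'
#' @inheritParams club_upper_bound
#' @return scalar mean negative log-likelihood.
#' @export
q_fit_loss <- function(u, v, q) {
  pred <- likelihood_estimator_q(q, u)
  -mean(gaussian_log_density(v, pred$mean, pred$logvar))
}

q_fit_nodes <- function(u_const, v_const, q) {
  pred <- q_nodes(q, u_const)
  ag_neg(ag_mean(gaussian_logq_nodes(pred$mean, pred$logvar, v_const)))
}

# one gradient step of Q on a detached (u, v) batch
q_fit_step <- function(q, u, v, lr) {
  ag_reset()
  loss <- q_fit_nodes(ag_const(u), ag_const(v), q)
  qp <- collect_params(q)
  ag_zero_grad(qp)
  ag_backward(loss)
  ag_sgd_step(qp, lr)
  val <- loss$value[1]
  ag_reset()
  val
}

#' Fit Q to a fixed sample by gradient descent
#'
#' Used for calibrating the CLUB estimator on data with known mutual
#' information, and internally by stage-1 training.
#'
#' @param u,v numeric matrices (n x d).
#' @param q a `q_net`; modified in place (environments) and returned.
#' @param iters full-batch gradient steps.
#' @param lr learning rate.
#' @return `q`, fitted.
#' @export
q_fit <- function(u, v, q, iters = 200L, lr = 0.05) {
  for (i in seq_len(iters)) q_fit_step(q, u, v, lr)
  q
}

#' Stage-1 configuration
#'
#' @param epochs training epochs (both encoder and Q).
#' @param batch_size pair batch size.
#' @param lr_encoder,lr_q SGD learning rates of the encoder and Q.
#' @param lambda1 weight of the cross-trial InfoNCE term.
#' @param lambda2 weight of the CLUB disentanglement penalty.
#' @param temperature InfoNCE similarity temperature.
#' @param augment_sd sd of the channel-independent Gaussian jitter used to
#'   form the two views of a window for the self term.
#' @param q_hidden hidden width of the likelihood estimator Q.
#' @return list of class `stage1_config`.
#' @export
stage1_config <- function(epochs = 30L, batch_size = 128L, lr_encoder = 0.001,
                          lr_q = 0.005, lambda1 = 1.0, lambda2 = 0.1,
                          temperature = 0.1, augment_sd = 0.01,
                          q_hidden = 64L) {
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")
  stopifnot(batch_size >= 2, temperature > 0, epochs >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_encoder = lr_encoder, lr_q = lr_q, lambda1 = lambda1,
                 lambda2 = lambda2, temperature = temperature,
                 augment_sd = augment_sd, q_hidden = as.integer(q_hidden)),
            class = "stage1_config")
}

# batch (anchor X, positive X row-major matrices) -> loss nodes + components
stage1_batch_nodes <- function(model, q, Xa, Xp, cfg) {
  jitter <- function(X) X + matrix(stats::rnorm(length(X), 0, cfg$augment_sd),
                                   nrow(X), ncol(X))
  e1 <- semgxcm_nodes(model, jitter(Xa), training = TRUE)
  p1 <- proj_nodes(model, e1$pooled)
  e2 <- semgxcm_nodes(model, jitter(Xa), training = TRUE)
  p2 <- proj_nodes(model, e2$pooled)
  ep <- semgxcm_nodes(model, Xp, training = TRUE)
  pp <- proj_nodes(model, ep$pooled)
  B <- e1$B
  mi_self <- infonce_nodes(ag_cbind(p1$u, p1$v), ag_cbind(p2$u, p2$v),
                           cfg$temperature)
  mi_cross <- infonce_nodes(p1$u, pp$u, cfg$temperature)
  shuffle <- sample.int(B)
  l_inter <- club_nodes_frozen(p1$u, p1$v, q, shuffle)
  total <- ag_add(ag_cmul(ag_add(mi_self, ag_cmul(mi_cross, cfg$lambda1)), -1),
                  ag_cmul(l_inter, cfg$lambda2))
  list(total = total, mi_self = mi_self, mi_cross = mi_cross,
       l_inter = l_inter, u = p1$u$value, v = p1$v$value)
}

#' Stage-1 total loss on one pair batch
#'
#' Computes the combined encoder objective
#' `-(mi_self + lambda1 * mi_cross) + lambda2 * l_inter` together with its
#' components and Q's current fitting loss, without updating any parameters.
#'
#' @param model a `semgxcm_model`.
#' @param q a `q_net` of matching representation dimension.
#' @param pairs a `pair_set` (or a batch subset of one).
#' @param config a [stage1_config()].
#' @return list with `total` and a `losses` list
#'   (mi_self, mi_cross, l_inter, l_kl_q, lambda1, lambda2).
#' @export
stage1_total_loss <- function(model, q, pairs, config = stage1_config()) {
  Xa <- batch_to_rows(pairs$anchor)
  Xp <- batch_to_rows(pairs$positive)
  ag_reset()
  nodes <- stage1_batch_nodes(model, q, Xa, Xp, config)
  l_kl_q <- q_fit_loss(nodes$u, nodes$v, q)
  res <- list(total = nodes$total$value[1],
              losses = list(mi_self = nodes$mi_self$value[1],
                            mi_cross = nodes$mi_cross$value[1],
                            l_inter = nodes$l_inter$value[1],
                            l_kl_q = l_kl_q,
                            lambda1 = config$lambda1, lambda2 = config$lambda2))
  ag_reset()
  res
}

#' Train the sEMG encoder by cross-trial mutual-information maximization
#'
#' Builds a Xavier-initialized encoder and likelihood estimator Q and trains
#' them in alternation with SGD: per batch, one encoder step on the combined
#' InfoNCE/CLUB objective (with Q frozen), then one maximum-likelihood step
#' of Q on the detached representations. Cross-trial pairs are resampled
#' every epoch. Deterministic given `seed`.
#'
#' @param trials preprocessed `emg_trial` list (training trials only) or a
#'   `semg_dataset`.
#' @param model_config a [model_config()].
#' @param config a [stage1_config()].
#' @param window_ms,stride_ms segmentation parameters for pair sampling.
#' @param seed integer RNG seed.
#' @param verbose print per-epoch losses.
#' @return object of class `stage1_fit`: `model`, `q`, `history`
#'   (per-epoch mean losses), configs and seed.
#' @export
train_stage1 <- function(trials, model_config, config = stage1_config(),
                         window_ms = 200, stride_ms = 100, seed = 1L,
                         verbose = FALSE) {
  if (inherits(trials, "semg_dataset")) trials <- trials$trials
  set.seed(seed)
  model <- semgxcm_new(model_config)
  q <- q_net_new(model_config$representation_dim, config$q_hidden)
  history <- data.frame()
  for (epoch in seq_len(config$epochs)) {
    pairs <- sample_pairs(trials, window_ms, stride_ms)
    n <- nrow(pairs$meta)
    ord <- sample.int(n)
    nb <- max(1L, n %/% config$batch_size)
    ep <- c(total = 0, mi_self = 0, mi_cross = 0, l_inter = 0, l_kl_q = 0)
    used <- 0L
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * config$batch_size + 1L):min(n, b * config$batch_size)]
      if (length(idx) < 2) next
      Xa <- batch_to_rows(pairs$anchor[, , idx, drop = FALSE])
      Xp <- batch_to_rows(pairs$positive[, , idx, drop = FALSE])
      ag_reset()
      nodes <- stage1_batch_nodes(model, q, Xa, Xp, config)
      mp <- collect_params(model)
      ag_zero_grad(mp)
      ag_backward(nodes$total)
      ag_sgd_step(mp, config$lr_encoder)
      vals <- c(total = nodes$total$value[1], mi_self = nodes$mi_self$value[1],
                mi_cross = nodes$mi_cross$value[1],
                l_inter = nodes$l_inter$value[1])
      u <- nodes$u; v <- nodes$v
      ag_reset()
      lq <- q_fit_step(q, u, v, config$lr_q)
      ep <- ep + c(vals, l_kl_q = lq)
      used <- used + 1L
    }
    ep <- ep / max(1L, used)
    history <- rbind(history, data.frame(epoch = epoch, t(ep)))
    if (verbose) {
      message(sprintf(
        "stage1 epoch %d: total %.4f (self %.4f cross %.4f inter %.4f klq %.4f)",
        epoch, ep["total"], ep["mi_self"], ep["mi_cross"], ep["l_inter"],
        ep["l_kl_q"]))
    }
  }
  structure(list(model = model, q = q, history = history,
                 model_config = model_config, config = config, seed = seed),
            class = "stage1_fit")
}

#' Cross-trial invariance of the gesture-relevant representation
#'
#' Mean cosine similarity between `u` of anchor windows and `u` of positive
#' windows (same subject, gesture and time step, different trial), in
#' evaluation mode. Higher values mean more trial-invariant representations.
#'
#' @param model a `semgxcm_model`.
#' @param trials preprocessed trials.
#' @param window_ms,stride_ms segmentation parameters.
#' @param seed seed for the pair sampling.
#' @param max_pairs subsample cap for speed.
#' @param relative when `TRUE`, return the matched-pair cosine minus the
#'   mean cosine over mismatched (randomly re-paired) windows — the
#'   alignment of matched time steps relative to the overall representation
#'   geometry, which is insensitive to a common-mode (collapsed) component.
#' @return scalar mean cosine similarity (or relative similarity).
#' @export
trial_invariance_score <- function(model, trials, window_ms = 200,
                                   stride_ms = 100, seed = 99L,
                                   max_pairs = 512L, relative = FALSE) {
  pairs <- sample_pairs(trials, window_ms, stride_ms, seed = seed)
  n <- nrow(pairs$meta)
  idx <- if (n > max_pairs) {
    with_local_seed(seed, sample.int(n, max_pairs))
  } else seq_len(n)
  ua <- projection_heads(model, semgxcm_forward(
    model, pairs$anchor[, , idx, drop = FALSE])$pooled)$u
  up <- projection_heads(model, semgxcm_forward(
    model, pairs$positive[, , idx, drop = FALSE])$pooled)$u
  una <- ua / (sqrt(rowSums(ua^2)) + 1e-12)
  unp <- up / (sqrt(rowSums(up^2)) + 1e-12)
  matched <- mean(rowSums(una * unp))
  if (!relative) return(matched)
  shuf <- with_local_seed(seed + 1L, sample.int(nrow(unp)))
  matched - mean(rowSums(una * unp[shuf, , drop = FALSE]))
}
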