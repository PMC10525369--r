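#' Model configuration for the dual-stream sEMG classifier
#'
#' Collects the architectural hyperparameters of the windowed sEMG classifier:
#' a temporal stream (two 1D convolution blocks over time with the electrodes
#' as input channels), a spatial stream (two 2D convolutions followed by two
#' 1x1 locally connected layers applied to the W x C window viewed as a
#' one-channel image), feature fusion by per-time-position concatenation, a
#' multi-head self-attention layer with residual connection and position-wise
#' feedforward, a further 1D convolution block, global average pooling over
#' time and an affine map to gesture logits.
#'
#' @param n_channels number of electrodes C.
#' @param window_len window length W in samples.
#' @param n_gestures number of gesture classes N (>= 2).
#' @param representation_dim length d of the disentangled gesture-relevant
#'   (u) and trial-relevant (v) projection-head outputs.
#' @param attention_heads number of self-attention heads.
#' @param temporal_filters filters per 1D convolution block.
#' @param spatial_filters filters per 2D convolution / locally connected layer.
#' @param dropout dropout probability in the spatial stream.
#' @param temporal_kernel temporal extent of the 1D kernels; default is W/2
#'   rounded to the nearest odd integer.
#' @param head_dim per-head attention dimension; default ceiling(D/heads)
#'   where D is the fused feature dimension, so heads always divide the
#'   attention embedding dimension heads * head_dim.
#' @param ff_dim hidden width of the position-wise feedforward layer
#'   (default 2 * D).
#' @return an object of class `semgxcm_config`.
#' @export
model_config <- function(n_channels, window_len, n_gestures,
                         representation_dim = 128L, attention_heads = 4L,
                         temporal_filters = 64L, spatial_filters = 64L,
                         dropout = 0.5, temporal_kernel = NULL,
                         head_dim = NULL, ff_dim = NULL) {
  stopifnot(n_channels >= 1, window_len >= 2, n_gestures >= 2,
            representation_dim >= 1, attention_heads >= 1,
            temporal_filters >= 1, spatial_filters >= 1,
            dropout >= 0, dropout < 1)
  if (is.null(temporal_kernel)) {
    temporal_kernel <- window_len %/% 2L
    if (temporal_kernel %% 2L == 0L) temporal_kernel <- temporal_kernel + 1L
    temporal_kernel <- max(1L, min(temporal_kernel, window_len))
  }
  if (temporal_kernel %% 2L != 1L) stop("temporal_kernel must be odd")
  fused <- temporal_filters + n_channels * spatial_filters
  if (is.null(head_dim)) head_dim <- as.integer(ceiling(fused / attention_heads))
  if (is.null(ff_dim)) ff_dim <- 2L * fused
  structure(list(
    n_channels = as.integer(n_channels), window_len = as.integer(window_len),
    n_gestures = as.integer(n_gestures),
    representation_dim = as.integer(representation_dim),
    attention_heads = as.integer(attention_heads),
    temporal_filters = as.integer(temporal_filters),
    spatial_filters = as.integer(spatial_filters),
    dropout = dropout, temporal_kernel = as.integer(temporal_kernel),
    head_dim = as.integer(head_dim), ff_dim = as.integer(ff_dim),
    fused_dim = as.integer(fused)
  ), class = "semgxcm_config")
}

#' Number of parameters in the self-attention layer implied by a config
#'
#' The fused feature dimension grows linearly with the electrode count, and
#' with it the query/key/value/output projections of the attention layer, so
#' this count increases with `n_channels`.
#'
#' @param config a `semgxcm_config`.
#' @return integer parameter count of the attention layer.
#' @export
attention_n_params <- function(config) {
  attn_n_params(config$fused_dim, config$attention_heads, config$head_dim)
}

#' Build a dual-stream sEMG window classifier
#'
#' Instantiates all layers with Xavier-uniform initial weights drawn from the
#' current R RNG state (seed before calling for reproducibility).
#'
#' @param config a `semgxcm_config` from [model_config()].
#' @return an object of class `semgxcm_model`.
#' @export
semgxcm_new <- function(config) {
  stopifnot(inherits(config, "semgxcm_config"))
  C <- config$n_channels; W <- config$window_len
  Ft <- config$temporal_filters; Fs <- config$spatial_filters
  D <- config$fused_dim; k <- config$temporal_kernel
  m <- list(
    config = config,
    tconv1 = conv1d_new(C, Ft, k), tbn1 = bn_new(Ft),
    tconv2 = conv1d_new(Ft, Ft, k), tbn2 = bn_new(Ft),
    sconv1 = conv2d_new(1L, Fs), sbn1 = bn_new(Fs),
    sconv2 = conv2d_new(Fs, Fs), sbn2 = bn_new(Fs),
    slc1 = lc1x1_new(W * C, Fs, Fs),
    slc2 = lc1x1_new(W * C, Fs, Fs),
    fbn = bn_new(D),
    attn = attn_new(D, config$attention_heads, config$head_dim),
    ff = ff_new(D, config$ff_dim),
    pconv = conv1d_new(D, Ft, k), pbn = bn_new(Ft),
    cls = dense_new(Ft, config$n_gestures),
    head_u = dense_new(Ft, config$representation_dim),
    head_v = dense_new(Ft, config$representation_dim)
  )
  class(m) <- "semgxcm_model"
  m
}

idx_to_image <- function(B, W, C) {
  idx_cached(sprintf("img_%d_%d_%d", B, W, C), function() {
    # output (B*W*C) x 1, row (b-1)*W*C + (w-1)*C + c <- x[(b-1)*W + w, c]
    r <- seq_len(B * W * C)
    b <- (r - 1L) %/% (W * C) + 1L
    rem <- (r - 1L) %% (W * C)
    w <- rem %/% C + 1L
    c <- rem %% C + 1L
    gather_plan(as.integer((b - 1L) * W + w + (c - 1L) * (B * W)), B * W * C)
  })
}

idx_collapse_electrodes <- function(B, W, C, Fs) {
  idx_cached(sprintf("col_%d_%d_%d_%d", B, W, C, Fs), function() {
    # output (B*W) x (C*Fs): (r=(b-1)*W+w, j=(c-1)*Fs+f) <- image row, feature f
    g <- expand.grid(r = seq_len(B * W), j = seq_len(C * Fs))
    b <- (g$r - 1L) %/% W + 1L
    w <- (g$r - 1L) %% W + 1L
    c <- (g$j - 1L) %/% Fs + 1L
    f <- (g$j - 1L) %% Fs + 1L
    gather_plan(
      as.integer((b - 1L) * W * C + (w - 1L) * C + c + (f - 1L) * (B * W * C)),
      B * W * C * Fs)
  })
}

# tape-level forward; X is the (B*W) x C row-major batch matrix
semgxcm_nodes <- function(model, X, training = FALSE) {
  cfg <- model$config
  C <- cfg$n_channels; W <- cfg$window_len; Fs <- cfg$spatial_filters
  stopifnot(ncol(X) == C, nrow(X) %% W == 0L)
  B <- nrow(X) %/% W
  x <- ag_const(X)
  t1 <- ag_relu(bn_fwd(model$tbn1, conv1d_fwd(model$tconv1, x, B, W), training))
  t2 <- ag_relu(bn_fwd(model$tbn2, conv1d_fwd(model$tconv2, t1, B, W), training))
  ximg <- ag_gather(x, idx_to_image(B, W, C), c(B * W * C, 1L))
  s1 <- ag_relu(bn_fwd(model$sbn1, conv2d_fwd(model$sconv1, ximg, B, W, C), training))
  s2 <- ag_relu(bn_fwd(model$sbn2, conv2d_fwd(model$sconv2, s1, B, W, C), training))
  l1 <- ag_relu(lc1x1_fwd(model$slc1, s2, B))
  l2 <- ag_relu(lc1x1_fwd(model$slc2, l1, B))
  l2 <- ag_dropout(l2, cfg$dropout, training)
  sp <- ag_gather(l2, idx_collapse_electrodes(B, W, C, Fs), c(B * W, C * Fs))
  fused <- bn_fwd(model$fbn, ag_cbind(t2, sp), training)
  a <- attn_fwd(model$attn, fused, B, W)
  f <- ff_fwd(model$ff, a)
  p <- ag_relu(bn_fwd(model$pbn, conv1d_fwd(model$pconv, f, B, W), training))
  pooled <- ag_time_pool(p, B, W)
  logits <- dense_fwd(model$cls, pooled)
  list(logits = logits, pooled = pooled, B = B)
}

# convert a (W, C, B) array (or single W x C window) to the row-major batch
batch_to_rows <- function(batch) {
  if (length(dim(batch)) == 2L) dim(batch) <- c(dim(batch), 1L)
  d <- dim(batch)
  m <- aperm(batch, c(1L, 3L, 2L))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}

#' Forward pass of the dual-stream classifier
#'
#' @param model a `semgxcm_model`.
#' @param batch a `W x C` matrix (one window) or a `W x C x B` array.
#' @param training logical; `TRUE` uses batch statistics and dropout,
#'   `FALSE` (default) is the deterministic evaluation mode.
#' @return list with `logits` (B x N) and `pooled` (B x F) matrices.
#' @export
semgxcm_forward <- function(model, batch, training = FALSE) {
  X <- batch_to_rows(batch)
  ag_reset()
  out <- semgxcm_nodes(model, X, training)
  res <- list(logits = out$logits$value, pooled = out$pooled$value)
  ag_reset()
  res
}

proj_nodes <- function(model, pooled) {
  list(u = ag_tanh(dense_fwd(model$head_u, pooled)),
       v = ag_tanh(dense_fwd(model$head_v, pooled)))
}

#' Disentangling projection heads
#'
#' Maps the pooled encoder feature to a gesture-relevant representation `u`
#' and a trial-relevant representation `v` through two independent
#' affine + tanh heads of equal output length d.
#'
#' @param model a `semgxcm_model`.
#' @param pooled numeric matrix (B x F) of pooled features.
#' @return list with matrices `u` and `v`, each B x d.
#' @export
projection_heads <- function(model, pooled) {
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = 1L)
  ag_reset()
  out <- proj_nodes(model, ag_const(pooled))
  res <- list(u = out$u$value, v = out$v$value)
  ag_reset()
  res
}

#' Build the variational likelihood estimator Q
#'
#' Q predicts a diagonal Gaussian q(v|u) from u through two fully connected
#' layers; the second layer emits the concatenated mean and log-variance.
#'
#' @param d representation dimension.
#' @param hidden hidden width of the first layer.
#' @return an object of class `q_net`.
#' @export
q_net_new <- function(d, hidden = 64L) {
  m <- list(f1 = dense_new(d, hidden), f2 = dense_new(hidden, 2L * d),
            d = as.integer(d))
  class(m) <- "q_net"
  m
}

q_nodes <- function(q, u) {
  h <- ag_relu(dense_fwd(q$f1, u))
  out <- dense_fwd(q$f2, h)
  list(mean = ag_cols(out, seq_len(q$d)),
       logvar = ag_cols(out, q$d + seq_len(q$d)))
}

#' Predict the variational Gaussian q(v|u)
#'
#' @param q a `q_net`.
#' @param u numeric matrix (B x d) of gesture-relevant representations.
#' @return list with `mean` and `logvar` matrices, each B x d.
#' @export
likelihood_estimator_q <- function(q, u) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  ag_reset()
  out <- q_nodes(q, ag_const(u))
  res <- list(mean = out$mean$value, logvar = out$logvar$value)
  ag_reset()
  res
}

# per-row log density of v under diagonal Gaussians (node version)
gaussian_logq_nodes <- function(mean, logvar, v_const) {
  d <- ncol(mean$value)
  diff <- ag_sub(v_const, mean)
  sq <- ag_mul(diff, diff)
  quad <- ag_mul(sq, ag_exp(ag_neg(logvar)))
  terms <- ag_cadd(ag_add(logvar, quad), log(2 * pi))
  ones <- ag_const(matrix(1, d, 1L))
  ag_cmul(ag_mm(terms, ones), -0.5)
}

#' Log-density of v under a diagonal Gaussian
#'
#' @param v,mean,logvar numeric matrices of equal shape (B x d).
#' @return numeric vector of per-row log densities.
#' @export
gaussian_log_density <- function(v, mean, logvar) {
  rowSums(-0.5 * (logvar + (v - mean)^2 * exp(-logvar) + log(2 * pi)))
}

# ---- pose teacher (reduced XceptionTime-style) ---------------------------

#' Build the hand-pose teacher network
#'
#' A reduced XceptionTime-derived classifier for pose windows: `n_blocks`
#' Inception-style blocks, each concatenating 1D convolutions with several
#' temporal kernel sizes, batch-normalized, with a residual connection
#' (1x1 convolution where dimensions differ), followed by global average
#' pooling over time and an affine map to gesture logits.
#'
#' @param input_dim per-frame input dimension (4 * joint_count for flattened
#'   quaternion frames).
#' @param n_gestures number of gesture classes.
#' @param filters filters per convolution branch.
#' @param n_blocks number of Inception-style blocks.
#' @param kernels odd temporal kernel sizes of the parallel branches.
#' @return an object of class `pose_teacher`.
#' @export
pose_teacher_new <- function(input_dim, n_gestures, filters = 8L,
                             n_blocks = 2L, kernels = c(3L, 5L, 7L)) {
  stopifnot(input_dim >= 1, n_gestures >= 2, n_blocks >= 1,
            all(kernels %% 2L == 1L))
  width <- filters * length(kernels)
  blocks <- vector("list", n_blocks)
  din <- input_dim
  for (i in seq_len(n_blocks)) {
    blocks[[i]] <- list(
      branches = lapply(kernels, function(k) conv1d_new(din, filters, k)),
      bn = bn_new(width),
      res = if (din != width) conv1d_new(din, width, 1L) else NULL
    )
    din <- width
  }
  m <- list(blocks = blocks, cls = dense_new(width, n_gestures),
            input_dim = as.integer(input_dim), filters = as.integer(filters),
            kernels = as.integer(kernels), width = as.integer(width),
            n_gestures = as.integer(n_gestures))
  class(m) <- "pose_teacher"
  m
}

#' Analytic parameter count of the pose teacher
#'
#' @inheritParams pose_teacher_new
#' @return total number of trainable parameters (including batch-norm
#'   scale/shift).
#' @export
pose_teacher_n_params <- function(input_dim, n_gestures, filters = 8L,
                                  n_blocks = 2L, kernels = c(3L, 5L, 7L)) {
  width <- filters * length(kernels)
  total <- 0
  din <- input_dim
  for (i in seq_len(n_blocks)) {
    total <- total + sum(kernels * din * filters + filters)  # branches
    total <- total + 2 * width                               # batch norm
    if (din != width) total <- total + din * width + width   # residual 1x1
    din <- width
  }
  total + dense_n_params(width, n_gestures)
}

pose_teacher_nodes <- function(model, X, training = FALSE) {
  stopifnot(ncol(X) == model$input_dim)
  x <- ag_const(X)
  din <- model$input_dim
  B <- NULL
  W <- attr(X, "window_len")
  stopifnot(!is.null(W), nrow(X) %% W == 0L)
  B <- nrow(X) %/% W
  h <- x
  for (blk in model$blocks) {
    branches <- lapply(blk$branches, function(l) conv1d_fwd(l, h, B, W))
    z <- branches[[1]]
    for (j in seq_along(branches)[-1]) z <- ag_cbind(z, branches[[j]])
    z <- bn_fwd(blk$bn, z, training)
    r <- if (is.null(blk$res)) h else conv1d_fwd(blk$res, h, B, W)
    h <- ag_relu(ag_add(z, r))
  }
  pooled <- ag_time_pool(h, B, W)
  logits <- dense_fwd(model$cls, pooled)
  list(logits = logits, pooled = pooled, B = B)
}

#' Forward pass of the pose teacher
#'
#' @param model a `pose_teacher`.
#' @param batch a `W x (4*joint_count)` matrix or `W x (4*joint_count) x B`
#'   array of flattened quaternion pose windows.
#' @param training logical; evaluation mode when `FALSE`.
#' @return list with `logits` (B x N) and `pooled` matrices.
#' @export
pose_teacher_forward <- function(model, batch, training = FALSE) {
  W <- dim(batch)[1]
  X <- batch_to_rows(batch)
  attr(X, "window_len") <- W
  ag_reset()
  out <- pose_teacher_nodes(model, X, training)
  res <- list(logits = out$logits$value, pooled = out$pooled$value)
  ag_reset()
  res
}

# ---- checkpoints ---------------------------------------------------------

collect_bn_states <- function(x) {
  if (is.environment(x)) {
    if (!is.null(x$running_mean)) return(list(x))
    return(list())
  }
  if (is.list(x)) {
    res <- do.call(c, lapply(x, collect_bn_states))
    return(if (is.null(res)) list() else res)
  }
  list()
}

get_weights <- function(model) {
  list(params = lapply(collect_params(model), function(p) p$value),
       states = lapply(collect_bn_states(model), function(s) {
         list(running_mean = s$running_mean, running_var = s$running_var)
       }))
}

set_weights <- function(model, weights) {
  ps <- collect_params(model)
  stopifnot(length(ps) == length(weights$params))
  for (i in seq_along(ps)) {
    stopifnot(length(ps[[i]]$value) == length(weights$params[[i]]))
    ps[[i]]$value <- weights$params[[i]]
    ps[[i]]$grad[] <- 0
  }
  ss <- collect_bn_states(model)
  stopifnot(length(ss) == length(weights$states))
  for (i in seq_along(ss)) {
    ss[[i]]$running_mean <- weights$states[[i]]$running_mean
    ss[[i]]$running_var <- weights$states[[i]]$running_var
  }
  invisible(model)
}

#' Save a model checkpoint
#'
#' Writes a single-file versioned archive holding all parameter arrays,
#' batch-norm running statistics and the model configuration.
#'
#' @param model a model object (`semgxcm_model`, `pose_teacher` or `q_net`).
#' @param path output file path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "semgpose-checkpoint", version = 1L,
              class = class(model), config = model$config,
              weights = get_weights(model))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint into a compatible model object
#'
#' @param model a model object built with the same configuration.
#' @param path checkpoint file written by [save_checkpoint()].
#' @return the model, with parameters restored.
#' @export
load_checkpoint <- function(model, path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "semgpose-checkpoint")) {
    stop("not a semgpose checkpoint: ", path)
  }
  set_weights(model, obj$weights)
}
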