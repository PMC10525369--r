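# Neural layer constructors and forwards on top of the autodiff tape.
#
# Batched sequences are laid out as (B*W) x C matrices with row (b-1)*W + t,
# i.e. time fastest within each batch item; 2D "EMG image" tensors as
# (B*W*C) x F with row (b-1)*W*C + (w-1)*C + c. Convolutions are im2col
# gathers followed by one matrix multiply; the gather index vectors depend
# only on shapes and are cached.

.idx <- new.env(parent = emptyenv())

idx_cached <- function(key, builder) {
  v <- .idx[[key]]
  if (is.null(v)) {
    v <- builder()
    .idx[[key]] <- v
  }
  v
}

# Xavier/Glorot uniform initialization: U(-sqrt(6/(fi+fo)), +sqrt(6/(fi+fo)))
xavier_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- dense -------------------------------------------------------------

dense_new <- function(nin, nout, zero = FALSE) {
  W <- if (zero) array(0, dim = c(nin, nout)) else xavier_uniform(nin, nout)
  list(W = ag_param(W), b = ag_param(matrix(0, nout, 1L)))
}

dense_fwd <- function(layer, x) {
  ag_add(ag_mm(x, ag_leaf(layer$W)), ag_leaf(layer$b))
}

dense_n_params <- function(nin, nout) nin * nout + nout

# ---- batch norm --------------------------------------------------------

bn_new <- function(nf) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(nf)
  st$running_var <- rep(1, nf)
  list(gamma = ag_param(matrix(1, nf, 1L)), beta = ag_param(matrix(0, nf, 1L)),
       state = st)
}

bn_fwd <- function(layer, x, training) {
  ag_batchnorm(x, ag_leaf(layer$gamma), ag_leaf(layer$beta), layer$state, training)
}

# ---- 1D convolution over time (C input channels, same padding, odd K) ----

conv1d_new <- function(cin, cout, k) {
  stopifnot(k %% 2 == 1)
  list(W = ag_param(xavier_uniform(k * cin, k * cout, dims = c(k * cin, cout))),
       b = ag_param(matrix(0, cout, 1L)), k = k, cin = cin, cout = cout)
}

idx_im2col_1d <- function(B, W, C, K) {
  idx_cached(sprintf("c1d_%d_%d_%d_%d", B, W, C, K), function() {
    R <- B * W
    pad <- (K - 1L) %/% 2L
    r <- seq_len(R)
    b_of_r <- (r - 1L) %/% W + 1L
    t_of_r <- (r - 1L) %% W + 1L
    ncol2 <- K * C
    out <- matrix(NA_integer_, R, ncol2)
    for (j in seq_len(ncol2)) {
      k <- (j - 1L) %/% C + 1L
      c <- (j - 1L) %% C + 1L
      t2 <- t_of_r + k - 1L - pad
      ok <- t2 >= 1L & t2 <= W
      inrow <- (b_of_r - 1L) * W + t2
      col <- rep(NA_integer_, R)
      col[ok] <- inrow[ok] + (c - 1L) * R
      out[, j] <- col
    }
    gather_plan(as.integer(out), B * W * C)
  })
}

conv1d_fwd <- function(layer, x, B, W) {
  idx <- idx_im2col_1d(B, W, layer$cin, layer$k)
  cols <- ag_gather(x, idx, c(B * W, layer$k * layer$cin))
  ag_add(ag_mm(cols, ag_leaf(layer$W)), ag_leaf(layer$b))
}

# ---- 2D convolution on the W x C image (same padding, odd kernels) -------

conv2d_new <- function(fin, fout, kh = 3L, kw = 3L) {
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  fan_in <- kh * kw * fin
  fan_out <- kh * kw * fout
  list(W = ag_param(xavier_uniform(fan_in, fan_out, dims = c(kh * kw * fin, fout))),
       b = ag_param(matrix(0, fout, 1L)), kh = kh, kw = kw, fin = fin, fout = fout)
}

idx_im2col_2d <- function(B, W, C, Fin, KH, KW) {
  idx_cached(sprintf("c2d_%d_%d_%d_%d_%d_%d", B, W, C, Fin, KH, KW), function() {
    R <- B * W * C
    padh <- (KH - 1L) %/% 2L
    padw <- (KW - 1L) %/% 2L
    r <- seq_len(R)
    b_of_r <- (r - 1L) %/% (W * C) + 1L
    rem <- (r - 1L) %% (W * C)
    w_of_r <- rem %/% C + 1L
    c_of_r <- rem %% C + 1L
    ncol2 <- KH * KW * Fin
    out <- matrix(NA_integer_, R, ncol2)
    for (j in seq_len(ncol2)) {
      f <- (j - 1L) %/% (KH * KW) + 1L
      rem2 <- (j - 1L) %% (KH * KW)
      kh <- rem2 %/% KW + 1L
      kw <- rem2 %% KW + 1L
      w2 <- w_of_r + kh - 1L - padh
      c2 <- c_of_r + kw - 1L - padw
      ok <- w2 >= 1L & w2 <= W & c2 >= 1L & c2 <= C
      inrow <- (b_of_r - 1L) * W * C + (w2 - 1L) * C + c2
      col <- rep(NA_integer_, R)
      col[ok] <- inrow[ok] + (f - 1L) * R
      out[, j] <- col
    }
    gather_plan(as.integer(out), B * W * C * Fin)
  })
}

conv2d_fwd <- function(layer, x, B, W, C) {
  idx <- idx_im2col_2d(B, W, C, layer$fin, layer$kh, layer$kw)
  cols <- ag_gather(x, idx, c(B * W * C, layer$kh * layer$kw * layer$fin))
  ag_add(ag_mm(cols, ag_leaf(layer$W)), ag_leaf(layer$b))
}

# ---- 2D locally connected, 1x1 kernels (no weight sharing across W x C) --

lc1x1_new <- function(P, fin, fout) {
  list(W = ag_param(xavier_uniform(fin, fout, dims = c(P, fin, fout))),
       b = ag_param(array(0, dim = c(P, fout))), P = P, fin = fin, fout = fout)
}

lc1x1_fwd <- function(layer, x, B) {
  Wn <- ag_leaf(layer$W)
  bn <- ag_leaf(layer$b)
  Wv <- Wn$value
  bv <- bn$value
  P <- layer$P; Fi <- layer$fin; Fo <- layer$fout
  xv <- x$value
  stopifnot(nrow(xv) == B * P, ncol(xv) == Fi)
  off <- (seq_len(B) - 1L) * P
  out <- matrix(0, B * P, Fo)
  for (p in seq_len(P)) {
    rp <- p + off
    Wp <- matrix(Wv[p, , ], Fi, Fo)
    out[rp, ] <- xv[rp, , drop = FALSE] %*% Wp +
      matrix(bv[p, ], B, Fo, byrow = TRUE)
  }
  ag_new(out, list(x, Wn, bn), function(g) {
    gx <- matrix(0, B * P, Fi)
    gW <- array(0, dim = c(P, Fi, Fo))
    gb <- array(0, dim = c(P, Fo))
    for (p in seq_len(P)) {
      rp <- p + off
      gp <- g[rp, , drop = FALSE]
      Wp <- matrix(Wv[p, , ], Fi, Fo)
      gx[rp, ] <- gp %*% t(Wp)
      gW[p, , ] <- t(xv[rp, , drop = FALSE]) %*% gp
      gb[p, ] <- colSums(gp)
    }
    list(gx, gW, gb)
  })
}

# ---- multi-head self-attention over time tokens --------------------------

attn_new <- function(din, heads, head_dim) {
  dk <- heads * head_dim
  list(Wq = dense_new(din, dk), Wk = dense_new(din, dk), Wv = dense_new(din, dk),
       Wo = dense_new(dk, din), heads = heads, head_dim = head_dim, din = din)
}

attn_n_params <- function(din, heads, head_dim) {
  dk <- heads * head_dim
  3L * dense_n_params(din, dk) + dense_n_params(dk, din)
}

idx_head_split <- function(B, W, H, hd, transposed = FALSE) {
  key <- sprintf("hs_%d_%d_%d_%d_%d", B, W, H, hd, transposed)
  idx_cached(key, function() {
    R <- B * W
    # input element (r, col) flat = r + (col-1)*R, r=(b-1)*W+t, col=(h-1)*hd+e
    flat_in <- function(b, h, t, e) {
      (b - 1L) * W + t + ((h - 1L) * hd + e - 1L) * R
    }
    if (!transposed) {
      # output (B*H, W, hd) element (i=(b-1)*H+h, t, e), column-major
      g <- expand.grid(i = seq_len(B * H), t = seq_len(W), e = seq_len(hd))
      b <- (g$i - 1L) %/% H + 1L
      h <- (g$i - 1L) %% H + 1L
      gather_plan(as.integer(flat_in(b, h, g$t, g$e)), B * W * H * hd)
    } else {
      # output (B*H, hd, W) element (i, e, t)
      g <- expand.grid(i = seq_len(B * H), e = seq_len(hd), t = seq_len(W))
      b <- (g$i - 1L) %/% H + 1L
      h <- (g$i - 1L) %% H + 1L
      gather_plan(as.integer(flat_in(b, h, g$t, g$e)), B * W * H * hd)
    }
  })
}

idx_head_merge <- function(B, W, H, hd) {
  idx_cached(sprintf("hm_%d_%d_%d_%d", B, W, H, hd), function() {
    # input 3D (B*H, W, hd) flat = i + (t-1)*B*H + (e-1)*B*H*W
    # output (B*W, H*hd) element (r=(b-1)*W+t, col=(h-1)*hd+e)
    g <- expand.grid(r = seq_len(B * W), col = seq_len(H * hd))
    b <- (g$r - 1L) %/% W + 1L
    t <- (g$r - 1L) %% W + 1L
    h <- (g$col - 1L) %/% hd + 1L
    e <- (g$col - 1L) %% hd + 1L
    i <- (b - 1L) * H + h
    gather_plan(as.integer(i + (t - 1L) * B * H + (e - 1L) * B * H * W),
                B * H * W * hd)
  })
}

attn_fwd <- function(layer, x, B, W) {
  H <- layer$heads
  hd <- layer$head_dim
  q <- dense_fwd(layer$Wq, x)
  k <- dense_fwd(layer$Wk, x)
  v <- dense_fwd(layer$Wv, x)
  q3 <- ag_gather(q, idx_head_split(B, W, H, hd), c(B * H, W, hd))
  k3t <- ag_gather(k, idx_head_split(B, W, H, hd, transposed = TRUE), c(B * H, hd, W))
  v3 <- ag_gather(v, idx_head_split(B, W, H, hd), c(B * H, W, hd))
  scores <- ag_cmul(ag_bmm(q3, k3t), 1 / sqrt(hd))
  att <- ag_setdim(ag_softmax_rows(ag_setdim(scores, c(B * H * W, W))), c(B * H, W, W))
  out3 <- ag_bmm(att, v3)
  merged <- ag_gather(out3, idx_head_merge(B, W, H, hd), c(B * W, H * hd))
  ag_add(x, dense_fwd(layer$Wo, merged))
}

# position-wise feedforward with residual connection
ff_new <- function(din, dff) {
  list(f1 = dense_new(din, dff), f2 = dense_new(dff, din))
}

ff_fwd <- function(layer, x) {
  ag_add(x, dense_fwd(layer$f2, ag_relu(dense_fwd(layer$f1, x))))
}

# collect every ag_param inside a nested layer list
collect_params <- function(x) {
  if (is.environment(x)) {
    if (!is.null(x$value) && !is.null(x$grad)) return(list(x))
    return(list())
  }
  if (is.list(x)) {
    res <- do.call(c, lapply(x, collect_params))
    return(if (is.null(res)) list() else res)
  }
  list()
}

n_parameters <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
}
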