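# Reverse-mode automatic differentiation on numeric arrays.
#
# A global tape records operation nodes in creation order; ag_backward() walks
# it in reverse, accumulating gradients. Trainable parameters live outside the
# tape (environments created by ag_param()) and enter a graph through
# ag_leaf(); their $grad fields accumulate across backward passes until
# ag_zero_grad(). Values are plain numeric matrices/arrays, so everything is
# deterministic given the R RNG state.

.ag <- new.env(parent = emptyenv())
.ag$tape <- vector("list", 512L)
.ag$n <- 0L

ag_reset <- function() {
  .ag$tape <- vector("list", 512L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_record <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) {
    .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  }
  .ag$tape[[n]] <- node
  .ag$n <- n
  node
}

ag_new <- function(value, parents = list(), backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$needs <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$needs, logical(1)))
  ag_record(node)
}

# Trainable parameter container (persistent across steps, off-tape).
ag_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim = dim(as.array(value)))
  p
}

ag_leaf <- function(param) {
  node <- ag_new(param$value)
  node$needs <- TRUE
  node$param <- param
  node
}

ag_const <- function(value) {
  if (is.null(dim(value))) value <- as.matrix(value)
  ag_new(value)
}

ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- loss$value * 0 + 1
  for (i in seq.int(.ag$n, 1L)) {
    node <- .ag$tape[[i]]
    if (is.null(node) || is.null(node$grad) || !isTRUE(node$needs)) next
    if (!is.null(node$param)) {
      node$param$grad <- node$param$grad + node$grad
      next
    }
    if (is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!isTRUE(p$needs) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

ag_sgd_step <- function(params, lr) {
  for (p in params) p$value <- p$value - lr * p$grad
  invisible(NULL)
}

# ---- primitive operations ----------------------------------------------

ag_mm <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_new(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

ag_t <- function(a) {
  ag_new(t(a$value), list(a), function(g) list(t(g)))
}

# a matrix + b (same shape | length-ncol bias vector broadcast over rows)
ag_add <- function(a, b) {
  av <- a$value; bv <- b$value
  if (identical(dim(as.array(av)), dim(as.array(bv)))) {
    ag_new(av + bv, list(a, b), function(g) list(g, g))
  } else {
    stopifnot(length(bv) == ncol(av))
    ag_new(sweep(av, 2L, as.numeric(bv), "+"), list(a, b), function(g) {
      list(g, matrix(colSums(g), ncol = 1L))
    })
  }
}

ag_sub <- function(a, b) {
  stopifnot(length(a$value) == length(b$value))
  ag_new(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_neg <- function(a) ag_new(-a$value, list(a), function(g) list(-g))

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  stopifnot(length(av) == length(bv))
  ag_new(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply / add a numeric constant (scalar or same-shape array)
ag_cmul <- function(a, m) {
  ag_new(a$value * m, list(a), function(g) list(g * m))
}

ag_cadd <- function(a, m) {
  ag_new(a$value + m, list(a), function(g) list(g))
}

ag_relu <- function(a) {
  v <- a$value
  out <- v * (v > 0)
  ag_new(out, list(a), function(g) list(g * (v > 0)))
}

ag_exp <- function(a) {
  out <- exp(a$value)
  ag_new(out, list(a), function(g) list(g * out))
}

ag_tanh <- function(a) {
  out <- tanh(a$value)
  ag_new(out, list(a), function(g) list(g * (1 - out^2)))
}

# change dim metadata only (data layout is column-major and unchanged)
ag_setdim <- function(a, dims) {
  d0 <- dim(as.array(a$value))
  v <- a$value
  dim(v) <- dims
  ag_new(v, list(a), function(g) {
    dim(g) <- d0
    list(g)
  })
}

ag_sum <- function(a) {
  d <- dim(as.array(a$value))
  ag_new(matrix(sum(a$value)), list(a), function(g) list(array(as.numeric(g), dim = d)))
}

ag_mean <- function(a) {
  d <- dim(as.array(a$value))
  n <- length(a$value)
  ag_new(matrix(mean(a$value)), list(a), function(g) {
    list(array(as.numeric(g) / n, dim = d))
  })
}

# pick a[i, idx[i]] -> n x 1 column
ag_pick <- function(a, idx) {
  av <- a$value
  n <- nrow(av)
  stopifnot(length(idx) == n, all(idx >= 1L), all(idx <= ncol(av)))
  sel <- cbind(seq_len(n), idx)
  ag_new(matrix(av[sel], ncol = 1L), list(a), function(g) {
    gx <- matrix(0, n, ncol(av))
    gx[sel] <- as.numeric(g)
    list(gx)
  })
}

# numerically stable row-wise log-softmax
ag_log_softmax <- function(a) {
  av <- a$value
  mx <- apply(av, 1L, max)
  sh <- av - mx
  lse <- log(rowSums(exp(sh)))
  out <- sh - lse
  sm <- exp(out)
  ag_new(out, list(a), function(g) {
    list(g - sm * rowSums(g))
  })
}

ag_softmax_rows <- function(a) {
  av <- a$value
  mx <- apply(av, 1L, max)
  e <- exp(av - mx)
  s <- e / rowSums(e)
  ag_new(s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

ag_l2normalize_rows <- function(a, eps = 1e-12) {
  av <- a$value
  nr <- sqrt(rowSums(av^2)) + eps
  y <- av / nr
  ag_new(y, list(a), function(g) {
    list((g - y * rowSums(g * y)) / nr)
  })
}

ag_cols <- function(a, cols) {
  av <- a$value
  ag_new(av[, cols, drop = FALSE], list(a), function(g) {
    gx <- matrix(0, nrow(av), ncol(av))
    gx[, cols] <- g
    list(gx)
  })
}

ag_cbind <- function(a, b) {
  na <- ncol(a$value)
  ag_new(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

# Precomputed gather/scatter plan for out[k] <- a[idx[k]] (flat indices,
# NA -> 0). `idx_pad` maps NA to a zero sentinel for the forward; `inv` is
# the transposed mapping (input element -> the <= maxc output slots reading
# it, padded with a sentinel) so the backward scatter-add is a rowSums.
gather_plan <- function(idx, len_in) {
  n <- length(idx)
  ok <- !is.na(idx)
  idx_pad <- as.integer(idx)
  idx_pad[!ok] <- len_in + 1L
  pos <- which(ok)
  tgt <- idx_pad[pos]
  cnt <- tabulate(tgt, nbins = len_in)
  maxc <- max(1L, cnt)
  o <- order(tgt)
  tgt_s <- tgt[o]
  pos_s <- pos[o]
  slot <- sequence(rle(tgt_s)$lengths)
  inv <- matrix(n + 1L, len_in, maxc)
  inv[cbind(tgt_s, slot)] <- pos_s
  list(n = n, idx_pad = idx_pad, inv = inv, len_in = len_in, maxc = maxc)
}

# Generalized gather/reshape: covers im2col, axis permutation and zero
# padding in one primitive. `plan` comes from gather_plan() (cached by the
# layer code for fixed shapes).
ag_gather <- function(a, plan, dims) {
  av <- a$value
  ad <- dim(as.array(av))
  stopifnot(length(av) == plan$len_in)
  v <- c(av, 0)[plan$idx_pad]
  dim(v) <- dims
  ag_new(v, list(a), function(g) {
    gpad <- c(as.numeric(g), 0)
    gx <- if (plan$maxc == 1L) {
      gpad[plan$inv[, 1L]]
    } else {
      rowSums(matrix(gpad[plan$inv], plan$len_in, plan$maxc))
    }
    dim(gx) <- ad
    list(gx)
  })
}

# batched matrix multiply: a (n,r,k) x b (n,k,c) -> (n,r,c)
ag_bmm <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3L, length(db) == 3L, da[1] == db[1], da[3] == db[2])
  n <- da[1]
  out <- array(0, dim = c(n, da[2], db[3]))
  for (i in seq_len(n)) {
    out[i, , ] <- matrix(av[i, , ], da[2], da[3]) %*% matrix(bv[i, , ], db[2], db[3])
  }
  ag_new(out, list(a, b), function(g) {
    ga <- array(0, dim = da)
    gb <- array(0, dim = db)
    for (i in seq_len(n)) {
      gi <- matrix(g[i, , ], da[2], db[3])
      ga[i, , ] <- gi %*% t(matrix(bv[i, , ], db[2], db[3]))
      gb[i, , ] <- t(matrix(av[i, , ], da[2], da[3])) %*% gi
    }
    list(ga, gb)
  })
}

# mean-pool rows over contiguous groups of size W: (B*W) x F -> B x F
ag_time_pool <- function(a, B, W) {
  av <- a$value
  stopifnot(nrow(av) == B * W)
  grp <- rep(seq_len(B), each = W)
  out <- rowsum(av, grp) / W
  dimnames(out) <- NULL
  ag_new(out, list(a), function(g) {
    list(g[grp, , drop = FALSE] / W)
  })
}

# inverted dropout; draws its mask from the R RNG at construction time
ag_dropout <- function(a, p, training) {
  if (!training || p <= 0) return(a)
  keep <- 1 - p
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) < keep) / keep
  ag_new(a$value * mask, list(a), function(g) list(g * mask))
}

# Batch normalization over rows (each column a feature). `state` is an
# environment holding running_mean / running_var for evaluation mode.
ag_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  n <- nrow(xv)
  if (training) {
    mu <- colMeans(xv)
    xc <- sweep(xv, 2L, mu)
    va <- colMeans(xc^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va * n / max(1, n - 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- sweep(xv, 2L, mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  gv <- as.numeric(gamma$value)
  bv <- as.numeric(beta$value)
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ag_new(out, list(x, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), ncol = 1L)
    dbeta <- matrix(colSums(g), ncol = 1L)
    if (training) {
      gm <- colMeans(g)
      gxm <- colMeans(g * xhat)
      dx <- sweep(g, 2L, gm) - sweep(xhat, 2L, gxm, "*")
      dx <- sweep(dx, 2L, gv * istd, "*")
    } else {
      dx <- sweep(g, 2L, gv * istd, "*")
    }
    list(dx, dgamma, dbeta)
  })
}

# ---- numeric gradient checking (used by the test suite) ------------------

# central finite differences of scalar-valued fn over a parameter's entries
ag_fd_grad <- function(fn, param, h = 1e-5) {
  g <- array(0, dim = dim(as.array(param$value)))
  for (i in seq_along(param$value)) {
    orig <- param$value[i]
    param$value[i] <- orig + h
    fp <- fn()
    param$value[i] <- orig - h
    fm <- fn()
    param$value[i] <- orig
    g[i] <- (fp - fm) / (2 * h)
  }
  g
}
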