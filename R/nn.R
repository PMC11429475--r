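# Layer compositions and optimizer on top of the autodiff engine.
# Images flow through the networks as (H, W, C, B) arrays; token tensors as
# (B*T, hidden) matrices; attention works on (T, d_head, B*heads) slabs.

# ---- parameter stores ------------------------------------------------------

new_params <- function(init = list()) {
  p <- new.env(parent = emptyenv())
  p$val <- init
  p$m <- list(); p$v <- list(); p$t <- 0L
  p
}

# wrap every parameter as a leaf node once per forward pass
param_leaves <- function(params) lapply(params$val, ad_leaf)

# He-style initialisation for a (fan_in, fan_out) weight matrix
winit <- function(nin, nout, scale = sqrt(2 / nin)) {
  matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
}

adam_step <- function(params, grads, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  params$t <- params$t + 1L
  t <- params$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(params$m[[nm]])) {
      params$m[[nm]] <- g * 0
      params$v[[nm]] <- g * 0
    }
    params$m[[nm]] <- beta1 * params$m[[nm]] + (1 - beta1) * g
    params$v[[nm]] <- beta2 * params$v[[nm]] + (1 - beta2) * g^2
    mhat <- params$m[[nm]] / (1 - beta1^t)
    vhat <- params$v[[nm]] / (1 - beta2^t)
    params$val[[nm]] <- params$val[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(params)
}

# ---- index caches ----------------------------------------------------------

 .idx_cache <- new.env(parent = emptyenv())

# flag an index vector as strictly positive so gather can skip zero masking,
# and key it so scatter-add can cache its accumulation plan
mark_dense <- function(x) {
  attr(x, "dense") <- all(x > 0L)
  n <- (.idx_cache$mark_seq %||% 0L) + 1L
  .idx_cache$mark_seq <- n
  attr(x, "aggkey") <- paste0("agg_", n)
  x
}

cache_get <- function(key, builder) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    .idx_cache[[key]] <- v
  }
  v
}

# im2col gather index for input (H,W,C,B), kernel k, given stride/pad.
# Returns list(idx = integer vector for the (N, k*k*C) column matrix,
#              perm = permutation index mapping (N, Cout) to (Ho,Wo,Cout,B))
conv_index <- function(H, W, C, B, k, stride, pad, Cout) {
  key <- paste("conv", H, W, C, B, k, stride, pad, Cout, sep = "_")
  cache_get(key, function() {
    Ho <- (H + 2 * pad - k) %/% stride + 1L
    Wo <- (W + 2 * pad - k) %/% stride + 1L
    P <- Ho * Wo
    N <- B * P
    p_ho <- rep(seq_len(Ho), times = Wo)
    p_wo <- rep(seq_len(Wo), each = Ho)
    boff <- (seq_len(B) - 1L) * H * W * C
    idx <- integer(N * k * k * C)
    j <- 0L
    for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
      hi <- (p_ho - 1L) * stride + dy - pad
      wi <- (p_wo - 1L) * stride + dx - pad
      ok <- hi >= 1L & hi <= H & wi >= 1L & wi <= W
      base <- hi + H * ((wi - 1L) + W * (c - 1L))
      base[!ok] <- NA_integer_
      col <- as.vector(outer(base, boff, `+`))      # (P, B) -> rows b-major?
      # row ordering must be (b-1)*P + p: outer gives p varying fastest per b
      col[is.na(col)] <- 0L
      idx[(j * N + 1L):((j + 1L) * N)] <- col
      j <- j + 1L
    }
    # permutation: output flat (Ho,Wo,Cout,B) <- y (N, Cout)
    p <- seq_len(P)
    perm <- integer(P * Cout * B)
    for (b in seq_len(B)) for (c in seq_len(Cout)) {
      dst <- p + P * ((c - 1L) + Cout * (b - 1L))
      src <- ((b - 1L) * P + p) + N * (c - 1L)
      perm[dst] <- src
    }
    list(idx = mark_dense(idx), perm = mark_dense(perm), Ho = Ho, Wo = Wo, N = N)
  })
}

# note: in conv_index the column rows are ordered with p fastest within each
# sample b, i.e. row i = (b-1)*P + p, matching the perm construction above.

# nearest-neighbour 2x upsample gather index for (H,W,C,B)
upsample_index <- function(H, W, C, B) {
  key <- paste("ups", H, W, C, B, sep = "_")
  cache_get(key, function() {
    H2 <- 2L * H; W2 <- 2L * W
    h2 <- rep(seq_len(H2), times = W2)
    w2 <- rep(seq_len(W2), each = H2)
    hs <- (h2 + 1L) %/% 2L
    ws <- (w2 + 1L) %/% 2L
    plane <- hs + H * (ws - 1L)                      # length H2*W2
    off <- as.vector(outer((seq_len(C) - 1L) * H * W,
                           (seq_len(B) - 1L) * H * W * C, `+`))
    idx <- mark_dense(as.vector(outer(plane, off, `+`)))
    list(idx = idx, dim = c(H2, W2, C, B))
  })
}

# head-split permutation: (B*T, nh*dh) matrix -> (T, dh, B*nh) array
headsplit_index <- function(B, T, nh, dh) {
  key <- paste("hs", B, T, nh, dh, sep = "_")
  cache_get(key, function() {
    N <- B * T; Hd <- nh * dh
    idx <- integer(T * dh * B * nh)
    for (b in seq_len(B)) for (h in seq_len(nh)) {
      s <- (b - 1L) * nh + h                        # slab index
      for (d in seq_len(dh)) {
        tpos <- seq_len(T)
        dst <- tpos + T * ((d - 1L) + dh * (s - 1L))
        src <- ((b - 1L) * T + tpos) + N * (((h - 1L) * dh + d) - 1L)
        idx[dst] <- src
      }
    }
    inv <- integer(length(idx)); inv[idx] <- seq_along(idx)
    list(split = mark_dense(idx), merge = mark_dense(inv),
         dim3 = c(T, dh, B * nh), dim2 = c(N, Hd))
  })
}

# ---- layer composites ------------------------------------------------------

ad_bias_rows <- function(x, b) {
  n <- nrow(ad_val(x)); k <- length(ad_val(b))
  idx <- cache_get(paste("bias", n, k, sep = "_"),
                   function() mark_dense(rep(seq_len(k), each = n)))
  ad_add(x, ad_gather(b, idx, dim = c(n, k)))
}

nn_dense <- function(x, W, b = NULL) {
  y <- ad_matmul(x, W)
  if (!is.null(b)) y <- ad_bias_rows(y, b) else y
}

# x: node over (H,W,C,B); W: (k*k*C, Cout); b: (Cout)
nn_conv2d <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- .dm(ad_val(x))
  Cout <- ncol(ad_val(W))
  ci <- conv_index(d[1], d[2], d[3], d[4], k, stride, pad, Cout)
  col <- ad_gather(x, ci$idx, dim = c(ci$N, k * k * d[3]))
  y <- ad_bias_rows(ad_matmul(col, W), b)
  ad_gather(y, ci$perm, dim = c(ci$Ho, ci$Wo, Cout, d[4]))
}

nn_upsample2x <- function(x) {
  d <- .dm(ad_val(x))
  ui <- upsample_index(d[1], d[2], d[3], d[4])
  ad_gather(x, ui$idx, dim = ui$dim)
}

# channel broadcast of a length-C vector over (H,W,C,B)
.ch_grp <- function(d) {
  key <- paste("chg", paste(d, collapse = "_"), sep = "_")
  cache_get(key, function() {
    mark_dense(rep(rep(seq_len(d[3]), each = d[1] * d[2]), times = d[4]))
  })
}

ch_bcast <- function(v, d) ad_gather(v, .ch_grp(d), dim = d)

# batch norm over (batch, spatial) per channel; composite of primitives so
# its gradient is exact.  `state` carries running moments for eval mode.
nn_batchnorm <- function(x, gamma, beta, state, name, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  d <- .dm(ad_val(x))
  grp <- .ch_grp(d)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- ad_mul(ad_aggr(x, grp, d[3]), 1 / m)
    xc <- ad_sub(x, ch_bcast(mu, d))
    va <- ad_mul(ad_aggr(ad_mul(xc, xc), grp, d[3]), 1 / m)
    if (!is.null(state)) {
      rmu <- state$val[[paste0(name, ".rmu")]]
      rva <- state$val[[paste0(name, ".rva")]]
      if (is.null(rmu)) { rmu <- ad_val(mu) * 0; rva <- ad_val(va) * 0 + 1 }
      state$val[[paste0(name, ".rmu")]] <- (1 - momentum) * rmu + momentum * ad_val(mu)
      state$val[[paste0(name, ".rva")]] <- (1 - momentum) * rva + momentum * ad_val(va)
    }
  } else {
    mu <- ad_const(state$val[[paste0(name, ".rmu")]] %||% numeric(d[3]))
    va <- ad_const(state$val[[paste0(name, ".rva")]] %||% (numeric(d[3]) + 1))
    xc <- ad_sub(x, ch_bcast(mu, d))
  }
  sd_ <- ad_sqrt(ad_add(va, eps))
  xhat <- ad_div(xc, ch_bcast(sd_, d))
  ad_add(ad_mul(xhat, ch_bcast(gamma, d)), ch_bcast(beta, d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# row-wise layer norm of a (N, H) token matrix
.row_grp <- function(n, h) {
  key <- paste("rg", n, h, sep = "_")
  cache_get(key, function() mark_dense(rep(seq_len(n), times = h)))
}

.col_grp <- function(n, h) {
  key <- paste("cg", n, h, sep = "_")
  cache_get(key, function() mark_dense(rep(seq_len(h), each = n)))
}

# fused row-wise layer norm: forward and first-order backward computed
# numerically in one node (never on the double-backprop path)
nn_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xv <- ad_val(x); gv <- as.numeric(ad_val(gamma)); bv <- as.numeric(ad_val(beta))
  n <- nrow(xv); h <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  sd_ <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd_
  y <- sweep(xhat, 2, gv, `*`)
  y <- sweep(y, 2, bv, `+`)
  new_op(y, list(x, gamma, beta), list(
    function(g) {
      gm <- ad_val(g)
      gy <- sweep(gm, 2, gv, `*`)                    # dL/dxhat
      t1 <- rowMeans(gy)
      t2 <- rowMeans(gy * xhat)
      ad_const((gy - t1 - xhat * t2) / sd_)
    },
    function(g) ad_const(colSums(ad_val(g) * xhat)),
    function(g) ad_const(colSums(ad_val(g)))))
}

# softmax along rows of a (N, C) matrix (max-shift detached)
nn_softmax_rows <- function(x) {
  d <- .dm(ad_val(x)); n <- d[1]; h <- d[2]
  grp <- .row_grp(n, h)
  mx <- apply(ad_val(x), 1, max)
  e <- ad_exp(ad_sub(x, ad_const(matrix(mx, n, h))))
  s <- ad_aggr(e, grp, n)
  ad_div(e, ad_gather(s, grp, dim = d))
}

nn_logsoftmax_rows <- function(x) {
  d <- .dm(ad_val(x)); n <- d[1]; h <- d[2]
  grp <- .row_grp(n, h)
  mx <- apply(ad_val(x), 1, max)
  xs <- ad_sub(x, ad_const(matrix(mx, n, h)))
  ls <- ad_log(ad_aggr(ad_exp(xs), grp, n))
  ad_sub(xs, ad_gather(ls, grp, dim = d))
}

# fused softmax over dim 2 of a (Tq, Tk, S) attention-score slab; numeric
# first-order backward (never on the double-backprop path)
nn_softmax_slab <- function(x) {
  x <- as_node(x)
  xv <- ad_val(x)
  d <- dim(xv)
  y <- xv
  for (s in seq_len(d[3])) {
    m <- xv[, , s]
    m <- exp(m - apply(m, 1, max))
    y[, , s] <- m / rowSums(m)
  }
  new_op(y, list(x), list(function(g) {
    gv <- ad_val(g)
    out <- gv
    for (s in seq_len(d[3])) {
      ys <- y[, , s]; gs <- gv[, , s]
      out[, , s] <- ys * (gs - rowSums(gs * ys))
    }
    ad_const(out)
  }))
}

# multi-head attention between query tokens (B*Tq, Hd) and key/value tokens
# (B*Tk, Hd); returns list(out = (B*Tq, Hd) node, attn = (Tq,Tk,B*nh) values)
nn_mha <- function(xq, xkv, L, prefix, B, Tq, Tk, nh) {
  Hd <- ncol(ad_val(xq)); dh <- Hd %/% nh
  Q <- nn_dense(xq, L[[paste0(prefix, ".Wq")]], L[[paste0(prefix, ".bq")]])
  K <- nn_dense(xkv, L[[paste0(prefix, ".Wk")]], L[[paste0(prefix, ".bk")]])
  V <- nn_dense(xkv, L[[paste0(prefix, ".Wv")]], L[[paste0(prefix, ".bv")]])
  hq <- headsplit_index(B, Tq, nh, dh)
  hk <- headsplit_index(B, Tk, nh, dh)
  Q3 <- ad_gather(Q, hq$split, dim = hq$dim3)
  K3 <- ad_gather(K, hk$split, dim = hk$dim3)
  V3 <- ad_gather(V, hk$split, dim = hk$dim3)
  S <- ad_mul(ad_bmm(Q3, ad_bt(K3)), 1 / sqrt(dh))
  A <- nn_softmax_slab(S)
  O3 <- ad_bmm(A, V3)                                # (Tq, dh, B*nh)
  O <- ad_gather(O3, hq$merge, dim = hq$dim2)
  out <- nn_dense(O, L[[paste0(prefix, ".Wo")]], L[[paste0(prefix, ".bo")]])
  list(out = out, attn = ad_val(A))
}

nn_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  v <- ad_val(x)
  mask <- (stats::runif(length(v)) >= p) / (1 - p)
  ad_mul(x, ad_const(array(mask, dim = .dm(v))))
}

ad_mean <- function(x) ad_mul(ad_sumall(x), 1 / length(ad_val(x)))
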