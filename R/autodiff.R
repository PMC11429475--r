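# Minimal reverse-mode automatic differentiation on dense numeric arrays.
#
# Every vector-Jacobian product is itself expressed through the same tape
# operations, so gradients are ordinary tape nodes and can be differentiated
# again.  That second differentiation is what the WGAN-GP gradient penalty
# needs: the critic's input gradient enters the critic loss, and its
# parameter gradient is obtained by a second backward pass.
#
# A node is an environment with fields
#   val : numeric array (the forward value)
#   prn : list of parent nodes
#   vjp : list of functions(gnode) -> node, one per parent
#   id  : creation index (defines a valid topological order)
#   req : TRUE if a gradient has to flow to or through this node
# Plain numerics passed to ops are wrapped as constants (req = FALSE).

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

# Gradient maps are environments keyed by node id; reusing ids (by resetting
# the counter whenever no nodes are live) keeps R's interned symbol table
# bounded across long training loops.
ad_reset <- function() {
  .ad$id <- 0L
  invisible(NULL)
}

ad_node <- function(val, prn = list(), vjp = list(), req = FALSE) {
  n <- new.env(parent = emptyenv())
  .ad$id <- .ad$id + 1L
  n$id <- .ad$id
  n$val <- val
  n$prn <- prn
  n$vjp <- vjp
  n$req <- req
  class(n) <- "ad_node"
  n
}

is_node <- function(x) inherits(x, "ad_node")

ad_const <- function(x) ad_node(x)

#' @noRd
ad_leaf <- function(x) ad_node(x, req = TRUE)

as_node <- function(x) if (is_node(x)) x else ad_const(x)

ad_val <- function(x) if (is_node(x)) x$val else x

# dims helper: treat vectors as their length
.dm <- function(v) if (is.null(dim(v))) length(v) else dim(v)

# reduce g to the shape of target value tv when the parent was a length-1
# scalar broadcast by R recycling
.unbroadcast <- function(g, tv) {
  if (length(tv) == 1L && length(ad_val(g)) != 1L) ad_sumall(g) else g
}

new_op <- function(val, parents, vjps) {
  req <- FALSE
  for (p in parents) if (p$req) { req <- TRUE; break }
  if (!req) return(ad_node(val))          # constant folding: no grad path
  ad_node(val, prn = parents, vjp = vjps, req = TRUE)
}

# ---- elementwise arithmetic ------------------------------------------------

ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_op(a$val + b$val, list(a, b),
         list(function(g) .unbroadcast(g, a$val),
              function(g) .unbroadcast(g, b$val)))
}

ad_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_op(a$val - b$val, list(a, b),
         list(function(g) .unbroadcast(g, a$val),
              function(g) .unbroadcast(ad_neg(g), b$val)))
}

ad_neg <- function(a) {
  a <- as_node(a)
  new_op(-a$val, list(a), list(function(g) ad_neg(g)))
}

ad_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_op(a$val * b$val, list(a, b),
         list(function(g) .unbroadcast(ad_mul(g, b), a$val),
              function(g) .unbroadcast(ad_mul(g, a), b$val)))
}

ad_div <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_op(a$val / b$val, list(a, b),
         list(function(g) .unbroadcast(ad_div(g, b), a$val),
              function(g) .unbroadcast(
                ad_neg(ad_div(ad_mul(g, a), ad_mul(b, b))), b$val)))
}

ad_exp <- function(a) {
  a <- as_node(a)
  y <- new_op(exp(a$val), list(a), list(NULL))
  y$vjp <- list(function(g) ad_mul(g, y))   # closure sees the final y
  y
}

ad_log <- function(a) {
  a <- as_node(a)
  new_op(log(a$val), list(a), list(function(g) ad_div(g, a)))
}

ad_sqrt <- function(a) {
  a <- as_node(a)
  y <- new_op(sqrt(a$val), list(a), list(NULL))
  y$vjp <- list(function(g) ad_div(g, ad_mul(2, y)))
  y
}

ad_tanh <- function(a) {
  a <- as_node(a)
  y <- new_op(tanh(a$val), list(a), list(NULL))
  y$vjp <- list(function(g) ad_mul(g, ad_sub(1, ad_mul(y, y))))
  y
}

ad_relu <- function(a) {
  a <- as_node(a)
  m <- ad_const((a$val > 0) * 1)      # mask frozen: a.e. derivative
  new_op(a$val * m$val, list(a), list(function(g) ad_mul(g, m)))
}

ad_lrelu <- function(a, alpha = 0.2) {
  a <- as_node(a)
  m <- ad_const((a$val > 0) * (1 - alpha) + alpha)
  new_op(a$val * m$val, list(a), list(function(g) ad_mul(g, m)))
}

ad_abs <- function(a) {
  a <- as_node(a)
  s <- ad_const(sign(a$val))
  new_op(abs(a$val), list(a), list(function(g) ad_mul(g, s)))
}

# ---- reductions and broadcasts --------------------------------------------

ad_sumall <- function(a) {
  a <- as_node(a)
  shp <- .dm(a$val)
  new_op(sum(a$val), list(a), list(function(g) ad_bcast(g, shp)))
}

# scalar -> array of given dims, every entry the scalar
ad_bcast <- function(a, shp) {
  a <- as_node(a)
  v <- if (length(shp) > 1L) array(as.numeric(a$val), dim = shp)
       else rep(as.numeric(a$val), shp)
  new_op(v, list(a), list(function(g) ad_sumall(g)))
}

# scatter-add plan for a fixed index vector: sorted positions and group
# boundaries, computed once and cached by the layer index caches
.agg_prep <- function(idx) {
  o <- order(idx, method = "radix")
  s <- idx[o]
  nz <- sum(s == 0L)
  if (nz > 0L) {
    o <- o[(nz + 1L):length(o)]
    s <- s[(nz + 1L):length(s)]
  }
  if (!length(s)) return(list(o = integer(), last = integer(), targets = integer()))
  last <- c(which(s[-1L] != s[-length(s)]), length(s))
  list(o = o, last = last, targets = s[last])
}

.aggsum_plan <- function(v, plan, n) {
  out <- numeric(n)
  if (!length(plan$o)) return(out)
  cs <- cumsum(v[plan$o])
  out[plan$targets] <- cs[plan$last] -
    c(0, cs[plan$last[-length(plan$last)]])
  out
}

# grouped accumulation kernel: out[k] = sum of v[i] with idx[i] == k;
# idx == 0 entries are dropped.  A plan cached on the index (attr "aggkey",
# set by the layer index caches) avoids re-sorting hot indices.
.aggsum_num <- function(v, idx, n) {
  ak <- attr(idx, "aggkey")
  plan <- if (!is.null(ak)) cache_get(ak, function() .agg_prep(idx))
          else .agg_prep(idx)
  .aggsum_plan(v, plan, n)
}

# grouped sum: y[k] = sum of x[i] with group[i] == k, k in 1..n
ad_aggr <- function(a, group, n) {
  a <- as_node(a)
  y <- .aggsum_num(as.numeric(a$val), group, n)
  shp <- .dm(a$val)
  new_op(y, list(a),
         list(function(g) ad_gather(g, group, dim = shp)))
}

# y = xflat[idx] (reshaped to `dim` when given); idx == 0 yields 0
ad_gather <- function(a, idx, dim = NULL) {
  a <- as_node(a)
  xv <- a$val
  if (attr(idx, "dense") %||% FALSE) {
    y <- xv[idx]
  } else {
    y <- numeric(length(idx))
    sel <- idx > 0L
    y[sel] <- xv[idx[sel]]
  }
  if (!is.null(dim) && length(dim) > 1L) dim(y) <- dim else dim(y) <- NULL
  nsrc <- length(xv)
  shp <- .dm(a$val)
  new_op(y, list(a),
         list(function(g) ad_scatter(g, idx, nsrc, dim = shp)))
}

# scatter-add dual of gather: y[k] = sum of x[i] with idx[i] == k
ad_scatter <- function(a, idx, n, dim = NULL) {
  a <- as_node(a)
  y <- .aggsum_num(as.numeric(a$val), idx, n)
  if (!is.null(dim) && length(dim) > 1L) dim(y) <- dim
  in_shp <- .dm(a$val)
  new_op(y, list(a), list(function(g) ad_gather(g, idx, dim = in_shp)))
}

ad_reshape <- function(a, shp) {
  a <- as_node(a)
  v <- a$val
  old <- .dm(v)
  if (length(shp) > 1L) dim(v) <- shp else { dim(v) <- NULL; v <- as.numeric(v) }
  new_op(v, list(a), list(function(g) ad_reshape(g, old)))
}

ad_t <- function(a) {
  a <- as_node(a)
  new_op(t(a$val), list(a), list(function(g) ad_t(g)))
}

# ---- linear algebra --------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_op(a$val %*% b$val, list(a, b),
         list(function(g) ad_matmul(g, ad_t(b)),
              function(g) ad_matmul(ad_t(a), g)))
}

# batched matmul on 3-d arrays: (m,k,nb) x (k,n,nb) -> (m,n,nb)
.bmm_val <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, dim = c(da[1], db[2], da[3]))
  for (i in seq_len(da[3])) out[, , i] <- A[, , i] %*% B[, , i]
  out
}

ad_bt <- function(a) {  # batch transpose (m,n,nb) -> (n,m,nb)
  a <- as_node(a)
  new_op(aperm(a$val, c(2, 1, 3)), list(a), list(function(g) ad_bt(g)))
}

ad_bmm <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_op(.bmm_val(a$val, b$val), list(a, b),
         list(function(g) ad_bmm(g, ad_bt(b)),
              function(g) ad_bmm(ad_bt(a), g)))
}

# ---- backward pass ---------------------------------------------------------

# Accumulate gradients of `loss` (scalar node unless seed given) into the
# nodes listed in `wrt`.  Returns a list of gradient *nodes* aligned with
# `wrt`; their $val fields hold the numeric gradients, and because vjps are
# tape ops they can be differentiated again (double backprop).
ad_grad <- function(loss, wrt, seed = NULL) {
  stopifnot(is_node(loss))
  if (is.null(seed)) {
    stopifnot(length(loss$val) == 1L)
    seed <- ad_const(1)
  }
  # collect reachable subgraph (nodes needing grad), iteratively
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- vector("list", 256L); nn <- 0L
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$prn) if (isTRUE(p$req)) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  nodes <- nodes[ord]

  grads <- new.env(parent = emptyenv())
  grads[[as.character(loss$id)]] <- seed
  for (nd in nodes) {
    g <- grads[[as.character(nd$id)]]
    if (is.null(g)) next
    if (length(nd$prn) == 0L) next
    for (i in seq_along(nd$prn)) {
      p <- nd$prn[[i]]
      if (!isTRUE(p$req)) next
      contrib <- nd$vjp[[i]](g)
      key <- as.character(p$id)
      cur <- grads[[key]]
      grads[[key]] <- if (is.null(cur)) contrib else ad_add(cur, contrib)
    }
  }
  lapply(wrt, function(w) {
    g <- grads[[as.character(w$id)]]
    if (is.null(g)) ad_const(array(0, dim = .dm(w$val))) else g
  })
}
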