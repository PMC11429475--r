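# Dual-branch vision-transformer classifier: a convolutional stem tokenises
# the image, a transformer encoder contextualises the tokens, and a
# transformer decoder attends over learned query embeddings (DETR-style);
# the mean-pooled decoder output feeds a linear presence head of length 5.
# During training the same backbone (shared weights) processes the image and
# its contour map; feature alignment sums the two pre-softmax score vectors
# and the loss is class-weighted cross-entropy.  Inference uses the image
# branch only.

#' Backbone configuration
#'
#' The desk-scale defaults (64 x 64 input, hidden 64, 2+2 transformer
#' layers, 2 heads, 8 queries) train in minutes on a CPU; the full-scale
#' design mirrors the published configuration (6 encoder and 6 decoder
#' layers, dropout 0.1, learning rate 1e-5, weight decay 1e-6) via
#' `vit_config(full_scale = TRUE)`.
#'
#' @param image_size Input resolution (square).
#' @param hidden Token width; divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param n_encoder_layers,n_decoder_layers Transformer depth.
#' @param n_queries Learned decoder query embeddings.
#' @param dropout Dropout probability in [0, 1).
#' @param lr,weight_decay Optimiser settings.
#' @param patch_size Side of the square patches the convolutional stem
#'   embeds (kernel = stride = patch size); the token grid is
#'   image_size / patch_size per side.
#' @param n_classes Number of output classes (5).
#' @param full_scale Use the full-scale published configuration.
#' @export
vit_config <- function(image_size = 64L, hidden = 64L, n_heads = 2L,
                       n_encoder_layers = 2L, n_decoder_layers = 2L,
                       n_queries = 8L, dropout = 0.1,
                       lr = 1e-3, weight_decay = 1e-6,
                       patch_size = 8L,
                       n_classes = 5L, full_scale = FALSE) {
  if (full_scale) {
    image_size <- 512L; hidden <- 256L; n_heads <- 8L
    n_encoder_layers <- 6L; n_decoder_layers <- 6L; n_queries <- 64L
    lr <- 1e-5; patch_size <- 32L
  }
  stopifnot(hidden %% n_heads == 0, dropout >= 0, dropout < 1)
  stopifnot(image_size %% patch_size == 0)
  structure(list(image_size = as.integer(image_size), hidden = as.integer(hidden),
                 n_heads = as.integer(n_heads),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 n_queries = as.integer(n_queries), dropout = dropout,
                 lr = lr, weight_decay = weight_decay,
                 patch_size = as.integer(patch_size),
                 n_classes = as.integer(n_classes)),
            class = "vit_config")
}

.tf_layer_params <- function(prefix, hd, mlp = 2L * hd) {
  p <- list()
  for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(prefix, ".", nm)]] <- winit(hd, hd, sqrt(1 / hd))
  for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(prefix, ".", nm)]] <- numeric(hd)
  p[[paste0(prefix, ".ln1.g")]] <- rep(1, hd); p[[paste0(prefix, ".ln1.b")]] <- numeric(hd)
  p[[paste0(prefix, ".ln2.g")]] <- rep(1, hd); p[[paste0(prefix, ".ln2.b")]] <- numeric(hd)
  p[[paste0(prefix, ".W1")]] <- winit(hd, mlp); p[[paste0(prefix, ".b1")]] <- numeric(mlp)
  p[[paste0(prefix, ".W2")]] <- winit(mlp, hd, sqrt(1 / mlp)); p[[paste0(prefix, ".b2")]] <- numeric(hd)
  p
}

#' Initialise classifier state
#'
#' @param config A [vit_config()].
#' @param seed Weight-initialisation seed.
#' @return A `fv_cavit` state.
#' @export
vit_init <- function(config = vit_config(), seed = 1L) {
  hd <- config$hidden
  ps <- config$patch_size
  tok <- (config$image_size / ps)^2
  with_seed(seed, {
    p <- list()
    p[["stem.W"]] <- winit(ps * ps * 3, hd, sqrt(1 / (ps * ps * 3)))
    p[["stem.b"]] <- numeric(hd)
    p[["pos"]] <- matrix(stats::rnorm(tok * hd, sd = 0.02), tok, hd)
    p[["query"]] <- matrix(stats::rnorm(config$n_queries * hd, sd = 0.02),
                           config$n_queries, hd)
    for (l in seq_len(config$n_encoder_layers)) {
      p <- c(p, .tf_layer_params(paste0("enc", l), hd))
    }
    for (l in seq_len(config$n_decoder_layers)) {
      p <- c(p, .tf_layer_params(paste0("dec", l), hd))
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0("dec", l, ".x.", nm)]] <- winit(hd, hd, sqrt(1 / hd))
      }
      for (nm in c("bq", "bk", "bv", "bo")) p[[paste0("dec", l, ".x.", nm)]] <- numeric(hd)
      p[[paste0("dec", l, ".ln3.g")]] <- rep(1, hd)
      p[[paste0("dec", l, ".ln3.b")]] <- numeric(hd)
    }
    p[["head.W"]] <- winit(hd, config$n_classes, sqrt(1 / hd))
    p[["head.b"]] <- numeric(config$n_classes)
    structure(list(params = new_params(p), config = config, epoch = 0L,
                   class_weights = rep(1, config$n_classes),
                   history = tibble::tibble()),
              class = "fv_cavit")
  })
}

.tf_block <- function(x, L, prefix, B, Tq, nh, dropout, training,
                      kv = NULL, Tk = Tq, xprefix = NULL) {
  hd <- ncol(ad_val(x))
  # self-attention sublayer (pre-norm residual)
  h <- nn_layernorm(x, L[[paste0(prefix, ".ln1.g")]], L[[paste0(prefix, ".ln1.b")]])
  at <- nn_mha(h, h, L, prefix, B, Tq, Tq, nh)
  x <- ad_add(x, nn_dropout(at$out, dropout, training))
  attn <- at$attn
  # cross-attention sublayer for decoder blocks
  if (!is.null(kv)) {
    h <- nn_layernorm(x, L[[paste0(prefix, ".ln3.g")]], L[[paste0(prefix, ".ln3.b")]])
    at <- nn_mha(h, kv, L, xprefix, B, Tq, Tk, nh)
    x <- ad_add(x, nn_dropout(at$out, dropout, training))
    attn <- at$attn
  }
  h <- nn_layernorm(x, L[[paste0(prefix, ".ln2.g")]], L[[paste0(prefix, ".ln2.b")]])
  h <- nn_dense(ad_relu(nn_dense(h, L[[paste0(prefix, ".W1")]],
                                 L[[paste0(prefix, ".b1")]])),
                L[[paste0(prefix, ".W2")]], L[[paste0(prefix, ".b2")]])
  list(x = ad_add(x, nn_dropout(h, dropout, training)), attn = attn)
}

# full backbone forward; returns logits node plus pooled features and the
# last decoder cross-attention
.vit_forward <- function(state, x, L, training = FALSE) {
  cfg <- state$config
  d <- .dm(ad_val(x)); B <- d[4]
  ps <- cfg$patch_size
  h <- nn_conv2d(x, L[["stem.W"]], L[["stem.b"]], ps, ps, 0L)
  hd <- cfg$hidden
  dh <- .dm(ad_val(h))                       # (s, s, hidden, B)
  T <- dh[1] * dh[2]
  # (s,s,C,B) -> token matrix (B*T, C) with rows ordered (b-1)*T + t
  perm <- cache_get(paste("tokperm", T, hd, B, sep = "_"), function() {
    idx <- integer(B * T * hd)
    for (b in seq_len(B)) for (cc in seq_len(hd)) {
      tpos <- seq_len(T)
      dst <- ((b - 1L) * T + tpos) + B * T * (cc - 1L)
      src <- tpos + T * ((cc - 1L) + hd * (b - 1L))
      idx[dst] <- src
    }
    mark_dense(idx)
  })
  tokmat <- ad_gather(h, perm, dim = c(B * T, hd))
  posb <- cache_get(paste("posrep", T, hd, B, sep = "_"), function() {
    m <- matrix(seq_len(T * hd), T, hd)
    mark_dense(as.integer(m[rep(seq_len(T), B), ]))
  })
  tok <- ad_add(tokmat, ad_gather(L[["pos"]], posb, dim = c(B * T, hd)))
  for (l in seq_len(cfg$n_encoder_layers)) {
    tok <- .tf_block(tok, L, paste0("enc", l), B, T, cfg$n_heads,
                     cfg$dropout, training)$x
  }
  nq <- cfg$n_queries
  qrep <- cache_get(paste("qrep", nq, hd, B, sep = "_"), function() {
    m <- matrix(seq_len(nq * hd), nq, hd)
    mark_dense(as.integer(m[rep(seq_len(nq), B), ]))
  })
  q <- ad_gather(L[["query"]], qrep, dim = c(B * nq, hd))
  attn <- NULL
  for (l in seq_len(cfg$n_decoder_layers)) {
    bl <- .tf_block(q, L, paste0("dec", l), B, nq, cfg$n_heads,
                    cfg$dropout, training,
                    kv = tok, Tk = T, xprefix = paste0("dec", l, ".x"))
    q <- bl$x; attn <- bl$attn
  }
  # mean over queries -> presence head
  pool_grp <- cache_get(paste("poolg", nq, hd, B, sep = "_"), function() {
    # element (row = (b-1)*nq + qi, col = c) -> group (b-1)*hd + c
    b <- rep(rep(seq_len(B), each = nq), times = hd)
    cc <- rep(seq_len(hd), each = B * nq)
    mark_dense((b - 1L) * hd + cc)
  })
  pooled <- ad_reshape(ad_t(ad_reshape(ad_mul(ad_aggr(q, pool_grp, B * hd), 1 / nq),
                                       c(hd, B))), c(B, hd))
  logits <- nn_dense(pooled, L[["head.W"]], L[["head.b"]])
  list(logits = logits, pooled = pooled, attn = attn, grid = dh[1:2])
}

#' Backbone forward pass
#'
#' Convolutional stem, positional encoding, transformer encoder, decoder
#' over learned queries, mean-pooled presence head. Deterministic in
#' evaluation mode.
#'
#' @param state A `fv_cavit`.
#' @param images (H,W,3,B) array in [-1,1], or `labeled_image`(s).
#' @return B x 5 matrix of pre-softmax scores.
#' @export
backbone_forward <- function(state, images) {
  ad_reset()
  x <- images_to_array(images)
  if (dim(x)[1] != state$config$image_size) {
    rlang::abort("image resolution does not match the model", class = "fundusvit_bad_image")
  }
  L <- lapply(state$params$val, ad_const)
  ad_val(.vit_forward(state, ad_const(x), L, training = FALSE)$logits)
}

#' Feature alignment: sum the two branch score vectors
#'
#' Elementwise sum of the backbone's pre-softmax scores for the original
#' image and for its contour map (summing probabilities instead would break
#' normalisation). Commutative; the zero vector is the identity.
#'
#' @param f_img,f_contour Equal-length numeric vectors (or matrices).
#' @export
align_features <- function(f_img, f_contour) {
  if (length(f_img) != length(f_contour)) {
    rlang::abort("feature length mismatch", class = "fundusvit_bad_params")
  }
  f_img + f_contour
}

#' Inverse-frequency class weights
#'
#' w_j = N / (C * n_j) with N the total count over the C = 5 classes;
#' balanced counts give unit weights, and sum_j w_j n_j = N for any counts.
#'
#' @param counts Named (class name) or ordered vector of per-class counts,
#'   all positive.
#' @return Numeric weight vector of length 5 ordered by class code.
#' @export
class_weights_from_counts <- function(counts) {
  if (!is.null(names(counts))) {
    cl <- glaucoma_classes()
    v <- counts[cl$name]
    if (anyNA(v)) rlang::abort("counts must cover all five classes (or be unnamed length 5)",
                               class = "fundusvit_bad_params")
    counts <- as.numeric(v)
  }
  if (length(counts) != 5) rlang::abort("need 5 class counts", class = "fundusvit_bad_params")
  if (any(counts <= 0)) {
    rlang::abort("zero-count class: exclude the class or smooth its count before weighting",
                 class = "fundusvit_bad_params")
  }
  as.numeric(sum(counts) / (5 * counts))
}

#' Class-weighted cross-entropy
#'
#' L = -(1/N) sum_i sum_j w_j 1(y_i = j) log(p_ij) over a batch of
#' probability rows; equals the unweighted cross-entropy when all weights
#' are one. Zero probabilities at the true class are clamped at 1e-12 with
#' a warning.
#'
#' @param scores_batch N x 5 matrix of probability rows.
#' @param labels Class codes (0-4) or names, length N.
#' @param weights Positive weight vector of length 5.
#' @export
weighted_cross_entropy <- function(scores_batch, labels, weights = rep(1, 5)) {
  if (!is.matrix(scores_batch)) scores_batch <- matrix(scores_batch, nrow = 1)
  codes <- if (is.numeric(labels)) as.integer(labels) else label_code(labels)
  if (any(weights <= 0)) rlang::abort("weights must be positive", class = "fundusvit_bad_params")
  p <- scores_batch[cbind(seq_len(nrow(scores_batch)), codes + 1L)]
  if (any(p <= 0)) {
    rlang::warn("zero probability at the true class; clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  mean(-weights[codes + 1L] * log(p))
}

# weighted CE node from aligned logits (training path); equals Eq-12 algebra
.wce_node <- function(logits, codes, weights) {
  lsm <- nn_logsoftmax_rows(logits)
  B <- nrow(ad_val(logits))
  pick <- matrix(0, B, ncol(ad_val(logits)))
  pick[cbind(seq_len(B), codes + 1L)] <- weights[codes + 1L]
  ad_neg(ad_mul(ad_sumall(ad_mul(lsm, ad_const(pick))), 1 / B))
}

# resolve a manifest record to a labeled_image (path or in-memory store)
.load_record <- function(rec, store = NULL) {
  if (!is.null(store) && !is.null(store[[rec$id]])) return(store[[rec$id]])
  read_labeled_image(rec$path, label = rec$class, source = rec$source, id = rec$id)
}

#' Train the dual-branch classifier
#'
#' Every training record contributes the pair (image, contour map); each
#' step computes aligned scores ViT(image) + ViT(contour) with one shared
#' backbone and minimises the class-weighted cross-entropy, with weights
#' from the training-class distribution. Deterministic under `seed`.
#'
#' @param manifest Manifest tibble with `path`, `class` and `split`
#'   (`train` rows are used; `val` rows, if any, are scored per epoch).
#' @param contours Named list (by record id) of contour `labeled_image`s or
#'   binary edge matrices; missing entries are an error. Use
#'   [prepare_contours()] to build it.
#' @param config A [vit_config()].
#' @param epochs Training epochs.
#' @param seed Seed for initialisation, shuffling and dropout.
#' @param batch_size Minibatch size.
#' @param images Optional named list (by id) of in-memory `labeled_image`s,
#'   bypassing file I/O.
#' @return A trained `fv_cavit`; `$history` holds one row per epoch with
#'   train loss/accuracy and validation accuracy.
#' @export
train_classifier <- function(manifest, contours, config = vit_config(),
                             epochs = 10L, seed = 1L, batch_size = 25L,
                             images = NULL) {
  tr <- dplyr::filter(manifest, .data$split == "train")
  if (nrow(tr) == 0) rlang::abort("no training records", class = "fundusvit_bad_params")
  missing <- setdiff(tr$id, names(contours))
  if (length(missing)) {
    rlang::abort(paste0(length(missing), " training records lack contour maps (e.g. ",
                        missing[1], ")"), class = "fundusvit_missing_contour")
  }
  counts <- table(factor(tr$class, levels = glaucoma_classes()$name))
  present <- counts > 0
  w <- rep(1, 5)
  w[present] <- sum(counts[present]) / (sum(present) * counts[present])
  state <- vit_init(config, seed = seed)
  state$class_weights <- w

  img_arr <- images_to_array(lapply(seq_len(nrow(tr)), function(i)
    .load_record(tr[i, ], images)))
  ctr_arr <- contours_to_array(contours[tr$id])
  codes <- label_code(tr$class)
  va <- dplyr::filter(manifest, .data$split == "val")
  val_arr <- if (nrow(va)) images_to_array(lapply(seq_len(nrow(va)), function(i)
    .load_record(va[i, ], images))) else NULL

  n <- nrow(tr)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0; nb <- 0L
      for (st in seq(1L, n, by = batch_size)) {
        sel <- ord[st:min(st + batch_size - 1L, n)]
        ad_reset()               # no nodes live between batches
        L <- param_leaves(state$params)
        xi <- ad_const(img_arr[, , , sel, drop = FALSE])
        xc <- ad_const(ctr_arr[, , , sel, drop = FALSE])
        fi <- .vit_forward(state, xi, L, training = TRUE)$logits
        fc <- .vit_forward(state, xc, L, training = TRUE)$logits
        aligned <- ad_add(fi, fc)                       # feature alignment
        loss <- .wce_node(aligned, codes[sel], state$class_weights)
        grads <- ad_grad(loss, L)
        gv <- lapply(grads, ad_val)
        names(gv) <- names(state$params$val)
        adam_step(state$params, gv, lr = config$lr)
        # decoupled weight decay
        if (config$weight_decay > 0) {
          for (nm in names(state$params$val)) {
            state$params$val[[nm]] <- state$params$val[[nm]] *
              (1 - config$lr * config$weight_decay)
          }
        }
        ep_loss <- ep_loss + ad_val(loss); nb <- nb + 1L
        ep_hits <- ep_hits + sum(max.col(ad_val(aligned), ties.method = "first") - 1L ==
                                   codes[sel])
      }
      val_acc <- NA_real_
      if (!is.null(val_arr)) {
        pv <- predict_batch(state, val_arr)
        val_acc <- mean(pv == label_code(va$class))
      }
      state$history <- dplyr::bind_rows(state$history, tibble::tibble(
        epoch = ep, train_loss = ep_loss / nb, train_acc = ep_hits / n,
        val_acc = val_acc))
      state$epoch <- ep
    }
  })
  state
}

# grayscale/binary contour maps stacked to a 3-channel model array; edges
# are replicated so the shared backbone accepts both branches
contours_to_array <- function(contours) {
  first <- contours[[1]]
  m1 <- if (inherits(first, "contour_map")) first$edges else first
  H <- nrow(m1); W <- ncol(m1)
  a <- array(0, dim = c(H, W, 3, length(contours)))
  for (i in seq_along(contours)) {
    e <- contours[[i]]
    m <- if (inherits(e, "contour_map")) e$edges else e
    v <- m * 2 - 1                       # binary {0,1} -> [-1,1]
    a[, , 1, i] <- v; a[, , 2, i] <- v; a[, , 3, i] <- v
  }
  a
}

#' Extract contour maps for a set of manifest records
#'
#' @param manifest Manifest tibble.
#' @param params Contour parameters.
#' @param images Optional named list of in-memory images.
#' @return Named list (by record id) of `contour_map`s.
#' @export
prepare_contours <- function(manifest, params = contour_params(), images = NULL) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    extract_contour(.load_record(manifest[i, ], images), params)
  })
  names(out) <- manifest$id
  out
}

# batch predictions (class codes) from an image array, image branch only
predict_batch <- function(state, arr, batch = 50L) {
  n <- dim(arr)[4]
  out <- integer(n)
  for (st in seq(1L, n, by = batch)) {
    sel <- st:min(st + batch - 1L, n)
    lg <- backbone_forward(state, arr[, , , sel, drop = FALSE])
    out[sel] <- max.col(lg, ties.method = "first") - 1L
  }
  out
}

#' Predict the class of fundus images
#'
#' Inference uses only the image branch: scores are the softmax of
#' `backbone_forward` on the image; no contour map is computed or consumed.
#' Ties in the argmax resolve to the smallest class code.
#'
#' @param object A `fv_cavit`.
#' @param images A `labeled_image`, list of them, or (H,W,3,B) array.
#' @param ... Unused.
#' @return A tibble with one row per image: predicted `class`, `code` and
#'   the five per-class probabilities (summing to one).
#' @export
predict.fv_cavit <- function(object, images, ...) {
  if (object$epoch == 0L) {
    rlang::warn("predicting with an untrained classifier")
  }
  lg <- backbone_forward(object, images)
  p <- ad_val(nn_softmax_rows(ad_const(lg)))
  code <- max.col(p, ties.method = "first") - 1L
  colnames(p) <- glaucoma_classes()$name
  dplyr::bind_cols(tibble::tibble(class = label_name(code), code = code),
                   tibble::as_tibble(p))
}

#' Export decoder cross-attention maps
#'
#' Per-head cross-attention of the final decoder layer, averaged over
#' queries: each head's map over the token grid sums to one before being
#' upsampled (nearest-neighbour) to the input resolution.
#'
#' @param state A `fv_cavit`.
#' @param image A single image.
#' @return H x W x n_heads array of attention maps.
#' @export
export_attention_maps <- function(state, image) {
  x <- images_to_array(image)
  if (dim(x)[4] != 1) rlang::abort("one image at a time", class = "fundusvit_bad_params")
  L <- lapply(state$params$val, ad_const)
  fw <- .vit_forward(state, ad_const(x), L, training = FALSE)
  at <- fw$attn                                  # (nq, T, n_heads) for B = 1
  nh <- state$config$n_heads
  g <- fw$grid
  H <- dim(x)[1]
  out <- array(0, dim = c(H, H, nh))
  f <- H / g[1]
  for (h in seq_len(nh)) {
    m <- colMeans(at[, , h, drop = FALSE][, , 1, drop = TRUE])  # over queries
    m <- m / sum(m)                              # sums to one on the grid
    mm <- matrix(m, g[1], g[2])
    out[, , h] <- mm[ceiling(seq_len(H) / f), ceiling(seq_len(H) / f)]
  }
  out
}

#' Pooled backbone features for external embedding (e.g. t-SNE)
#'
#' @param state A `fv_cavit`.
#' @param images Images (list or array).
#' @return Tibble with one row per image and `hidden` feature columns.
#' @export
export_features <- function(state, images) {
  x <- images_to_array(images)
  L <- lapply(state$params$val, ad_const)
  n <- dim(x)[4]
  out <- NULL
  for (st in seq(1L, n, by = 50L)) {
    sel <- st:min(st + 49L, n)
    fw <- .vit_forward(state, ad_const(x[, , , sel, drop = FALSE]), L,
                       training = FALSE)
    out <- rbind(out, ad_val(fw$pooled))
  }
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  tibble::as_tibble(out)
}

#' @method tidy fv_cavit
#' @export
tidy.fv_cavit <- function(x, ...) x$history

#' @method glance fv_cavit
#' @export
glance.fv_cavit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = x$epoch,
                 train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
                 train_acc = if (nrow(h)) h$train_acc[nrow(h)] else NA_real_,
                 val_acc = if (nrow(h)) h$val_acc[nrow(h)] else NA_real_)
}
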