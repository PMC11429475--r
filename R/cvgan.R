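# Conditional GAN with an encoder-generator reconstruction path:
# the encoder E maps an image to a class estimate and a latent code, the
# generator G decodes (latent, class) back to an image, and the critic D
# scores realness (unbounded Wasserstein-style value) alongside auxiliary
# class logits.  Training couples a critic loss
#     LDc = E[Ds(fake) - Ds(real)] + LGP - lambda2 * LCEL
# with an encoder/generator objective
#     LEd = E[Ds(fake)] + lambda4 * logp(Dd(fake) = d)
#           - lambda5 * L1(x, fake) - LCEL
# maximised by E and G (implemented as minimising its negation).  LGP is the
# WGAN-GP gradient penalty lambda1 * E[(||grad Ds(xhat)||_2 - 1)^2] on
# per-sample interpolates xhat = eps x + (1 - eps) fake, trained with exact
# double backpropagation.  The critic uses no normalisation layers (the
# penalty is per-sample); E and G use batch norm.

#' CVGAN configuration
#'
#' @param image_size Square model resolution (divisible by 4).
#' @param latent_dim Dimension of the encoder's latent code.
#' @param base_channels Channel width of the first stage.
#' @param loss_weights Numeric vector lambda1..lambda5; lambda1 scales the
#'   gradient penalty, lambda2 the critic's auxiliary class loss, lambda4
#'   the generator's class-agreement reward, lambda5 the L1 reconstruction
#'   term. lambda3 is declared for completeness and enters no objective.
#' @param lr,beta1,beta2 Adam settings for all three networks.
#' @param n_critic Critic updates per encoder/generator update.
#' @param batch_size Minibatch size (the expectation operators in the
#'   objectives are batch means).
#' @export
cvgan_config <- function(image_size = 32L, latent_dim = 128L,
                         base_channels = 8L,
                         loss_weights = c(10, 1, 1, 1, 1),
                         lr = 1e-4, beta1 = 0.5, beta2 = 0.9,
                         n_critic = 5L, batch_size = 16L) {
  stopifnot(image_size %% 4 == 0, length(loss_weights) == 5,
            all(loss_weights >= 0))
  structure(list(image_size = as.integer(image_size),
                 latent_dim = as.integer(latent_dim),
                 base_channels = as.integer(base_channels),
                 loss_weights = loss_weights, lr = lr,
                 beta1 = beta1, beta2 = beta2,
                 n_critic = as.integer(n_critic),
                 batch_size = as.integer(batch_size)),
            class = "cvgan_config")
}

#' Initialise CVGAN state
#'
#' @param config A [cvgan_config()].
#' @param seed Seed for weight initialisation.
#' @return A `fv_cvgan` state holding parameter stores for E, G and D, the
#'   config, a step counter and an (initially empty) loss history.
#' @export
cvgan_init <- function(config = cvgan_config(), seed = 1L) {
  c0 <- config$base_channels; L <- config$latent_dim
  s0 <- config$image_size %/% 4L
  f_enc <- s0 * s0 * 2L * c0
  with_seed(seed, {
    E <- new_params(list(
      c1.W = winit(1 * 1 * 3, c0), c1.b = numeric(c0),
      c2.W = winit(1 * 1 * c0, c0), c2.b = numeric(c0),
      bn3.g = rep(1, c0), bn3.b = numeric(c0),
      c3.W = winit(3 * 3 * c0, 2 * c0), c3.b = numeric(2 * c0),
      bn4.g = rep(1, 2 * c0), bn4.b = numeric(2 * c0),
      c4.W = winit(1 * 1 * 2 * c0, 2 * c0), c4.b = numeric(2 * c0),
      bn5.g = rep(1, 2 * c0), bn5.b = numeric(2 * c0),
      c5.W = winit(1 * 1 * 2 * c0, 2 * c0), c5.b = numeric(2 * c0),
      d.W = winit(f_enc, 5, scale = sqrt(1 / f_enc)), d.b = numeric(5),
      z.W = winit(f_enc, L, scale = sqrt(1 / f_enc)), z.b = numeric(L)))
    G <- new_params(list(
      z.W = winit(L, f_enc, scale = sqrt(1 / L)),
      d.W = winit(5, f_enc, scale = sqrt(1 / 5)), in.b = numeric(f_enc),
      c1.W = winit(1 * 1 * 2 * c0, 2 * c0), c1.b = numeric(2 * c0),
      bn2.g = rep(1, 2 * c0), bn2.b = numeric(2 * c0),
      c2.W = winit(3 * 3 * 2 * c0, c0), c2.b = numeric(c0),
      bn3.g = rep(1, c0), bn3.b = numeric(c0),
      c3.W = winit(1 * 1 * c0, c0), c3.b = numeric(c0),
      bn4.g = rep(1, c0), bn4.b = numeric(c0),
      c4.W = winit(1 * 1 * c0, 3), c4.b = numeric(3)))
    D <- new_params(list(
      c1.W = winit(3 * 3 * 3, c0), c1.b = numeric(c0),
      c2.W = winit(1 * 1 * c0, c0), c2.b = numeric(c0),
      c3.W = winit(3 * 3 * c0, 2 * c0), c3.b = numeric(2 * c0),
      c4.W = winit(1 * 1 * 2 * c0, 2 * c0), c4.b = numeric(2 * c0),
      c5.W = winit(3 * 3 * 2 * c0, 4 * c0), c5.b = numeric(4 * c0),
      ds.W = winit(s0 * s0 * 4 * c0, 1, scale = sqrt(1 / (s0 * s0 * 4 * c0))),
      ds.b = numeric(1),
      dd.W = winit(s0 * s0 * 4 * c0, 5, scale = sqrt(1 / (s0 * s0 * 4 * c0))),
      dd.b = numeric(5)))
    log <- new.env(parent = emptyenv())
    log$rows <- list()
    structure(list(E = E, G = G, D = D, config = config, step = 0L,
                   log = log),
              class = "fv_cvgan")
  })
}

#' @export
`$.fv_cvgan` <- function(x, name) {
  if (name == "history") {
    lg <- unclass(x)$log
    rows <- if (is.null(lg)) NULL else lg$rows
    if (!length(rows)) return(tibble::tibble())
    return(dplyr::bind_rows(rows))
  }
  unclass(x)[[name]]
}

# (H,W,C,B) node -> (B, H*W*C) matrix node
.flatten_bhwc <- function(x) {
  d <- .dm(ad_val(x))
  ad_t(ad_reshape(x, c(prod(d[1:3]), d[4])))
}

.enc_forward <- function(state, x, L, training = TRUE) {
  # 1x1 stem, then strided 1x1 stages so the 3x3 stage runs at half
  # resolution; heads read the flattened quarter-resolution features
  h <- nn_conv2d(x, L$c1.W, L$c1.b, 1L, 1L, 0L)
  h <- nn_conv2d(ad_relu(h), L$c2.W, L$c2.b, 1L, 2L, 0L)
  h <- nn_batchnorm(h, L$bn3.g, L$bn3.b, state$E, "bn3", training)
  h <- nn_conv2d(ad_relu(h), L$c3.W, L$c3.b, 3L, 1L, 1L)
  h <- nn_batchnorm(h, L$bn4.g, L$bn4.b, state$E, "bn4", training)
  h <- nn_conv2d(ad_relu(h), L$c4.W, L$c4.b, 1L, 2L, 0L)
  h <- nn_batchnorm(h, L$bn5.g, L$bn5.b, state$E, "bn5", training)
  h <- nn_conv2d(ad_relu(h), L$c5.W, L$c5.b, 1L, 1L, 0L)
  f <- .flatten_bhwc(h)
  list(d_logits = nn_dense(f, L$d.W, L$d.b),
       z = nn_dense(f, L$z.W, L$z.b))
}

.gen_forward <- function(state, z, onehot, L, training = TRUE) {
  cfg <- state$config
  c0 <- cfg$base_channels; s0 <- cfg$image_size %/% 4L
  h <- ad_bias_rows(ad_add(ad_matmul(z, L$z.W), ad_matmul(onehot, L$d.W)), L$in.b)
  B <- nrow(ad_val(z))
  h <- ad_reshape(ad_t(h), c(s0, s0, 2L * c0, B))
  h <- nn_conv2d(ad_relu(h), L$c1.W, L$c1.b, 1L, 1L, 0L)
  h <- nn_batchnorm(h, L$bn2.g, L$bn2.b, state$G, "bn2", training)
  h <- nn_conv2d(ad_relu(h), L$c2.W, L$c2.b, 3L, 1L, 1L)  # 3x3 at low res
  h <- nn_upsample2x(h)
  h <- nn_batchnorm(h, L$bn3.g, L$bn3.b, state$G, "bn3", training)
  h <- nn_conv2d(ad_relu(h), L$c3.W, L$c3.b, 1L, 1L, 0L)
  h <- nn_upsample2x(h)
  h <- nn_batchnorm(h, L$bn4.g, L$bn4.b, state$G, "bn4", training)
  h <- nn_conv2d(ad_relu(h), L$c4.W, L$c4.b, 1L, 1L, 0L)
  ad_tanh(h)
}

.disc_forward <- function(x, L) {
  # 3x3 stride-1 stem per the architecture sketch; strided 1x1 stages put
  # the remaining 3x3 convolutions at reduced resolution
  h <- nn_conv2d(x, L$c1.W, L$c1.b, 3L, 1L, 1L)
  h <- nn_conv2d(ad_lrelu(h), L$c2.W, L$c2.b, 1L, 2L, 0L)
  h <- nn_conv2d(ad_lrelu(h), L$c3.W, L$c3.b, 3L, 1L, 1L)
  h <- nn_conv2d(ad_lrelu(h), L$c4.W, L$c4.b, 1L, 2L, 0L)
  h <- nn_conv2d(ad_lrelu(h), L$c5.W, L$c5.b, 3L, 1L, 1L)
  f <- .flatten_bhwc(ad_lrelu(h))
  list(ds = nn_dense(f, L$ds.W, L$ds.b), dd = nn_dense(f, L$dd.W, L$dd.b))
}

.onehot <- function(codes, k = 5L) {
  m <- matrix(0, length(codes), k)
  m[cbind(seq_along(codes), codes + 1L)] <- 1
  m
}

# stack labeled_images (or an existing array) into (H,W,3,B) in [-1, 1]
images_to_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  if (inherits(images, "labeled_image")) images <- list(images)
  d <- dim(images[[1]]$pixels)
  a <- array(0, dim = c(d[1], d[2], 3, length(images)))
  for (i in seq_along(images)) a[, , , i] <- images[[i]]$pixels / 127.5 - 1
  a
}

array_to_images <- function(a, labels, ids, source = "generated") {
  lapply(seq_len(dim(a)[4]), function(i) {
    px <- array(as.integer(pmin(pmax(round((a[, , , i] + 1) * 127.5), 0), 255)),
                dim = dim(a)[1:3])
    structure(list(pixels = px, label = labels[i], source = source, id = ids[i]),
              class = "labeled_image")
  })
}

#' Encode images to class estimate and latent code
#'
#' Evaluation-mode forward pass of the encoder: deterministic for fixed
#' weights and input. The class estimate is a softmax probability vector.
#'
#' @param state A `fv_cvgan`.
#' @param images `labeled_image`(s) or an (H,W,3,B) array in [-1,1].
#' @return List with `class_probs` (B x 5) and `latent` (B x latent_dim).
#' @export
cvgan_encode <- function(state, images) {
  ad_reset()
  x <- ad_const(images_to_array(images))
  L <- lapply(state$E$val, ad_const)
  eo <- .enc_forward(state, x, L, training = FALSE)
  list(class_probs = ad_val(nn_softmax_rows(eo$d_logits)),
       latent = ad_val(eo$z))
}

#' Generate images from latent codes and class labels
#'
#' @param state A `fv_cvgan`.
#' @param z B x latent_dim matrix of latent codes.
#' @param labels Class names or codes, length B.
#' @return (H,W,3,B) array with values in [-1, 1] (tanh output); rescaled to
#'   8-bit on export.
#' @export
cvgan_generate <- function(state, z, labels) {
  codes <- if (is.numeric(labels)) {
    if (any(labels < 0 | labels > 4)) {
      rlang::abort("class code outside 0-4", class = "fundusvit_bad_label")
    }
    as.integer(labels)
  } else label_code(labels)
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  ad_reset()
  L <- lapply(state$G$val, ad_const)
  ad_val(.gen_forward(state, ad_const(z), ad_const(.onehot(codes)), L,
                      training = FALSE))
}

#' Interpolate real and generated samples for the gradient penalty
#'
#' xhat = eps * x + (1 - eps) * x_gen, elementwise; eps may be a scalar or a
#' per-sample vector, each entry in [0, 1].
#'
#' @param x,x_gen Arrays of identical shape ((H,W,3,B) or any).
#' @param eps Interpolation factor(s) in [0, 1].
#' @export
interpolate_gp_sample <- function(x, x_gen, eps) {
  if (any(eps < 0 | eps > 1)) {
    rlang::abort("eps must lie in [0, 1]", class = "fundusvit_bad_params")
  }
  if (!identical(dim(x), dim(x_gen))) {
    rlang::abort("shape mismatch", class = "fundusvit_bad_params")
  }
  if (length(eps) == 1L) return(eps * x + (1 - eps) * x_gen)
  d <- dim(x)
  ee <- array(rep(eps, each = prod(d[-length(d)])), dim = d)
  ee * x + (1 - ee) * x_gen
}

# node-level gradient penalty; critic_fn maps an image node to a length-B
# realness node.  Per-sample input gradients exist because the critic has no
# cross-sample coupling (no batch norm).
.gp_node <- function(critic_fn, xhat, lambda1) {
  xl <- ad_leaf(xhat)
  ds <- critic_fn(xl)
  g <- ad_grad(ad_sumall(ds), list(xl))[[1]]
  d <- .dm(xhat)
  B <- d[length(d)]
  grp <- rep(seq_len(B), each = prod(d[-length(d)]))
  nrm <- ad_sqrt(ad_aggr(ad_mul(g, g), grp, B))
  dev <- ad_sub(nrm, 1)
  ad_mul(ad_mean(ad_mul(dev, dev)), lambda1)
}

#' WGAN-GP gradient penalty
#'
#' lambda1 * E[(||grad_xhat Ds(xhat)||_2 - 1)^2], the expectation a batch
#' mean over per-sample gradient norms. The gradient is computed exactly by
#' reverse-mode differentiation of the critic.
#'
#' @param critic Either a `fv_cvgan` state (its critic is used) or a function
#'   mapping an image node to a length-B realness node.
#' @param x_hat Interpolated input array (H,W,C,B).
#' @param lambda1 Penalty weight (default 10).
#' @return Penalty value (non-negative scalar).
#' @export
gradient_penalty <- function(critic, x_hat, lambda1 = 10) {
  fn <- if (inherits(critic, "fv_cvgan")) {
    L <- lapply(critic$D$val, ad_const)
    function(x) .disc_forward(x, L)$ds
  } else critic
  v <- ad_val(.gp_node(fn, x_hat, lambda1))
  if (!is.finite(v)) {
    rlang::abort("non-finite gradient penalty", class = "fundusvit_numeric_error")
  }
  v
}

# cross-entropy node from logits and true codes (batch mean)
.ce_node <- function(logits, codes) {
  lsm <- nn_logsoftmax_rows(logits)
  B <- nrow(ad_val(logits))
  pick <- matrix(0, B, ncol(ad_val(logits)))
  pick[cbind(seq_len(B), codes + 1L)] <- 1
  ad_neg(ad_mul(ad_sumall(ad_mul(lsm, ad_const(pick))), 1 / B))
}

#' Auxiliary classifier cross-entropy loss
#'
#' Categorical cross-entropy of the softmax of the class logits against the
#' true class, averaged over the batch (AC-GAN convention). Non-negative and
#' approaching zero as the true-class probability approaches one.
#'
#' @param class_logits B x 5 matrix of logits (a single vector is treated as
#'   one sample).
#' @param true_class Class names or codes.
#' @export
aux_class_loss <- function(class_logits, true_class) {
  if (!is.matrix(class_logits)) class_logits <- matrix(class_logits, nrow = 1)
  codes <- if (is.numeric(true_class)) as.integer(true_class) else label_code(true_class)
  if (any(codes < 0 | codes > 4)) {
    rlang::abort("class code outside 0-4", class = "fundusvit_bad_label")
  }
  ad_val(.ce_node(ad_const(class_logits), codes))
}

#' Softmax-entropy diagnostic monitor
#'
#' The literal self-entropy -sum p log p of the softmax of the class logits,
#' averaged over the batch; a label-free diagnostic of how peaked the
#' auxiliary classifier is (it trains nothing).
#'
#' @inheritParams aux_class_loss
#' @export
entropy_monitor <- function(class_logits) {
  if (!is.matrix(class_logits)) class_logits <- matrix(class_logits, nrow = 1)
  p <- ad_val(nn_softmax_rows(ad_const(class_logits)))
  mean(-rowSums(p * log(pmax(p, 1e-12))))
}

#' Critic (discriminator) loss
#'
#' LDc = E[Ds(fake) - Ds(real)] + gp - lambda2 * lcel, the critic's
#' minimisation objective; expectations are batch means of the supplied
#' score vectors.
#'
#' @param ds_fake,ds_real Critic realness scores (scalars or vectors).
#' @param gp Gradient-penalty value.
#' @param lcel Auxiliary class loss value.
#' @param weights Loss-weight vector lambda1..lambda5.
#' @export
discriminator_loss <- function(ds_fake, ds_real, gp, lcel,
                               weights = c(10, 1, 1, 1, 1)) {
  mean(ds_fake) - mean(ds_real) + gp - weights[2] * lcel
}

#' Encoder/generator loss
#'
#' LEd = E[Ds(fake)] + lambda4 * p(Dd(fake) = d) - lambda5 * L1(x, fake)
#'       - lcel; E and G are trained to maximise this value (implemented by
#' minimising its negation). The class-agreement term is the mean
#' log-probability of the conditioning class under the critic's auxiliary
#' head.
#'
#' @param ds_fake Critic realness scores of generated samples.
#' @param class_logprob_fake Mean log-probability of the true class under
#'   softmax of the critic's class logits for the generated samples.
#' @param l1_recon Reconstruction error: the L1 norm ||x - fake||_1 per
#'   sample, averaged over the batch (non-negative).
#' @param lcel Encoder's class loss value.
#' @param weights Loss-weight vector lambda1..lambda5.
#' @export
encoder_generator_loss <- function(ds_fake, class_logprob_fake, l1_recon, lcel,
                                   weights = c(10, 1, 1, 1, 1)) {
  if (l1_recon < 0) rlang::abort("l1_recon must be >= 0", class = "fundusvit_bad_params")
  mean(ds_fake) + weights[4] * class_logprob_fake - weights[5] * l1_recon - lcel
}

#' Combined objective (monitoring only)
#'
#' The sum LEd + LDc; reported for monitoring, the two parts are optimised
#' by disjoint parameter sets.
#' @param led,ldc Loss values.
#' @export
total_objective <- function(led, ldc) led + ldc

#' One CVGAN training step
#'
#' Performs `n_critic` critic updates (minimising the critic loss with the
#' gradient penalty trained through double backpropagation) followed by one
#' joint encoder+generator update (maximising the encoder/generator loss).
#' The interpolation factor eps is drawn fresh per sample. Aborts with
#' diagnostics if any recorded loss is non-finite.
#'
#' @param state A `fv_cvgan`.
#' @param images (H,W,3,B) array in [-1,1] (or list of `labeled_image`).
#' @param labels Class codes or names, length B.
#' @return The state, with one row appended to its loss history.
#' @export
cvgan_train_step <- function(state, images, labels) {
  ad_reset()                     # no nodes live between steps
  cfg <- state$config
  w <- cfg$loss_weights
  x <- images_to_array(images)
  codes <- if (is.numeric(labels)) as.integer(labels) else label_code(labels)
  B <- dim(x)[4]
  oh <- .onehot(codes)

  ldc_v <- gp_v <- NA_real_
  # fake batch from the current E/G, detached for the critic updates (E and
  # G do not move during the critic loop, so one reconstruction serves all
  # n_critic iterations; only eps is redrawn)
  EL <- lapply(state$E$val, ad_const)
  GL <- lapply(state$G$val, ad_const)
  z <- ad_val(.enc_forward(state, ad_const(x), EL, training = FALSE)$z)
  xf <- ad_val(.gen_forward(state, ad_const(z), ad_const(oh), GL, training = FALSE))
  # real and fake blocks share one stacked critic forward (D has no
  # cross-sample coupling); the gradient penalty keeps its own small
  # forward so the double-backprop graph covers only the interpolates
  d4 <- dim(x)
  xrf <- array(c(x, xf), dim = c(d4[1:3], 2L * B))
  sel_real <- matrix(0, 1, 2 * B); sel_real[1, seq_len(B)] <- 1 / B
  sel_fake <- matrix(0, 1, 2 * B); sel_fake[1, B + seq_len(B)] <- 1 / B
  sel_dd <- matrix(0, B, 2 * B); sel_dd[cbind(seq_len(B), seq_len(B))] <- 1
  for (it in seq_len(cfg$n_critic)) {
    DLeaf <- param_leaves(state$D)
    eps <- stats::runif(B)
    xhat <- interpolate_gp_sample(x, xf, eps)
    gp <- .gp_node(function(xn) .disc_forward(xn, DLeaf)$ds, xhat, w[1])
    dall <- .disc_forward(ad_const(xrf), DLeaf)
    lcel <- .ce_node(ad_matmul(ad_const(sel_dd), dall$dd), codes)
    # optimisation objective: the critic *minimises* its auxiliary class
    # cross-entropy (AC-GAN convention); the printed loss composition with
    # the opposite sign is unbounded below in the class head and diverges,
    # so it is kept for reporting only (see discriminator_loss())
    wdist <- ad_sub(ad_matmul(ad_const(sel_fake), dall$ds),
                    ad_matmul(ad_const(sel_real), dall$ds))
    opt <- ad_sumall(ad_add(wdist, ad_add(gp, ad_mul(lcel, w[2]))))
    grads <- ad_grad(opt, DLeaf)
    adam_step(state$D, lapply(grads, ad_val), lr = cfg$lr,
              beta1 = cfg$beta1, beta2 = cfg$beta2)
    ldc_v <- discriminator_loss(as.numeric(ad_val(ad_matmul(ad_const(sel_fake), dall$ds))),
                                as.numeric(ad_val(ad_matmul(ad_const(sel_real), dall$ds))),
                                ad_val(gp), ad_val(lcel), w)
    gp_v <- ad_val(gp)
  }

  # encoder + generator update through a frozen critic
  ELeaf <- param_leaves(state$E)
  GLeaf <- param_leaves(state$G)
  DC <- lapply(state$D$val, ad_const)
  eo <- .enc_forward(state, ad_const(x), ELeaf, training = TRUE)
  xfn <- .gen_forward(state, eo$z, ad_const(oh), GLeaf, training = TRUE)
  dfo <- .disc_forward(xfn, DC)
  logp <- ad_neg(.ce_node(dfo$dd, codes))        # mean log p(true class)
  # L1 norm per sample (sum of absolute residuals), averaged over the batch
  l1 <- ad_mul(ad_sumall(ad_abs(ad_sub(ad_const(x), xfn))), 1 / B)
  lcel_e <- .ce_node(eo$d_logits, codes)
  led <- ad_sub(ad_add(ad_mean(dfo$ds), ad_mul(logp, w[4])),
                ad_add(ad_mul(l1, w[5]), lcel_e))
  grads <- ad_grad(ad_neg(led), c(ELeaf, GLeaf))
  ne <- length(ELeaf)
  adam_step(state$E, lapply(grads[seq_len(ne)], ad_val), lr = cfg$lr,
            beta1 = cfg$beta1, beta2 = cfg$beta2)
  adam_step(state$G, lapply(grads[-seq_len(ne)], ad_val), lr = cfg$lr,
            beta1 = cfg$beta1, beta2 = cfg$beta2)

  npx <- prod(dim(x)[1:3])
  rec <- tibble::tibble(step = state$step + 1L, ldc = ldc_v,
                        led = ad_val(led), gp = gp_v,
                        l1 = ad_val(l1), l1_px = ad_val(l1) / npx,
                        lcel = ad_val(lcel_e),
                        total = total_objective(ad_val(led), ldc_v))
  if (!all(is.finite(unlist(rec)))) {
    rlang::abort(paste0("non-finite loss at step ", state$step + 1L, ": ",
                        paste(names(rec), round(unlist(rec), 4), collapse = ", ")),
                 class = "fundusvit_numeric_error")
  }
  state$step <- state$step + 1L
  state$log$rows[[length(state$log$rows) + 1L]] <- rec
  state
}

#' Train the CVGAN on labelled images
#'
#' Minibatches are sampled with replacement under the given seed, so a fixed
#' seed reproduces the loss trace exactly.
#'
#' @param state A `fv_cvgan`.
#' @param images List of `labeled_image` (all at the model resolution).
#' @param labels Class names or codes (defaults to the image labels).
#' @param steps Number of [cvgan_train_step()] calls.
#' @param seed Seed for batch sampling and interpolation draws.
#' @export
cvgan_train <- function(state, images, labels = NULL, steps = 100L, seed = 1L) {
  if (is.null(labels)) labels <- vapply(images, function(i) i$label, character(1))
  codes <- if (is.numeric(labels)) as.integer(labels) else label_code(labels)
  arr <- images_to_array(images)
  B <- state$config$batch_size
  with_seed(seed, {
    for (s in seq_len(steps)) {
      pick <- sample.int(dim(arr)[4], B, replace = TRUE)
      state <- cvgan_train_step(state, arr[, , , pick, drop = FALSE], codes[pick])
    }
  })
  state
}

#' Sample class-conditional synthetic images
#'
#' Draws latent codes from N(0, I) and decodes them with the generator,
#' conditioning on each requested class; produces exactly the requested
#' counts, labelled with the conditioning class and tagged
#' `source = "generated"`. Deterministic under the seed.
#'
#' @param state A `fv_cvgan`.
#' @param class_counts Named non-negative integer vector.
#' @param seed Sampling seed.
#' @param dir,write_images Optional PNG materialisation.
#' @return List with `images` (list of `labeled_image`) and `manifest`
#'   (tibble rows with `split = "train"`).
#' @export
sample_synthetic <- function(state, class_counts, seed = 1L,
                             dir = NULL, write_images = FALSE) {
  if (any(class_counts < 0)) {
    rlang::abort("negative class count", class = "fundusvit_bad_params")
  }
  if (write_images && !is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  imgs <- list(); rows <- list()
  for (cls in names(class_counts)) {
    k <- class_counts[[cls]]
    if (k == 0) next
    code <- label_code(cls)
    z <- with_seed(derive_seed(seed, code, 0L),
                   matrix(stats::rnorm(k * state$config$latent_dim),
                          k, state$config$latent_dim))
    ids <- sprintf("%s_gen_%05d", gsub("/", "-", cls), seq_len(k))
    paths <- rep(NA_character_, k)
    bs <- 64L
    for (st in seq(1L, k, by = bs)) {
      en <- min(st + bs - 1L, k)
      a <- cvgan_generate(state, z[st:en, , drop = FALSE], rep(code, en - st + 1L))
      gi <- array_to_images(a, rep(cls, en - st + 1L), ids[st:en])
      if (write_images) {
        for (j in seq_along(gi)) {
          p <- file.path(dir, paste0(gi[[j]]$id, ".png"))
          write_labeled_image(gi[[j]], p)
          paths[st + j - 1L] <- p
        }
      }
      imgs <- c(imgs, gi)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = ids, path = paths, class = cls, source = "generated", split = "train")
  }
  list(images = imgs, manifest = dplyr::bind_rows(rows))
}

#' @method tidy fv_cvgan
#' @export
tidy.fv_cvgan <- function(x, ...) x$history

#' @method glance fv_cvgan
#' @export
glance.fv_cvgan <- function(x, ...) {
  h <- x$history
  tibble::tibble(steps = x$step,
                 l1 = if (nrow(h)) h$l1[nrow(h)] else NA_real_,
                 ldc = if (nrow(h)) h$ldc[nrow(h)] else NA_real_,
                 led = if (nrow(h)) h$led[nrow(h)] else NA_real_)
}
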