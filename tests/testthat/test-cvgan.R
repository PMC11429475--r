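ns <- asNamespace("fundusvit")

tiny_gan <- function(seed = 1, size = 16L, batch = 4L) {
  cvgan_init(cvgan_config(image_size = size, latent_dim = 8L,
                          base_channels = 4L, batch_size = batch,
                          n_critic = 2L), seed = seed)
}

test_that("encoder output obeys the softmax and latent contracts", {
  st <- tiny_gan()
  x <- fundusvit:::images_to_array(two_class_phantoms(3))
  eo <- cvgan_encode(st, x)
  expect_equal(rowSums(eo$class_probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(eo$class_probs >= 0))
  expect_equal(ncol(eo$latent), 8)
  expect_true(all(is.finite(eo$latent)))
  eo2 <- cvgan_encode(st, x)
  expect_identical(eo, eo2)                 # eval mode is deterministic
})

test_that("generator emits bounded image-shaped output deterministically", {
  st <- tiny_gan()
  set.seed(1)
  z <- matrix(rnorm(5 * 8), 5, 8)
  g1 <- cvgan_generate(st, z, rep("glaucoma", 5))
  expect_equal(dim(g1), c(16, 16, 3, 5))
  expect_true(all(g1 >= -1 & g1 <= 1))
  expect_identical(g1, cvgan_generate(st, z, rep("glaucoma", 5)))
  # 100 latent draws all bounded
  z2 <- matrix(rnorm(100 * 8), 100, 8)
  g2 <- cvgan_generate(st, z2, rep(0L, 100))
  expect_true(all(g2 >= -1 & g2 <= 1))
  expect_error(cvgan_generate(st, z, rep(9L, 5)), class = "fundusvit_bad_label")
})

test_that("interpolation endpoints and midpoint are exact", {
  x <- array(0, dim = c(2, 2, 1, 2))
  y <- array(2, dim = c(2, 2, 1, 2))
  expect_identical(interpolate_gp_sample(x, y, 1), x)
  expect_identical(interpolate_gp_sample(x, y, 0), y)
  expect_true(all(interpolate_gp_sample(x, y, 0.5) == 1))
  # per-sample vector form
  half <- interpolate_gp_sample(x, y, c(1, 0))
  expect_true(all(half[, , , 1] == 0) && all(half[, , , 2] == 2))
  expect_error(interpolate_gp_sample(x, y, 1.5), class = "fundusvit_bad_params")
  expect_error(interpolate_gp_sample(x, array(0, dim = c(2, 2, 1, 1)), 0.5),
               class = "fundusvit_bad_params")
})

test_that("gradient penalty matches analytic closed forms", {
  set.seed(4)
  H <- 4; W <- 4; C <- 3; B <- 3
  w <- array(rnorm(H * W * C), dim = c(H, W, C))
  w <- w / sqrt(sum(w^2))
  flat <- get(".flatten_bhwc", ns)
  mm <- get("ad_matmul", ns); cst <- get("ad_const", ns)
  addn <- get("ad_add", ns); muln <- get("ad_mul", ns)
  lin <- function(sc) function(xn) mm(flat(xn), cst(matrix(sc * as.numeric(w))))
  const_critic <- function(xn) addn(muln(mm(flat(xn),
                                            cst(matrix(0, H * W * C, 1))), 1), 3)
  xh <- array(rnorm(H * W * C * B), dim = c(H, W, C, B))
  expect_lt(abs(gradient_penalty(lin(1), xh, 10)), 1e-6)      # unit-norm: 0
  expect_equal(gradient_penalty(const_critic, xh, 10), 10)    # zero grad
  expect_equal(gradient_penalty(lin(2), xh, 10), 10, tolerance = 1e-5)
  # a trained-state critic yields a finite non-negative value
  st <- tiny_gan()
  xh2 <- array(rnorm(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  gp <- gradient_penalty(st, xh2)
  expect_gte(gp, 0)
})

test_that("auxiliary class loss matches the softmax cross-entropy oracle", {
  # certain prediction: zero loss
  big <- c(100, 0, 0, 0, 0)
  expect_lt(aux_class_loss(big, 0L), 1e-6)
  # uniform logits: ln 5
  expect_equal(aux_class_loss(rep(1, 5), 3L), log(5), tolerance = 1e-9)
  # random logits against a naive transcription
  set.seed(8)
  lg <- matrix(rnorm(4 * 5), 4, 5)
  codes <- c(0L, 2L, 4L, 1L)
  naive <- mean(vapply(1:4, function(i) {
    p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
    -log(p[codes[i] + 1])
  }, numeric(1)))
  expect_equal(aux_class_loss(lg, codes), naive, tolerance = 1e-9)
  expect_error(aux_class_loss(lg, c(0L, 1L, 2L, 9L)),
               class = "fundusvit_bad_label")
  # the entropy monitor is the label-free self entropy
  expect_equal(entropy_monitor(rep(0, 5)), log(5), tolerance = 1e-9)
})

test_that("critic and encoder/generator losses reproduce hand arithmetic", {
  w <- c(10, 1, 1, 1, 1)
  expect_equal(discriminator_loss(0, 0, 0, 0, w), 0)
  expect_equal(discriminator_loss(2, 1, 10, log(5), w), 2 - 1 + 10 - log(5))
  expect_equal(discriminator_loss(2, 1, 10, 1.6094, w), 9.3906)
  # linearity in the real score
  d0 <- discriminator_loss(2, 1, 0.5, 0.1, w)
  expect_equal(discriminator_loss(2, 1 + 0.3, 0.5, 0.1, w), d0 - 0.3)
  expect_equal(encoder_generator_loss(3, 0, 0, 0, w), 3)
  expect_equal(encoder_generator_loss(1, -0.1, 0.5, 0.2, w), 0.2)
  e0 <- encoder_generator_loss(1, -0.1, 0.5, 0.2, w)
  expect_equal(encoder_generator_loss(1, -0.1, 0.5 + 0.25, 0.2, w), e0 - 0.25)
  expect_error(encoder_generator_loss(1, 0, -0.5, 0, w),
               class = "fundusvit_bad_params")
  # total objective is the plain sum, symmetric
  expect_equal(total_objective(0.2, 9.3906), 9.5906)
  expect_equal(total_objective(0, 0), 0)
  expect_equal(total_objective(1.2, 3.4), total_objective(3.4, 1.2))
  # property: random finite inputs against direct transcription
  set.seed(11)
  for (k in 1:20) {
    v <- rnorm(4); lw <- c(10, runif(4, 0, 2))
    expect_equal(discriminator_loss(v[1], v[2], abs(v[3]), abs(v[4]), lw),
                 v[1] - v[2] + abs(v[3]) - lw[2] * abs(v[4]), tolerance = 1e-12)
    expect_equal(encoder_generator_loss(v[1], v[2], abs(v[3]), abs(v[4]), lw),
                 v[1] + lw[4] * v[2] - lw[5] * abs(v[3]) - abs(v[4]),
                 tolerance = 1e-12)
  }
})

test_that("short training runs are finite-loss and reproducible", {
  imgs <- two_class_phantoms(8)
  st1 <- cvgan_train(tiny_gan(seed = 3), imgs, steps = 3, seed = 5)
  expect_true(all(is.finite(unlist(st1$history[, -1]))))
  st2 <- cvgan_train(tiny_gan(seed = 3), imgs, steps = 3, seed = 5)
  expect_identical(st1$history, st2$history)
})

test_that("synthetic sampling hits requested counts with conditioning labels", {
  st <- tiny_gan()
  out <- sample_synthetic(st, c(glaucoma = 7), seed = 2)
  expect_equal(length(out$images), 7)
  expect_true(all(vapply(out$images, function(i) i$label, "") == "glaucoma"))
  expect_true(all(out$manifest$source == "generated"))
  expect_true(all(out$manifest$split == "train"))
  out2 <- sample_synthetic(st, c(glaucoma = 7), seed = 2)
  expect_identical(lapply(out$images, `[[`, "pixels"),
                   lapply(out2$images, `[[`, "pixels"))
  mixed <- sample_synthetic(st, c(normal = 2, suspect = 3), seed = 1)
  expect_equal(as.integer(table(mixed$manifest$class)[c("normal", "suspect")]),
               c(2L, 3L))
  expect_error(sample_synthetic(st, c(normal = -1)),
               class = "fundusvit_bad_params")
})
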