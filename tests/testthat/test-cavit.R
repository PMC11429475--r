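tiny_vit <- function(...) vit_config(image_size = 32L, hidden = 16L,
                                     n_heads = 2L, n_queries = 4L,
                                     patch_size = 8L, dropout = 0, ...)

test_that("backbone forward meets shape, determinism and batch independence", {
  st <- vit_init(tiny_vit(), seed = 1)
  set.seed(2)
  x <- array(runif(32 * 32 * 3 * 4, -1, 1), dim = c(32, 32, 3, 4))
  f <- backbone_forward(st, x)
  expect_equal(dim(f), c(4, 5))
  expect_identical(f, backbone_forward(st, x))
  # batched result equals per-item results
  f1 <- backbone_forward(st, x[, , , 1, drop = FALSE])
  f3 <- backbone_forward(st, x[, , , 3, drop = FALSE])
  expect_equal(f[1, ], f1[1, ], tolerance = 1e-5)
  expect_equal(f[3, ], f3[1, ], tolerance = 1e-5)
  expect_error(backbone_forward(st, array(0, dim = c(16, 16, 3, 1))),
               class = "fundusvit_bad_image")
})

test_that("feature alignment is an exact elementwise sum", {
  a <- c(1, 2, 3, 4, 5); b <- c(5, 4, 3, 2, 1)
  expect_identical(align_features(a, b), rep(6, 5))
  expect_identical(align_features(a, numeric(5)), a)
  expect_identical(align_features(a, b), align_features(b, a))
  expect_error(align_features(a, 1:3), class = "fundusvit_bad_params")
})

test_that("class weights follow the inverse-frequency formula", {
  expect_equal(class_weights_from_counts(rep(10, 5)), rep(1, 5))
  w <- class_weights_from_counts(c(glaucoma = 100, normal = 100,
                                   `POAG/NTG` = 100, referable = 100,
                                   suspect = 600))
  expect_equal(w, c(2, 2, 2, 2, 1 / 3))
  # sum_j w_j n_j = N identity for arbitrary counts
  set.seed(4)
  for (k in 1:10) {
    n <- sample(1:500, 5)
    expect_equal(sum(class_weights_from_counts(n) * n), sum(n))
  }
  expect_error(class_weights_from_counts(c(0, 1, 1, 1, 1)),
               class = "fundusvit_bad_params")
})

test_that("weighted cross-entropy matches its transcription oracle", {
  # single sample, certain: zero
  p1 <- matrix(c(1, 0, 0, 0, 0), 1)
  expect_equal(suppressWarnings(weighted_cross_entropy(p1, 0L)), 0)
  # w = 2, p = 0.5 gives 2 ln 2
  p2 <- matrix(c(0.5, 0.5, 0, 0, 0), 1)
  expect_equal(weighted_cross_entropy(p2, 0L, c(2, 1, 1, 1, 1)), 2 * log(2))
  # unit weights equal the unweighted cross-entropy; random batches match
  # a naive double loop
  set.seed(6)
  for (k in 1:5) {
    p <- matrix(stats::runif(8 * 5, 0.01, 1), 8, 5)
    p <- p / rowSums(p)
    y <- sample(0:4, 8, TRUE)
    w <- runif(5, 0.5, 3)
    naive <- 0
    for (i in 1:8) for (j in 0:4) {
      if (y[i] == j) naive <- naive + w[j + 1] * (-log(p[i, j + 1]))
    }
    naive <- naive / 8
    expect_equal(weighted_cross_entropy(p, y, w), naive, tolerance = 1e-9)
    expect_equal(weighted_cross_entropy(p, y, rep(1, 5)),
                 mean(-log(p[cbind(1:8, y + 1)])), tolerance = 1e-9)
  }
  expect_warning(weighted_cross_entropy(matrix(c(0, 1, 0, 0, 0), 1), 0L),
                 "clamped")
})

test_that("training learns separable phantoms and is seed-reproducible", {
  set <- phantom_set(c("normal", "glaucoma"), 12, size = 32, radius = 8,
                     seed = 3)
  ctr <- prepare_contours(set$manifest, images = set$images)
  cfg <- tiny_vit(lr = 3e-3)
  st1 <- train_classifier(set$manifest, ctr, cfg, epochs = 8, seed = 9,
                          batch_size = 12, images = set$images)
  expect_equal(nrow(st1$history), 8)
  expect_gt(st1$history$train_acc[8], 0.5)         # above 2-class chance
  st2 <- train_classifier(set$manifest, ctr, cfg, epochs = 8, seed = 9,
                          batch_size = 12, images = set$images)
  expect_identical(st1$history, st2$history)       # bitwise loss history
  # missing contours are a hard error
  expect_error(train_classifier(set$manifest, ctr[-1], cfg, epochs = 1,
                                seed = 1, images = set$images),
               class = "fundusvit_missing_contour")
})

test_that("prediction is image-only, normalised, and ties break low", {
  st <- vit_init(tiny_vit(), seed = 2)
  img <- render_phantom(phantom_spec(image_size = 32, disc_radius = 8,
                                     seed = 1), "normal")
  n0 <- contour_call_count()
  pred <- suppressWarnings(predict(st, img))
  expect_equal(contour_call_count(), n0)           # no contour work at inference
  probs <- as.matrix(pred[, glaucoma_classes()$name])
  expect_equal(rowSums(probs), 1, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(pred$code, unname(which.max(probs[1, ])) - 1L)
  expect_warning(predict(st, img), "untrained")
})

test_that("attention maps are normalised and counted per head", {
  st <- vit_init(tiny_vit(), seed = 3)
  img <- render_phantom(phantom_spec(image_size = 32, disc_radius = 8,
                                     seed = 2), "suspect")
  at <- export_attention_maps(st, img)
  expect_equal(dim(at), c(32, 32, 2))              # n_heads maps at input size
  # each head's map summed over the 4x4 grid is one: on the upsampled grid
  # every grid cell is replicated 8x8 times
  for (h in 1:2) expect_equal(sum(at[, , h]) / 64, 1, tolerance = 1e-6)
})

test_that("exported features are constant-dimensional and input-determined", {
  st <- vit_init(tiny_vit(), seed = 4)
  imgs <- two_class_phantoms(4, size = 32)
  fx <- export_features(st, imgs)
  expect_equal(dim(fx), c(4L, 16L))
  fx2 <- export_features(st, imgs[c(1, 1)])
  expect_equal(unlist(fx2[1, ]), unlist(fx2[2, ]))  # identical inputs
})

test_that("the contour branch's effect on validation accuracy is reported", {
  # reduced-scale report (not an assertion): train the same tiny model with
  # and without the contour branch and print the mean validation accuracy
  accs <- matrix(NA_real_, 2, 2,
                 dimnames = list(c("with", "without"), c("s1", "s2")))
  set <- phantom_set(c("normal", "glaucoma"), 30, size = 32, radius = 8,
                     seed = 13, split = NA_character_)
  man <- split_dataset(set$manifest, seed = 14)
  ctr <- prepare_contours(dplyr::filter(man, split == "train"),
                          images = set$images)
  blank <- lapply(ctr, function(cm) {
    cm$edges[] <- 0L
    cm
  })
  va <- dplyr::filter(man, split == "val")
  va_arr <- fundusvit:::images_to_array(set$images[va$id])
  va_codes <- label_code(va$class)
  for (s in 1:2) {
    for (arm in c("with", "without")) {
      stx <- train_classifier(man, if (arm == "with") ctr else blank,
                              tiny_vit(lr = 3e-3), epochs = 4, seed = s,
                              batch_size = 21, images = set$images)
      accs[arm, s] <- mean(fundusvit:::predict_batch(stx, va_arr) == va_codes)
    }
  }
  message(sprintf("validation accuracy with contours %.3f, without %.3f (reported)",
                  mean(accs["with", ]), mean(accs["without", ])))
  expect_true(all(is.finite(accs)))
})
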