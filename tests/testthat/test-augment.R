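mini_policy <- function(seed = 1) {
  augmentation_policy(targets = c(normal = 0), seed = seed)
}

test_that("flips and transposition are exact involutions; rotate 0 is identity", {
  img <- render_phantom(phantom_spec(image_size = 32, disc_radius = 8,
                                     seed = 2), "normal")
  pol <- mini_policy()
  for (op in c("flip_h", "flip_v", "transpose")) {
    once <- augment_image(img, op, pol)
    twice <- augment_image(once, op, pol)
    expect_identical(twice$pixels, img$pixels)
    expect_identical(once$label, img$label)
    expect_identical(once$source, "augmented")
  }
  pol0 <- augmentation_policy(targets = c(normal = 0), seed = 1,
                              rotate_angles = 0, small_angle_range = c(0, 0))
  expect_identical(augment_image(img, "rotate", pol0)$pixels, img$pixels)
  expect_error(augment_image(img, "swirl", pol), class = "fundusvit_bad_params")
})

test_that("brightness shifts act pointwise and clip to 8 bits", {
  px <- array(100L, dim = c(8, 8, 3))
  img <- structure(list(pixels = px, label = "normal", source = "original",
                        id = "c"), class = "labeled_image")
  pol <- augmentation_policy(targets = c(normal = 0),
                             brightness_range = c(20, 20))  # deterministic +20
  out <- augment_image(img, "brightness", pol)
  expect_true(all(out$pixels == 120L))
  px2 <- array(250L, dim = c(8, 8, 3))
  img2 <- structure(list(pixels = px2, label = "normal", source = "original",
                         id = "c"), class = "labeled_image")
  expect_true(all(augment_image(img2, "brightness", pol)$pixels == 255L))
})

test_that("every op keeps dimensions, label and 8-bit range", {
  img <- render_phantom(phantom_spec(image_size = 32, disc_radius = 8,
                                     seed = 5), "suspect")
  pol <- augmentation_policy(targets = c(suspect = 0))
  set.seed(3)
  for (op in c("transpose", "flip_h", "flip_v", "rotate", "brightness",
               "blur", "distortion", "contrast", "clahe")) {
    out <- augment_image(img, op, pol)
    expect_identical(dim(out$pixels), dim(img$pixels))
    expect_identical(out$label, "suspect")
    expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  }
})

test_that("augmentation budgeting reaches per-class totals deterministically", {
  set <- phantom_set(c("normal", "glaucoma"), 4, size = 32, seed = 2)
  pol <- augmentation_policy(targets = c(normal = 9, glaucoma = 4), seed = 7)
  m1 <- run_augmentation(set$manifest, pol)
  # targets are totals: normal grows by 5 new records, glaucoma by none
  expect_equal(sum(m1$class == "normal" & m1$source == "augmented"), 5)
  expect_equal(sum(m1$class == "glaucoma" & m1$source == "augmented"), 0)
  expect_true(all(m1$split[m1$source == "augmented"] == "train"))
  # label preservation through the source link
  aug <- dplyr::filter(m1, source == "augmented")
  src_class <- set$manifest$class[match(aug$src_id, set$manifest$id)]
  expect_identical(aug$class, src_class)
  # determinism under the policy seed
  m2 <- run_augmentation(set$manifest, pol)
  expect_identical(m1, m2)
  # below-original targets and empty classes are errors
  expect_error(run_augmentation(set$manifest,
                                augmentation_policy(c(normal = 2))),
               class = "fundusvit_bad_params")
  expect_error(run_augmentation(set$manifest,
                                augmentation_policy(c(suspect = 3))),
               class = "fundusvit_bad_params")
})

test_that("materialised augmentation writes readable files", {
  d <- withr::local_tempdir()
  man <- generate_dataset(c(normal = 2), phantom_spec(image_size = 32,
                                                      disc_radius = 8),
                          seed = 1, dir = d)
  pol <- augmentation_policy(targets = c(normal = 4), seed = 3)
  m2 <- run_augmentation(man, pol, materialize = TRUE, dir = d)
  aug <- dplyr::filter(m2, source == "augmented")
  expect_equal(nrow(aug), 2)
  expect_true(all(file.exists(aug$path)))
  im <- read_labeled_image(aug$path[1])
  expect_identical(dim(im$pixels), c(32L, 32L, 3L))
})
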