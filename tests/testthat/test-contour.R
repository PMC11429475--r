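gray_of <- function(seed, n = 16) {
  set.seed(seed)
  matrix(runif(n * n, 0, 255), n, n)
}

test_that("grayscale conversion uses the declared luma weights", {
  px <- array(0L, dim = c(2, 2, 3))
  px[, , 1] <- 255; px[, , 2] <- 255; px[, , 3] <- 255
  expect_equal(to_grayscale(px), matrix(255, 2, 2))
  expect_equal(to_grayscale(array(0L, dim = c(2, 2, 3))), matrix(0, 2, 2))
  px[] <- 100L
  expect_equal(to_grayscale(px), matrix(100, 2, 2))
  expect_error(to_grayscale(array(0, dim = c(2, 2, 2))),
               class = "fundusvit_bad_image")
})

test_that("gaussian blur is normalised, impulse-reproducing and reflective", {
  p <- contour_params(gaussian_kernel = 5)
  const <- matrix(7, 9, 9)
  expect_lt(max(abs(gaussian_blur(const, p) - 7)), 1e-9)
  # unit impulse reproduces the kernel in the interior
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  out <- gaussian_blur(imp, p)
  kern <- fundusvit:::gaussian_kernel_matrix(5, p$gaussian_sigma)
  expect_equal(out[4:8, 4:8], kern)
  expect_equal(sum(out), 1)            # weights sum to one
  expect_error(contour_params(gaussian_kernel = 4), class = "fundusvit_bad_params")
})

test_that("sobel gradients satisfy the magnitude/direction identities", {
  # analytic 3-4-5 check through the raw fields
  gf <- sobel_gradients(gray_of(1))
  expect_lt(max(abs(gf$magnitude - sqrt(gf$gx^2 + gf$gy^2))), 1e-9)
  expect_true(all(gf$direction >= 0 & gf$direction < 180))
  expect_equal(sqrt(3^2 + 4^2), 5)
  expect_equal(atan2(1, 1) * 180 / pi, 45)
  # vertical step edge: interior step columns have horizontal gradient (0 deg)
  step <- cbind(matrix(0, 8, 4), matrix(100, 8, 4))
  gfs <- sobel_gradients(step)
  expect_true(all(gfs$direction[3:6, 4:5] == 0))
  expect_true(all(gfs$gy[3:6, 4:5] == 0))
  expect_error(sobel_gradients(matrix(0, 2, 2)), class = "fundusvit_bad_image")
})

test_that("non-maximum suppression equals the per-pixel reference on random fields", {
  for (seed in 1:6) {
    g <- gray_of(seed)
    gf <- sobel_gradients(gaussian_blur(g, contour_params()))
    got <- non_maximum_suppression(gf)
    # exhaustive per-pixel oracle
    H <- nrow(g); W <- ncol(g)
    want <- matrix(0, H, W)
    nbr <- function(i, j) if (i < 1 || i > H || j < 1 || j > W) 0 else gf$magnitude[i, j]
    for (i in seq_len(H)) for (j in seq_len(W)) {
      a <- gf$direction[i, j]
      ns <- if (a < 22.5 || a >= 157.5) c(nbr(i, j - 1), nbr(i, j + 1))
      else if (a < 67.5) c(nbr(i - 1, j - 1), nbr(i + 1, j + 1))
      else if (a < 112.5) c(nbr(i - 1, j), nbr(i + 1, j))
      else c(nbr(i - 1, j + 1), nbr(i + 1, j - 1))
      if (gf$magnitude[i, j] >= ns[1] && gf$magnitude[i, j] >= ns[2]) {
        want[i, j] <- gf$magnitude[i, j]
      }
    }
    expect_identical(got, want)
  }
  zero <- list(magnitude = matrix(0, 4, 4), direction = matrix(0, 4, 4))
  expect_identical(non_maximum_suppression(zero), matrix(0, 4, 4))
})

test_that("double thresholding partitions as counted by brute force", {
  set.seed(9)
  nms <- matrix(runif(64, 0, 10), 8, 8)
  p <- contour_params(low_threshold = 0.2, high_threshold = 0.5)
  th <- double_threshold(nms, p)
  mx <- max(nms)
  expect_identical(sum(th$strong), sum(nms >= 0.5 * mx))
  expect_identical(sum(th$weak), sum(nms >= 0.2 * mx & nms < 0.5 * mx))
  expect_false(any(th$strong & th$weak))
  # boundary: pixel exactly at high*max is strong (inclusive convention)
  nms2 <- matrix(c(10, 5, 1, 0), 2, 2)
  th2 <- double_threshold(nms2, p)
  expect_true(th2$strong[1, 1])
  expect_true(th2$strong[2, 1])        # 5 == 0.5 * 10 exactly
  # everything below low discards both maps
  th3 <- double_threshold(matrix(0, 3, 3), p)
  expect_equal(sum(th3$strong) + sum(th3$weak), 0)
  expect_error(contour_params(low_threshold = 0.5, high_threshold = 0.2),
               class = "fundusvit_bad_params")
})

test_that("hysteresis keeps weak pixels only when 8-connected to strong", {
  s <- matrix(FALSE, 5, 7); w <- matrix(FALSE, 5, 7)
  w[3, 2] <- TRUE                               # isolated weak: dropped
  out <- hysteresis_tracking(s, w)
  expect_equal(sum(out), 0)
  s[1, 1] <- TRUE; w2 <- matrix(FALSE, 5, 7); w2[2, 2] <- TRUE  # diagonal
  expect_equal(sum(hysteresis_tracking(s, w2)), 2)
  # chain of five weak pixels ending at a strong pixel: all kept
  s3 <- matrix(FALSE, 3, 8); w3 <- matrix(FALSE, 3, 8)
  s3[2, 1] <- TRUE
  for (j in 2:6) w3[2, j] <- TRUE
  out3 <- hysteresis_tracking(s3, w3)
  expect_equal(sum(out3), 6)
  expect_true(all(out3[2, 1:6] == 1L))
  expect_error(hysteresis_tracking(w3, w3), class = "fundusvit_bad_params")
})

test_that("contours of uniform images are empty and dimensions are kept", {
  cm <- extract_contour(matrix(5, 20, 24))
  expect_equal(dim(cm$edges), c(20, 24))
  expect_equal(sum(cm$edges), 0)
})

test_that("rotating the image rotates the contour", {
  img <- render_phantom(noiseless_spec(48, 12, 0.5, seed = 2), "referable")
  g <- to_grayscale(img)
  r <- t(g[nrow(g):1, ])               # exact 90-degree rotation
  c1 <- extract_contour(g)$edges
  c2 <- extract_contour(r)$edges
  expect_identical(c2, t(c1[nrow(c1):1, ]))
})

test_that("raising the low threshold never adds edge pixels", {
  img <- render_phantom(phantom_spec(image_size = 32, disc_radius = 8,
                                     seed = 4), "normal")
  lows <- c(0.05, 0.1, 0.2)
  ons <- vapply(lows, function(lo) {
    sum(extract_contour(img, contour_params(low_threshold = lo))$edges)
  }, numeric(1))
  expect_true(all(diff(ons) <= 0))
})

test_that("circular Hough transform localises the disc and scores contrast", {
  sp <- phantom_spec(image_size = 64, disc_center = c(32, 32),
                     disc_radius = 15, cup_to_disc_ratio = 0.5,
                     n_vessels = 0, noise_sigma = 0, illumination_slope = 0,
                     seed = 1, disc_intensity = 200, cup_intensity = 200)
  d <- locate_optic_disc(render_phantom(sp, "normal"), c(8, 25))
  expect_lte(max(abs(d$center - c(32, 32))), 2)
  expect_lte(abs(d$radius - 15), 2)
  expect_error(locate_optic_disc(matrix(0, 32, 32), c(4, 10)),
               class = "fundusvit_no_disc")
  # of two discs the one with stronger rim contrast wins
  g <- matrix(40, 64, 64)
  d2 <- (row(g) - 18)^2 + (col(g) - 18)^2
  g[d2 <= 81] <- 240                                # strong disc r = 9
  d3 <- (row(g) - 46)^2 + (col(g) - 46)^2
  g[d3 <= 81] <- 80                                 # faint disc r = 9
  loc <- locate_optic_disc(g, c(6, 12))
  expect_lte(max(abs(loc$center - c(18, 18))), 2)
})

test_that("cup segmentation recovers the cup-to-disc ratio", {
  img <- render_phantom(noiseless_spec(64, 20, 0.7), "glaucoma")
  geo <- estimate_disc_geometry(img)
  expect_lte(abs(geo$disc$radius - 20), 2)
  expect_lte(abs(geo$cdr - 0.7), 0.1)
  # containment: cup never leaves the disc
  cup <- locate_optic_cup(to_grayscale(img), geo$disc)
  d2 <- (row(cup$cup_mask) - geo$disc$center[1])^2 +
    (col(cup$cup_mask) - geo$disc$center[2])^2
  expect_equal(sum(cup$cup_mask & d2 > geo$disc$radius^2), 0)
  # degenerate uniform interior: empty cup, ratio zero (documented)
  flat <- matrix(120, 64, 64)
  dl <- structure(list(center = c(32, 32), radius = 10,
                       accumulator_score = 1), class = "disc_location")
  expect_equal(locate_optic_cup(flat, dl)$cdr, 0)
  expect_error(locate_optic_cup(flat, structure(list(center = c(32, 32),
                                                     radius = 2),
                                                class = "disc_location")),
               class = "fundusvit_bad_params")
})

test_that("the vectorised chain is bit-identical to the naive reference", {
  # spot checks here; the 100-image sweep runs in the acceptance suite
  for (seed in 1:5) {
    set.seed(seed)
    px <- array(as.integer(sample(0:255, 16 * 16 * 3, TRUE)), dim = c(16, 16, 3))
    img <- structure(list(pixels = px, label = "normal", source = "original",
                          id = "x"), class = "labeled_image")
    expect_identical(extract_contour(img)$edges, ref_canny(px))
  }
})
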