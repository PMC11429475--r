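# Classical augmentation: transposition, flips, rotation, brightness,
# blurring, elastic distortion, contrast enhancement and CLAHE, plus
# per-class budgeting that grows each class to an explicit target count.

.augment_ops <- c("transpose", "flip_h", "flip_v", "rotate", "brightness",
                  "blur", "distortion", "contrast", "clahe")

#' Augmentation policy
#'
#' Per-class target counts are totals after augmentation (originals plus new
#' augmented images), so a target equal to the original count adds nothing.
#' Non-uniform per-class targets reproduce severe-imbalance rebalancing
#' ledgers exactly.
#'
#' @param targets Named vector: per-class total count after augmentation.
#' @param ops Enabled operations, a subset of
#'   transpose, flip_h, flip_v, rotate, brightness, blur, distortion,
#'   contrast, clahe.
#' @param seed Seed controlling source-image and operation sampling.
#' @param rotate_angles Angles sampled for `rotate` (degrees); right angles
#'   keep the disc in frame exactly, the small-angle range is applied on top.
#' @param brightness_range,contrast_range,small_angle_range,elastic_alpha,elastic_sigma
#'   Operation parameter ranges/settings.
#' @export
augmentation_policy <- function(targets, ops = .augment_ops, seed = 1L,
                                rotate_angles = c(90, 180, 270),
                                small_angle_range = c(-10, 10),
                                brightness_range = c(-25, 25),
                                contrast_range = c(0.8, 1.25),
                                elastic_alpha = 4, elastic_sigma = 3) {
  stopifnot(all(targets >= 0))
  bad <- setdiff(ops, .augment_ops)
  if (length(bad)) rlang::abort(paste("unknown ops:", paste(bad, collapse = ", ")),
                                class = "fundusvit_bad_params")
  structure(list(targets = targets, ops = ops, seed = as.integer(seed),
                 rotate_angles = rotate_angles,
                 small_angle_range = small_angle_range,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma),
            class = "augmentation_policy")
}

# bilinear resampling of one channel at fractional source coordinates
.bilinear <- function(ch, sr, sc) {
  H <- nrow(ch); W <- ncol(ch)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  cl <- function(r, c) {
    r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
    ch[cbind(r, c)]
  }
  (1 - fr) * (1 - fc) * cl(r0, c0) + (1 - fr) * fc * cl(r0, c0 + 1) +
    fr * (1 - fc) * cl(r0 + 1, c0) + fr * fc * cl(r0 + 1, c0 + 1)
}

.warp_image <- function(px, sr, sc) {
  out <- array(0, dim = dim(px))
  for (ch in 1:3) {
    out[, , ch] <- matrix(.bilinear(px[, , ch], as.vector(sr), as.vector(sc)),
                          nrow(px), ncol(px))
  }
  out
}

#' Apply one augmentation operation to an image
#'
#' Output keeps the input's dimensions and class label and is tagged
#' `source = "augmented"`; intensities are clipped to [0, 255]. Flips and
#' transposition are involutions; `rotate` by 0 or a multiple of 90 degrees
#' is exact (index permutation), other angles use bilinear resampling.
#' Stochastic parameters (angles, brightness deltas, displacement fields)
#' are drawn from the current RNG stream.
#'
#' @param image A `labeled_image`.
#' @param op_name Operation name.
#' @param policy An [augmentation_policy()] supplying parameter ranges.
#' @return The augmented `labeled_image`.
#' @export
augment_image <- function(image, op_name, policy = augmentation_policy(c())) {
  if (!op_name %in% .augment_ops) {
    rlang::abort(paste("unknown augmentation op:", op_name),
                 class = "fundusvit_bad_params")
  }
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  out <- switch(
    op_name,
    transpose = aperm(px, c(2, 1, 3)),
    flip_h = px[, W:1, , drop = FALSE],
    flip_v = px[H:1, , , drop = FALSE],
    rotate = {
      base <- sample(c(0, policy$rotate_angles), 1)
      small <- stats::runif(1, policy$small_angle_range[1], policy$small_angle_range[2])
      .rotate_pixels(px, base, small)
    },
    brightness = px + stats::runif(1, policy$brightness_range[1],
                                   policy$brightness_range[2]),
    blur = {
      p <- contour_params(gaussian_kernel = 3L, gaussian_sigma = 0.8)
      o <- px
      for (ch in 1:3) o[, , ch] <- gaussian_blur(px[, , ch], p)
      o
    },
    distortion = {
      # elastic: Gaussian-smoothed random displacement field, amplitude alpha
      p <- contour_params(gaussian_kernel = 2L * ceiling(2 * policy$elastic_sigma) + 1L,
                          gaussian_sigma = policy$elastic_sigma)
      dr <- gaussian_blur(matrix(stats::runif(H * W, -1, 1), H, W), p) * policy$elastic_alpha
      dc <- gaussian_blur(matrix(stats::runif(H * W, -1, 1), H, W), p) * policy$elastic_alpha
      sr <- row(dr) + dr; sc <- col(dc) + dc
      .warp_image(px, sr, sc)
    },
    contrast = {
      f <- stats::runif(1, policy$contrast_range[1], policy$contrast_range[2])
      m <- mean(px)
      (px - m) * f + m
    },
    clahe = .clahe_pixels(px)
  )
  out <- array(as.integer(pmin(pmax(round(out), 0), 255)), dim = dim(px))
  structure(list(pixels = out, label = image$label, source = "augmented",
                 id = paste0(image$id, "_", op_name)),
            class = "labeled_image")
}

.rotate_pixels <- function(px, base, small) {
  rot90 <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  k <- (base / 90) %% 4
  for (i in seq_len(k)) px <- rot90(px)
  if (abs(small) < 1e-9) return(px)
  H <- nrow(px); W <- ncol(px)
  th <- small * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- row(px[, , 1]) - cy; cc <- col(px[, , 1]) - cx
  sr <- cy + cos(th) * rr - sin(th) * cc
  sc <- cx + sin(th) * rr + cos(th) * cc
  .warp_image(px, sr, sc)
}

# contrast-limited adaptive histogram equalisation (EBImage when available,
# otherwise a global histogram equalisation fallback)
.clahe_pixels <- function(px) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    a <- px / 255
    # EBImage uses (x, y) order
    img <- EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
    nx <- max(2L, min(8L, floor(dim(px)[2] / 8)))
    ny <- max(2L, min(8L, floor(dim(px)[1] / 8)))
    eq <- EBImage::clahe(img, nx = nx, ny = ny, limit = 2)
    out <- aperm(eq@.Data, c(2, 1, 3)) * 255
    return(out)
  }
  g <- px[, , 1]
  r <- rank(g, ties.method = "max") / length(g)
  eq <- matrix(r * 255, nrow(g), ncol(g))
  array(rep(eq, 3), dim = dim(px))
}

#' Grow each class to its augmentation target
#'
#' Samples source images and enabled operations with replacement until each
#' class's total (original + augmented) count equals the policy target, in
#' deterministic order under the policy seed. New records keep their source
#' record's class and are tagged `source = "augmented"`, `split = "train"`.
#'
#' @param manifest Manifest tibble (id, path, class, source, split).
#' @param policy An [augmentation_policy()].
#' @param materialize Write augmented PNG files next to their sources; if
#'   FALSE only the manifest rows are created (ledger dry-run).
#' @param dir Output directory when materialising (defaults to the source
#'   image directory).
#' @return The manifest with augmented rows appended.
#' @export
run_augmentation <- function(manifest, policy, materialize = FALSE, dir = NULL) {
  out <- list(manifest)
  for (cls in names(policy$targets)) {
    tgt <- policy$targets[[cls]]
    src <- dplyr::filter(manifest, .data$class == cls, .data$source == "original")
    n_new <- tgt - nrow(src)
    if (n_new < 0) {
      rlang::abort(paste0("augmentation target for ", cls,
                          " is below the original count"),
                   class = "fundusvit_bad_params")
    }
    if (n_new == 0) next
    if (nrow(src) == 0) {
      rlang::abort(paste0("class ", cls, " has a positive target but no originals"),
                   class = "fundusvit_bad_params")
    }
    rows <- with_seed(derive_seed(policy$seed, label_code(cls), 1L), {
      pick <- sample.int(nrow(src), n_new, replace = TRUE)
      opk <- sample(policy$ops, n_new, replace = TRUE)
      aug <- tibble::tibble(
        id = sprintf("%s_aug_%05d", gsub("/", "-", cls), seq_len(n_new)),
        path = NA_character_,
        class = cls, source = "augmented", split = "train",
        src_id = src$id[pick], op = opk)
      if (materialize) {
        for (i in seq_len(n_new)) {
          srec <- src[pick[i], ]
          img <- read_labeled_image(srec$path, label = cls, id = srec$id)
          a <- augment_image(img, opk[i], policy)
          a$id <- aug$id[i]
          d <- if (is.null(dir)) dirname(srec$path) else dir
          if (!dir.exists(d)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
          p <- file.path(d, paste0(aug$id[i], ".png"))
          write_labeled_image(a, p)
          aug$path[i] <- p
        }
      }
      aug
    })
    out[[length(out) + 1L]] <- rows
  }
  dplyr::bind_rows(out)
}
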