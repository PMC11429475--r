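# Contour extraction for optic disc/cup structure: grayscale -> Gaussian
# smoothing -> Sobel gradients -> non-maximum suppression -> double
# thresholding -> hysteresis tracking, plus circular-Hough disc localisation
# and intensity-based cup segmentation.
#
# Numerical conventions (fixed so independent reimplementations agree
# bit-for-bit):
#   * borders are reflected with edge duplication (1-p maps to p, H+p to H+1-p)
#   * convolution sums accumulate kernel offsets in (dy outer, dx inner) order
#   * gradient direction is folded to [0, 180) degrees and quantised to the
#     four bins 0/45/90/135 with half-open [b-22.5, b+22.5) intervals
#   * non-maximum suppression keeps ties (>= both directional neighbours);
#     out-of-frame neighbours count as zero
#   * the high threshold is inclusive (pixel == high*max is strong)
#   * coordinates are (row, col), 1-based

.fv_counters <- new.env(parent = emptyenv())
.fv_counters$contour_calls <- 0L

#' Count of contour extractions performed this session
#'
#' Diagnostic counter incremented by every [extract_contour()] call; used to
#' verify that the inference path never touches the contour pipeline.
#' @param reset Reset the counter to zero.
#' @export
contour_call_count <- function(reset = FALSE) {
  n <- .fv_counters$contour_calls
  if (reset) .fv_counters$contour_calls <- 0L
  n
}

#' Contour-extraction parameters
#'
#' @param gaussian_kernel Odd kernel size (3, 5, 7, ...).
#' @param gaussian_sigma Gaussian standard deviation in pixels; the default
#'   follows the common kernel-size heuristic 0.3*((k-1)/2 - 1) + 0.8.
#' @param low_threshold,high_threshold Hysteresis thresholds as fractions of
#'   the maximum suppressed gradient magnitude, 0 < low < high.
#' @export
contour_params <- function(gaussian_kernel = 5L,
                           gaussian_sigma = 0.3 * ((gaussian_kernel - 1) / 2 - 1) + 0.8,
                           low_threshold = 0.10, high_threshold = 0.30) {
  k <- as.integer(gaussian_kernel)
  if (k < 3L || k %% 2L == 0L) {
    rlang::abort("gaussian_kernel must be an odd integer >= 3",
                 class = "fundusvit_bad_params")
  }
  if (!(low_threshold > 0 && low_threshold < high_threshold)) {
    rlang::abort("need 0 < low_threshold < high_threshold",
                 class = "fundusvit_bad_params")
  }
  if (gaussian_sigma <= 0) {
    rlang::abort("gaussian_sigma must be positive", class = "fundusvit_bad_params")
  }
  structure(list(gaussian_kernel = k, gaussian_sigma = gaussian_sigma,
                 low_threshold = low_threshold, high_threshold = high_threshold),
            class = "contour_params")
}

#' Convert an RGB image to grayscale
#'
#' Fixed luma weights 0.299/0.587/0.114.
#'
#' @param pixels An H x W x 3 array (or a `labeled_image`).
#' @return An H x W numeric matrix in [0, 255].
#' @export
to_grayscale <- function(pixels) {
  if (inherits(pixels, "labeled_image")) pixels <- pixels$pixels
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    rlang::abort("expected an H x W x 3 array", class = "fundusvit_bad_image")
  }
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# reflected (edge-duplicating) index map for positions 1-p .. n+p
.reflect_idx <- function(n, p) {
  i <- (1 - p):(n + p)
  i[i < 1] <- 1 - i[i < 1]
  i[i > n] <- 2 * n + 1 - i[i > n]
  i
}

# generic small-kernel convolution with reflective border; offsets accumulate
# in (dy outer, dx inner) order so per-pixel addition order is reproducible
conv2_reflect <- function(x, kern) {
  k <- nrow(kern); p <- (k - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- x[.reflect_idx(H, p), .reflect_idx(W, p)]
  out <- matrix(0, H, W)
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      w <- kern[dy, dx]
      if (w == 0) next
      out <- out + w * xp[dy:(dy + H - 1L), dx:(dx + W - 1L)]
    }
  }
  out
}

gaussian_kernel_matrix <- function(k, sigma) {
  c0 <- (k + 1) / 2
  g <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    g[i, j] <- exp(-((i - c0)^2 + (j - c0)^2) / (2 * sigma^2))
  }
  g / sum(g)
}

#' Gaussian smoothing
#'
#' Convolution with a normalised 2-D Gaussian kernel (weights sum to one),
#' reflective border handling.
#'
#' @param gray H x W numeric matrix.
#' @param params A [contour_params()].
#' @export
gaussian_blur <- function(gray, params = contour_params()) {
  stopifnot(inherits(params, "contour_params"))
  conv2_reflect(gray, gaussian_kernel_matrix(params$gaussian_kernel,
                                             params$gaussian_sigma))
}

.sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)           # d/dcol
.sobel_y <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)           # d/drow

#' Sobel gradients, magnitude and direction
#'
#' Horizontal and vertical first derivatives from the 3 x 3 Sobel kernels;
#' magnitude is sqrt(gx^2 + gy^2) and direction the full-quadrant inverse
#' tangent folded to [0, 180) degrees.
#'
#' @param smoothed H x W matrix (at least 3 x 3).
#' @return A `gradient_field` list with `gx`, `gy`, `magnitude`, `direction`.
#' @export
sobel_gradients <- function(smoothed) {
  if (nrow(smoothed) < 3L || ncol(smoothed) < 3L) {
    rlang::abort("image smaller than the Sobel kernel", class = "fundusvit_bad_image")
  }
  gx <- conv2_reflect(smoothed, .sobel_x)
  gy <- conv2_reflect(smoothed, .sobel_y)
  mag <- sqrt(gx^2 + gy^2)
  th <- atan2(gy, gx) * 180 / pi
  th[th < 0] <- th[th < 0] + 180
  th[th >= 180] <- th[th >= 180] - 180
  structure(list(gx = gx, gy = gy, magnitude = mag, direction = th),
            class = "gradient_field")
}

# neighbour offsets for the four direction bins (0, 45, 90, 135 degrees)
.nms_offsets <- list(`0` = rbind(c(0, -1), c(0, 1)),
                     `45` = rbind(c(-1, -1), c(1, 1)),
                     `90` = rbind(c(-1, 0), c(1, 0)),
                     `135` = rbind(c(-1, 1), c(1, -1)))

quantize_direction <- function(th) {
  b <- integer(length(th))
  b[th < 22.5 | th >= 157.5] <- 0L
  b[th >= 22.5 & th < 67.5] <- 1L
  b[th >= 67.5 & th < 112.5] <- 2L
  b[th >= 112.5 & th < 157.5] <- 3L
  b
}

#' Non-maximum suppression
#'
#' A pixel keeps its gradient magnitude iff it is >= both neighbours along
#' its quantised gradient direction; otherwise it is reset to zero.
#' Neighbours outside the frame count as zero.
#'
#' @param field A `gradient_field`.
#' @return H x W matrix of suppressed magnitudes.
#' @export
non_maximum_suppression <- function(field) {
  m <- field$magnitude
  H <- nrow(m); W <- ncol(m)
  bins <- matrix(quantize_direction(as.vector(field$direction)), H, W)
  mp <- matrix(0, H + 2, W + 2)
  mp[2:(H + 1), 2:(W + 1)] <- m
  keep <- matrix(TRUE, H, W)
  for (b in 0:3) {
    off <- .nms_offsets[[as.character(b * 45)]]
    n1 <- mp[(2 + off[1, 1]):(H + 1 + off[1, 1]), (2 + off[1, 2]):(W + 1 + off[1, 2])]
    n2 <- mp[(2 + off[2, 1]):(H + 1 + off[2, 1]), (2 + off[2, 2]):(W + 1 + off[2, 2])]
    sel <- bins == b
    keep[sel] <- m[sel] >= n1[sel] & m[sel] >= n2[sel]
  }
  out <- m
  out[!keep] <- 0
  out
}

#' Double thresholding
#'
#' Partitions suppressed magnitudes into strong (>= high * max, inclusive),
#' weak ([low * max, high * max)) and discarded pixels.
#'
#' @param nms Suppressed magnitude matrix.
#' @param params A [contour_params()].
#' @return List of disjoint logical matrices `strong` and `weak`.
#' @export
double_threshold <- function(nms, params = contour_params()) {
  stopifnot(inherits(params, "contour_params"))
  mx <- max(nms)
  # featureless images (max magnitude at rounding-noise level, in 8-bit
  # units) yield empty maps rather than thresholding noise
  if (mx <= 1e-9) {
    empty <- matrix(FALSE, nrow(nms), ncol(nms))
    return(list(strong = empty, weak = empty))
  }
  hi <- params$high_threshold * mx
  lo <- params$low_threshold * mx
  list(strong = nms >= hi, weak = nms >= lo & nms < hi)
}

#' Hysteresis edge tracking
#'
#' Keeps every strong pixel plus every weak pixel connected to a strong pixel
#' through a chain of 8-connected weak pixels (transitive closure).
#'
#' @param strong,weak Disjoint logical matrices.
#' @return Binary (0/1) matrix of tracked edges.
#' @export
hysteresis_tracking <- function(strong, weak) {
  if (any(strong & weak)) {
    rlang::abort("strong and weak maps must be disjoint", class = "fundusvit_bad_params")
  }
  H <- nrow(strong); W <- ncol(strong)
  cur <- strong
  repeat {
    cp <- matrix(FALSE, H + 2, W + 2)
    cp[2:(H + 1), 2:(W + 1)] <- cur
    dil <- matrix(FALSE, H, W)
    for (dy in -1:1) for (dx in -1:1) {
      dil <- dil | cp[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    }
    grow <- dil & weak & !cur
    if (!any(grow)) break
    cur <- cur | grow
  }
  mode(cur) <- "integer"
  cur
}

#' Full contour-extraction chain
#'
#' Grayscale conversion, Gaussian smoothing, Sobel gradients, non-maximum
#' suppression, double thresholding and hysteresis tracking, composed in that
#' order. Deterministic.
#'
#' @param image A `labeled_image`, an H x W x 3 array, or an H x W matrix
#'   (already grayscale).
#' @param params A [contour_params()].
#' @return A `contour_map`: list with binary `edges` (same spatial size as the
#'   input) and the `params` used.
#' @export
extract_contour <- function(image, params = contour_params()) {
  .fv_counters$contour_calls <- .fv_counters$contour_calls + 1L
  gray <- if (is.matrix(image)) image else to_grayscale(image)
  sm <- gaussian_blur(gray, params)
  gf <- sobel_gradients(sm)
  nm <- non_maximum_suppression(gf)
  th <- double_threshold(nm, params)
  edges <- hysteresis_tracking(th$strong, th$weak)
  structure(list(edges = edges, params = params), class = "contour_map")
}

#' Locate the optic disc with a circular Hough transform
#'
#' Votes each contour pixel onto candidate circle centres over the requested
#' radius range. When the source image is available, votes are weighted by
#' the local gradient magnitude so the high-contrast disc rim out-scores the
#' weaker interior cup rim; on a bare contour map all votes weigh one. The
#' accumulator score is the supported vote mass per sampled perimeter
#' position, comparable across radii. Ties are broken by the smallest
#' (row, col, radius).
#'
#' @param image Image or precomputed `contour_map`.
#' @param radius_range `c(rmin, rmax)` in pixels, both below half the image.
#' @param params Contour parameters used if `image` is not already a contour.
#' @return A `disc_location`: list with `center` (row, col), `radius` and
#'   `accumulator_score`.
#' @export
locate_optic_disc <- function(image, radius_range, params = contour_params()) {
  have_img <- !inherits(image, "contour_map")
  cm <- if (have_img) extract_contour(image, params) else image
  e <- cm$edges
  H <- nrow(e); W <- ncol(e)
  rmin <- as.integer(radius_range[1]); rmax <- as.integer(radius_range[2])
  if (!(rmin < rmax) || rmax >= min(H, W) / 2) {
    rlang::abort("invalid radius range", class = "fundusvit_bad_params")
  }
  pts <- which(e == 1L, arr.ind = TRUE)
  if (nrow(pts) == 0L) {
    rlang::abort("no edge pixels: no disc found", class = "fundusvit_no_disc")
  }
  wts <- rep(1, nrow(pts))
  if (have_img) {
    gray <- if (is.matrix(image)) image else to_grayscale(image)
    gf <- sobel_gradients(gaussian_blur(gray, params))
    mg <- gf$magnitude[pts]
    if (max(mg) > 0) wts <- mg / max(mg)
  }
  best <- NULL
  for (r in rmin:rmax) {
    n_ang <- max(24L, ceiling(2 * pi * r))
    ang <- (seq_len(n_ang) - 1) * 2 * pi / n_ang
    acc <- matrix(0, H, W)
    for (a in ang) {
      cy <- round(pts[, 1] - r * sin(a))
      cx <- round(pts[, 2] - r * cos(a))
      ok <- cy >= 1 & cy <= H & cx >= 1 & cx <= W
      if (!any(ok)) next
      ix <- cy[ok] + (cx[ok] - 1L) * H
      r2 <- rowsum(wts[ok], group = ix)
      ii <- as.integer(rownames(r2))
      acc[ii] <- acc[ii] + r2[, 1]
    }
    sc <- max(acc) / n_ang
    hit <- which(acc == max(acc), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    cand <- list(center = c(hit[[1]], hit[[2]]), radius = r, accumulator_score = sc)
    if (is.null(best) || sc > best$accumulator_score ||
        (sc == best$accumulator_score &&
         (cand$center[1] < best$center[1] ||
          (cand$center[1] == best$center[1] && cand$center[2] < best$center[2])))) {
      best <- cand
    }
  }
  class(best) <- "disc_location"
  best
}

#' Segment the optic cup inside a located disc
#'
#' The cup is the set of disc-interior pixels brighter than a percentile
#' position within the disc ROI's robust intensity range (1st to 99th pixel
#' quantiles). The vertical cup-to-disc ratio is approximated as
#' sqrt(cup area / disc area). A uniform-interior disc yields an empty cup
#' and ratio 0 (documented degenerate behaviour).
#'
#' @param image Image (or grayscale matrix).
#' @param disc A `disc_location`.
#' @param percentile Threshold position within the ROI intensity range,
#'   in (50, 100).
#' @return List with logical `cup_mask` (subset of the disc ROI) and `cdr`.
#' @export
locate_optic_cup <- function(image, disc, percentile = 70) {
  gray <- if (is.matrix(image)) image else to_grayscale(image)
  if (disc$radius < 3) {
    rlang::abort("degenerate disc (radius < 3 px)", class = "fundusvit_bad_params")
  }
  if (!(percentile > 50 && percentile < 100)) {
    rlang::abort("percentile must lie in (50, 100)", class = "fundusvit_bad_params")
  }
  d2 <- (row(gray) - disc$center[1])^2 + (col(gray) - disc$center[2])^2
  roi <- d2 <= disc$radius^2
  vals <- gray[roi]
  q <- stats::quantile(vals, c(0.01, 0.99), names = FALSE)
  thr <- q[1] + (percentile / 100) * (q[2] - q[1])
  cup <- roi & gray > thr
  cdr <- sqrt(sum(cup) / sum(roi))
  list(cup_mask = cup, cdr = cdr)
}

#' Estimate disc geometry and cup-to-disc ratio of an image
#'
#' Convenience wrapper: contour extraction, circular-Hough disc localisation
#' and cup segmentation in one call; used as the geometric probe when scoring
#' generated images.
#'
#' @inheritParams locate_optic_disc
#' @inheritParams locate_optic_cup
#' @return List with `disc` and `cdr`.
#' @export
estimate_disc_geometry <- function(image, radius_range = NULL,
                                   params = contour_params(), percentile = 70) {
  gray <- if (is.matrix(image)) image else to_grayscale(image)
  if (is.null(radius_range)) {
    n <- min(dim(gray))
    radius_range <- c(max(4L, round(n / 12)), floor(n / 2) - 1L)
  }
  disc <- locate_optic_disc(gray, radius_range, params)
  cup <- locate_optic_cup(gray, disc, percentile)
  list(disc = disc, cdr = cup$cdr)
}
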