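# Synthetic fundus phantoms: a bright elliptical optic disc containing a
# brighter optic cup (cup-to-disc ratio varies by class), curvilinear dark
# vessels, a linear illumination gradient and Gaussian sensor noise.
# Phantoms stand in for clinical fundus photographs so the full pipeline is
# testable without any external dataset.

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic per-image seed
#'
#' Hashes (master seed, class code, within-class index) into a per-image
#' seed below 2^31, so datasets are reproducible yet images distinct.
#' @param master Master seed.
#' @param code Class code (0-4).
#' @param index Within-class index.
#' @export
derive_seed <- function(master, code, index) {
  as.integer((master * 2654435 + code * 97003 + index * 101) %% 2147483647)
}

#' Specify a synthetic fundus phantom
#'
#' @param image_size Side length in pixels (square image).
#' @param disc_center `(row, col)` of the optic-disc centre in pixels
#'   (1-based); defaults to the image centre.
#' @param disc_radius Disc radius in pixels.
#' @param cup_to_disc_ratio Cup radius as a fraction of disc radius, in (0,1).
#' @param n_vessels Number of dark random-walk vessel polylines.
#' @param noise_sigma Gaussian sensor-noise standard deviation in 8-bit
#'   intensity units.
#' @param illumination_slope Linear illumination gradient, intensity units
#'   per pixel across columns.
#' @param seed Non-negative integer seed; identical spec + seed gives a
#'   bit-identical image.
#' @param background,disc_intensity,cup_intensity Base 8-bit intensities of
#'   the background, disc annulus and cup.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(image_size = 64L,
                         disc_center = NULL,
                         disc_radius = round(image_size / 4.5),
                         cup_to_disc_ratio = 0.3,
                         n_vessels = 3L,
                         noise_sigma = 5,
                         illumination_slope = 0.2,
                         seed = 0L,
                         background = 40,
                         disc_intensity = 150,
                         cup_intensity = 220) {
  if (is.null(disc_center)) {
    disc_center <- c(ceiling(image_size / 2), ceiling(image_size / 2))
  }
  spec <- list(image_size = as.integer(image_size), disc_center = disc_center,
               disc_radius = disc_radius, cup_to_disc_ratio = cup_to_disc_ratio,
               n_vessels = as.integer(n_vessels), noise_sigma = noise_sigma,
               illumination_slope = illumination_slope, seed = as.integer(seed),
               background = background, disc_intensity = disc_intensity,
               cup_intensity = cup_intensity)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  s <- spec
  if (s$image_size < 8) rlang::abort("image_size too small", class = "fundusvit_bad_spec")
  if (!(s$cup_to_disc_ratio > 0 && s$cup_to_disc_ratio < 1)) {
    rlang::abort("cup_to_disc_ratio must lie in (0,1)", class = "fundusvit_bad_spec")
  }
  if (s$noise_sigma < 0 || s$n_vessels < 0 || s$seed < 0) {
    rlang::abort("noise_sigma, n_vessels and seed must be non-negative",
                 class = "fundusvit_bad_spec")
  }
  r <- s$disc_radius
  if (any(s$disc_center - r < 1) || any(s$disc_center + r > s$image_size)) {
    rlang::abort("optic disc extends outside the image frame",
                 class = "fundusvit_bad_spec")
  }
  invisible(spec)
}

#' Render a labelled phantom fundus image
#'
#' The disc is a filled ellipse strictly brighter (in mean) than the
#' background and the concentric cup is strictly brighter than the disc
#' annulus, mirroring the relative brightness of the optic cup within the
#' disc on real photographs. Vessels are darker random-walk polylines.
#' Deterministic: identical spec and seed give bit-identical pixel grids.
#'
#' @param spec A [phantom_spec()]; its `cup_to_disc_ratio` controls the cup
#'   geometry (see [class_default_cdr()] for the per-class defaults).
#' @param label Class name attached to the image.
#' @param id Record identifier stored on the image.
#' @return A `labeled_image`: list with `pixels` (H x W x 3 integer array in
#'   [0,255]), `label`, `source = "original"` and `id`.
#' @export
render_phantom <- function(spec, label, id = "phantom") {
  validate_phantom_spec(spec)
  code <- label_code(label)
  n <- spec$image_size
  with_seed(spec$seed, {
    img <- matrix(spec$background, n, n)
    # illumination gradient across columns, centred so the frame mean is kept
    if (spec$illumination_slope != 0) {
      grad <- spec$illumination_slope * (col(img) - (n + 1) / 2)
      img <- img + grad
    }
    # vessels: darker random walks entering from a random border point
    if (spec$n_vessels > 0) {
      for (v in seq_len(spec$n_vessels)) {
        r0 <- sample.int(n, 1); c0 <- if (stats::runif(1) < 0.5) 1L else n
        dr <- stats::runif(1, -0.6, 0.6); dc <- if (c0 == 1L) 1 else -1
        pr <- r0; pc <- c0
        for (step in seq_len(2L * n)) {
          rr <- round(pr); cc <- round(pc)
          if (rr < 1 || rr > n || cc < 1 || cc > n) break
          img[rr, cc] <- 25
          if (rr + 1 <= n) img[rr + 1, cc] <- 25
          dr <- dr + stats::rnorm(1, 0, 0.15)
          dr <- max(min(dr, 1), -1)
          pr <- pr + dr; pc <- pc + dc
        }
      }
    }
    # optic disc and cup: concentric filled ellipses (circular by default)
    cy <- spec$disc_center[1]; cx <- spec$disc_center[2]
    d2 <- (row(img) - cy)^2 + (col(img) - cx)^2
    disc <- d2 <= spec$disc_radius^2
    cupr <- spec$cup_to_disc_ratio * spec$disc_radius
    cup <- d2 <= cupr^2
    img[disc] <- spec$disc_intensity
    img[cup] <- spec$cup_intensity
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
    }
    img <- pmin(pmax(round(img), 0), 255)
    img <- as.integer(img)
    px <- array(0L, dim = c(n, n, 3))
    px[, , 1] <- img; px[, , 2] <- img; px[, , 3] <- img
    structure(list(pixels = px, label = label, source = "original", id = id),
              class = "labeled_image")
  })
}

#' Generate a phantom dataset with per-class counts
#'
#' Builds a manifest (and optionally PNG files) with exactly the requested
#' number of phantoms per class. Per-image seeds are derived deterministically
#' from the master seed, the class code and the within-class index, so two
#' master seeds give disjoint image sets while a fixed master seed reproduces
#' the dataset bit-for-bit.
#'
#' @param class_counts Named integer vector, names from [glaucoma_classes()];
#'   absent classes default to zero.
#' @param spec_template A [phantom_spec()] whose geometry is reused for every
#'   image; the per-class default cup-to-disc ratio overrides the template's
#'   unless `keep_template_cdr` is TRUE.
#' @param seed Master seed.
#' @param dir Output directory for PNG files; created if needed.
#' @param write_images If FALSE, build the manifest only (dry-run ledger
#'   mode; `path` is the planned location).
#' @param keep_template_cdr Use the template's cup-to-disc ratio for all
#'   classes instead of the class defaults.
#' @param jitter Randomise disc centre/radius slightly per image (fraction of
#'   image size) for less rigid datasets.
#' @return A manifest tibble with columns `id`, `path`, `class`, `source`,
#'   `split` (NA at this stage), plus `seed` and `cdr` provenance columns.
#' @export
generate_dataset <- function(class_counts, spec_template = phantom_spec(),
                             seed = 1L, dir = tempfile("phantoms"),
                             write_images = TRUE, keep_template_cdr = FALSE,
                             jitter = 0.05) {
  stopifnot(all(class_counts >= 0))
  bad <- setdiff(names(class_counts), glaucoma_classes()$name)
  if (length(bad)) rlang::abort(paste("unknown classes:", paste(bad, collapse = ", ")),
                                class = "fundusvit_bad_label")
  if (write_images && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      rlang::abort(paste("cannot create output directory", dir),
                   class = "fundusvit_io_error")
    }
  }
  rows <- list()
  for (cls in names(class_counts)) {
    k <- class_counts[[cls]]
    if (k == 0) next
    code <- label_code(cls)
    cdr <- if (keep_template_cdr) spec_template$cup_to_disc_ratio else class_default_cdr(cls)
    for (i in seq_len(k)) {
      sd_i <- derive_seed(seed, code, i)
      id <- sprintf("%s_%05d", gsub("/", "-", cls), i)
      path <- file.path(dir, paste0(id, ".png"))
      if (write_images) {
        sp <- spec_template
        sp$cup_to_disc_ratio <- cdr
        sp$seed <- sd_i
        if (jitter > 0) {
          # geometric jitter drawn from the image seed, before rendering
          jv <- with_seed(sd_i + 1L, stats::runif(3, -1, 1))
          n <- sp$image_size
          off <- round(jv[1:2] * jitter * n)
          sp$disc_center <- sp$disc_center + off
          sp$disc_radius <- max(4, round(sp$disc_radius * (1 + jv[3] * jitter)))
          # keep the disc inside the frame
          sp$disc_center <- pmin(pmax(sp$disc_center, sp$disc_radius + 1),
                                 n - sp$disc_radius)
        }
        img <- render_phantom(sp, cls, id = id)
        write_labeled_image(img, path)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, path = path, class = cls, source = "original",
        split = NA_character_, seed = sd_i, cdr = cdr)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(id = character(), path = character(),
                          class = character(), source = character(),
                          split = character(), seed = integer(), cdr = double()))
  }
  dplyr::bind_rows(rows)
}

#' Read and write labelled images as PNG
#'
#' @param img A `labeled_image`.
#' @param path PNG file path.
#' @export
write_labeled_image <- function(img, path) {
  a <- aperm(array(img$pixels / 255, dim = dim(img$pixels)), c(1, 2, 3))
  png::writePNG(a, path)
  invisible(path)
}

#' @rdname write_labeled_image
#' @param label,source,id Metadata attached to the returned object.
#' @export
read_labeled_image <- function(path, label = NA_character_,
                               source = "original", id = basename(path)) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  px <- array(as.integer(round(a * 255)), dim = dim(a))
  structure(list(pixels = px, label = label, source = source, id = id),
            class = "labeled_image")
}
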