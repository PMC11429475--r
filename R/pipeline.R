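# Three-phase orchestration: data generation (classical augmentation +
# GAN sampling + contour extraction), training, and image-only inference,
# with manifest bookkeeping throughout.  Records are only ever added or
# annotated, never silently removed.

#' SMDG-19 per-source class inventory
#'
#' The published per-dataset class counts of the Standardized Multi-Channel
#' Dataset for Glaucoma (SMDG-19, 19 public fundus collections); the ledger
#' driving manifest bookkeeping. Column sums give 1598 glaucoma, 6732
#' normal, 40 POAG/NTG, 3270 referable and 25 suspect records - 11,665
#' images in total.
#'
#' @return Tibble with `dataset` and one column per class.
#' @export
smdg_source_counts <- function() {
  tibble::tribble(
    ~dataset, ~glaucoma, ~normal, ~`POAG/NTG`, ~referable, ~suspect,
    "CRFO-v4",     48,   31, 0,    0,  0,
    "BEH",        172,  462, 0,    0,  0,
    "DRISHTI-GS",  70,   31, 0,    0,  0,
    "EyePACS",      0,    0, 0, 3270,  0,
    "JSIEC",        0,   38, 0,    0, 11,
    "G1020",      296,  724, 0,    0,  0,
    "REFUGE",     400,  359, 40,   0,  0,
    "ODIA-ODIR",  346, 4302, 0,    0, 14,
    "sjchoi86",   101,  300, 0,    0,  0,
    "ORIGA",      165,  485, 0,    0,  0)
}

#' Generation-phase budgets per class
#'
#' The rebalancing ledger: per class, the training originals, the total of
#' the augmented pool (originals plus classically augmented copies), the
#' number of GAN-generated images, and their combined total. The combined
#' column sums to 24,127 training images; the GAN column sums to 4035.
#' Note the suspect originals (27) exceed the 25 suspect records in
#' [smdg_source_counts()]; both ledgers are kept as published.
#'
#' @return Tibble with columns `class`, `original_train`, `augmented_total`,
#'   `cvgan` and `combined`.
#' @export
generation_budgets <- function() {
  tibble::tribble(
    ~class, ~original_train, ~augmented_total, ~cvgan, ~combined,
    "glaucoma", 1598, 4794, 1000, 5794,
    "normal", 6732, 8530, 2000, 10530,
    "POAG/NTG", 40, 120, 20, 140,
    "suspect", 27, 108, 15, 123,
    "referable", 3270, 6540, 1000, 7540)
}

#' Pipeline configuration
#'
#' @param image_size Working resolution (desk-scale default 64; full scale
#'   512).
#' @param split_fractions Named fractions for train/val/test; must sum to 1.
#'   The default keeps 70% for training and splits the held-out 30% evenly.
#' @param budgets Generation budgets tibble (see [generation_budgets()]).
#' @param contour A [contour_params()].
#' @param backbone A [vit_config()].
#' @param cvgan A [cvgan_config()].
#' @param seed Master seed.
#' @param output_root Directory for phase outputs.
#' @param materialize Write image files during generation (FALSE = ledger
#'   dry-run).
#' @export
pipeline_config <- function(image_size = 64L,
                            split_fractions = c(train = 0.70, val = 0.15, test = 0.15),
                            budgets = generation_budgets(),
                            contour = contour_params(),
                            backbone = vit_config(image_size = image_size),
                            cvgan = cvgan_config(),
                            seed = 1L,
                            output_root = tempfile("fundusvit"),
                            materialize = FALSE) {
  if (abs(sum(split_fractions) - 1) > 1e-9 || any(split_fractions <= 0)) {
    rlang::abort("split fractions must be positive and sum to 1",
                 class = "fundusvit_bad_params")
  }
  structure(list(image_size = as.integer(image_size),
                 split_fractions = split_fractions, budgets = budgets,
                 contour = contour, backbone = backbone, cvgan = cvgan,
                 seed = as.integer(seed), output_root = output_root,
                 materialize = materialize),
            class = "pipeline_config")
}

#' Build a manifest from a per-source class inventory
#'
#' One record per image. When `image_root` is given, files are checked on
#' disk and missing paths are listed in the `missing` attribute (never
#' silently dropped).
#'
#' @param source_counts Tibble like [smdg_source_counts()].
#' @param image_root Optional directory of real images to validate against.
#' @return Manifest tibble (id, path, class, source, split, dataset).
#' @export
build_manifest <- function(source_counts = smdg_source_counts(),
                           image_root = NULL) {
  cls <- setdiff(names(source_counts), "dataset")
  rows <- list()
  for (i in seq_len(nrow(source_counts))) {
    for (cl in cls) {
      k <- source_counts[[cl]][i]
      if (is.na(k) || k == 0) next
      ds <- source_counts$dataset[i]
      ids <- sprintf("%s_%s_%05d", ds, gsub("/", "-", cl), seq_len(k))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = ids,
        path = if (is.null(image_root)) NA_character_ else
          file.path(image_root, paste0(ids, ".png")),
        class = cl, source = "original", split = NA_character_, dataset = ds)
    }
  }
  m <- dplyr::bind_rows(rows)
  if (!is.null(image_root)) {
    missing <- m$path[!file.exists(m$path)]
    if (length(missing)) {
      rlang::warn(paste(length(missing), "manifest files missing on disk"))
    }
    attr(m, "missing") <- missing
  }
  m
}

#' Stratified train/val/test split
#'
#' Splits the original records of each class with |train| = round(f_train*N)
#' (within one record), deterministically under the seed. Augmented and
#' generated records are train-only by construction and keep their split.
#' Classes with fewer than 3 records go entirely to train with a warning.
#'
#' @param manifest Manifest tibble.
#' @param fractions Named split fractions summing to 1.
#' @param seed Split seed.
#' @export
split_dataset <- function(manifest,
                          fractions = c(train = 0.70, val = 0.15, test = 0.15),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    rlang::abort("fractions must sum to 1", class = "fundusvit_bad_params")
  }
  orig <- manifest$source == "original"
  out <- manifest
  with_seed(seed, {
    for (cl in unique(manifest$class[orig])) {
      sel <- which(orig & manifest$class == cl)
      n <- length(sel)
      if (n < 3) {
        rlang::warn(paste0("class ", cl, " has fewer than 3 records; all assigned to train"))
        out$split[sel] <- "train"
        next
      }
      nt <- round(fractions[["train"]] * n)
      nv <- round(fractions[["val"]] * n)
      nv <- min(nv, n - nt)
      ord <- sample(sel)
      out$split[ord[seq_len(nt)]] <- "train"
      if (nv > 0) out$split[ord[nt + seq_len(nv)]] <- "val"
      if (nt + nv < n) out$split[ord[(nt + nv + 1L):n]] <- "test"
    }
  })
  out
}

#' Run the data-generation phase
#'
#' Applies classical augmentation up to each class's augmented-pool total
#' and GAN sampling for each class's generated budget, then (when
#' materialising) extracts one contour map per training record so images
#' and contours pair one-to-one. Budgets below the original count are a
#' configuration error. Per-class ledger totals are reported via message.
#'
#' @param config A [pipeline_config()].
#' @param manifest Manifest with a `split` column; train originals feed the
#'   budgets.
#' @param cvgan_state Optional trained `fv_cvgan` used for sampling when
#'   materialising.
#' @return List with the enlarged `manifest` and, when materialised,
#'   `contours` (named list) and generated images.
#' @export
run_generation_phase <- function(config, manifest, cvgan_state = NULL) {
  b <- config$budgets
  tr <- dplyr::filter(manifest, .data$split == "train", .data$source == "original")
  counts <- table(factor(tr$class, levels = glaucoma_classes()$name))
  for (i in seq_len(nrow(b))) {
    if (b$augmented_total[i] < sum(tr$class == b$class[i])) {
      rlang::abort(paste0("augmented budget for ", b$class[i],
                          " is below its original train count"),
                   class = "fundusvit_bad_params")
    }
  }
  targets <- stats::setNames(b$augmented_total, b$class)
  pol <- augmentation_policy(targets = targets, seed = config$seed)
  man2 <- run_augmentation(manifest, pol, materialize = config$materialize,
                           dir = if (config$materialize)
                             file.path(config$output_root, "augmented") else NULL)
  gen_counts <- stats::setNames(b$cvgan, b$class)
  gen_imgs <- NULL
  if (config$materialize) {
    if (is.null(cvgan_state)) {
      rlang::abort("materialising generation requires a trained cvgan_state",
                   class = "fundusvit_bad_params")
    }
    sres <- sample_synthetic(cvgan_state, gen_counts, seed = config$seed,
                             dir = file.path(config$output_root, "generated"),
                             write_images = TRUE)
    man2 <- dplyr::bind_rows(man2, sres$manifest)
    gen_imgs <- sres$images
  } else {
    rows <- purrr::map_dfr(names(gen_counts), function(cl) {
      k <- gen_counts[[cl]]
      if (k == 0) return(NULL)
      tibble::tibble(id = sprintf("%s_gen_%05d", gsub("/", "-", cl), seq_len(k)),
                     path = NA_character_, class = cl, source = "generated",
                     split = "train")
    })
    man2 <- dplyr::bind_rows(man2, rows)
  }
  tr2 <- dplyr::filter(man2, .data$split == "train")
  ledger <- dplyr::count(dplyr::filter(tr2, .data$source != "original"),
                         .data$class, .data$source)
  message("generation phase ledger (new records): ",
          paste(ledger$class, ledger$source, ledger$n, collapse = "; "))
  out <- list(manifest = man2, generated_images = gen_imgs)
  if (config$materialize) {
    newrec <- dplyr::filter(tr2, .data$source != "original")
    imgs <- NULL
    if (!is.null(gen_imgs)) {
      imgs <- gen_imgs
      names(imgs) <- vapply(gen_imgs, function(i) i$id, character(1))
    }
    out$contours <- prepare_contours(tr2, config$contour, images = imgs)
  }
  out
}

#' Run the training phase
#'
#' Delegates to [train_classifier()] on the (image, contour) pairs of the
#' training split, evaluates the validation split per epoch, and writes a
#' versioned checkpoint plus a history CSV under the output root.
#'
#' @param config A [pipeline_config()].
#' @param manifest Enlarged manifest from the generation phase.
#' @param contours Named list of contour maps for every training record.
#' @param images Optional in-memory image store.
#' @param epochs Training epochs.
#' @return List with `state`, `checkpoint` path and `history`.
#' @export
run_training_phase <- function(config, manifest, contours, images = NULL,
                               epochs = 10L) {
  state <- train_classifier(manifest, contours, config$backbone,
                            epochs = epochs, seed = config$seed,
                            images = images)
  dir.create(config$output_root, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(config$output_root, "classifier.rds")
  save_classifier(state, ckpt)
  utils::write.csv(state$history,
                   file.path(config$output_root, "history.csv"),
                   row.names = FALSE)
  list(state = state, checkpoint = ckpt, history = state$history)
}

#' Run the inference phase
#'
#' Image-only prediction: the contour pipeline is never invoked (verified
#' by the package's contour call counter). With truth labels available, the
#' full metric report is attached.
#'
#' @param config A [pipeline_config()].
#' @param state A trained `fv_cavit` (or checkpoint path).
#' @param images List of `labeled_image`s or (H,W,3,B) array.
#' @param truth Optional class labels for evaluation.
#' @return List with `predictions` tibble and optional `report`.
#' @export
run_inference_phase <- function(config, state, images, truth = NULL) {
  if (is.character(state)) state <- load_classifier(state)
  pred <- predict(state, images)
  out <- list(predictions = pred)
  if (!is.null(truth)) {
    cm <- confusion_matrix(truth, pred$code)
    out$report <- multiclass_report(cm)
  }
  out
}

#' Save and load classifier checkpoints
#'
#' Single-file, versioned (format v1): parameter values, optimizer moments,
#' config, class weights and history.
#'
#' @param state A `fv_cavit`.
#' @param path Checkpoint file.
#' @export
save_classifier <- function(state, path) {
  obj <- list(format = "fundusvit_cavit", version = 1L,
              params = state$params$val, m = state$params$m,
              v = state$params$v, t = state$params$t,
              config = state$config, epoch = state$epoch,
              class_weights = state$class_weights, history = state$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    rlang::abort(paste("unreadable checkpoint:", conditionMessage(e)),
                 class = "fundusvit_bad_checkpoint")
  })
  if (!identical(obj$format, "fundusvit_cavit") || is.null(obj$version)) {
    rlang::abort("not a fundusvit classifier checkpoint (missing format/version)",
                 class = "fundusvit_bad_checkpoint")
  }
  p <- new_params(obj$params)
  p$m <- obj$m; p$v <- obj$v; p$t <- obj$t
  structure(list(params = p, config = obj$config, epoch = obj$epoch,
                 class_weights = obj$class_weights, history = obj$history),
            class = "fv_cavit")
}

#' Save and load CVGAN checkpoints
#' @param state A `fv_cvgan`.
#' @param path Checkpoint file.
#' @export
save_cvgan <- function(state, path) {
  saveRDS(list(format = "fundusvit_cvgan", version = 1L,
               E = state$E$val, G = state$G$val, D = state$D$val,
               config = state$config, step = state$step,
               history = state$history), path)
  invisible(path)
}

#' @rdname save_cvgan
#' @export
load_cvgan <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    rlang::abort(paste("unreadable checkpoint:", conditionMessage(e)),
                 class = "fundusvit_bad_checkpoint")
  })
  if (!identical(obj$format, "fundusvit_cvgan")) {
    rlang::abort("not a fundusvit CVGAN checkpoint", class = "fundusvit_bad_checkpoint")
  }
  log <- new.env(parent = emptyenv())
  log$rows <- if (nrow(obj$history)) list(obj$history) else list()
  structure(list(E = new_params(obj$E), G = new_params(obj$G),
                 D = new_params(obj$D), config = obj$config,
                 step = obj$step, log = log),
            class = "fv_cvgan")
}

#' Write and read CSV manifests
#' @param manifest Manifest tibble.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}
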