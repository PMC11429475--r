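# shared fixture builders (all data generated in code at test time)

noiseless_spec <- function(size = 64, radius = 20, cdr = 0.7, seed = 3) {
  phantom_spec(image_size = size, disc_radius = radius,
               cup_to_disc_ratio = cdr, n_vessels = 0, noise_sigma = 0,
               illumination_slope = 0, seed = seed)
}

# small in-memory labelled dataset + manifest for classifier tests
phantom_set <- function(classes, per_class, size = 64, radius = round(size / 4.5),
                        seed = 1, noise = 5, split = "train") {
  imgs <- list()
  rows <- list()
  for (cls in classes) {
    for (i in seq_len(per_class)) {
      id <- sprintf("%s_%03d", gsub("/", "-", cls), i)
      sp <- phantom_spec(image_size = size, disc_radius = radius,
                         cup_to_disc_ratio = class_default_cdr(cls),
                         noise_sigma = noise,
                         seed = derive_seed(seed, label_code(cls), i))
      imgs[[id]] <- render_phantom(sp, cls, id = id)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, path = NA_character_, class = cls, source = "original",
        split = split)
    }
  }
  list(images = imgs, manifest = dplyr::bind_rows(rows))
}

# numeric finite-difference gradient of a scalar-valued function
fd_grad <- function(fun, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fun(xp) - fun(xm)) / (2 * eps)
  }
  g
}

two_class_phantoms <- function(n, size = 16, seed = 0) {
  lapply(seq_len(n), function(i) {
    cls <- c("normal", "glaucoma")[(i %% 2) + 1]
    render_phantom(phantom_spec(image_size = size, disc_radius = round(size / 3.2),
                                cup_to_disc_ratio = class_default_cdr(cls),
                                n_vessels = 0, noise_sigma = 0,
                                illumination_slope = 0, seed = i * 13 + seed),
                   cls)
  })
}
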