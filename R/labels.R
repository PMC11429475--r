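#' The five-way glaucoma grading scheme
#'
#' The classifier grades fundus photographs into five classes: glaucoma,
#' normal, POAG/NTG (primary open-angle / normal-tension glaucoma), referable
#' and suspect. Codes are fixed integers 0-4 used throughout manifests,
#' model heads and metrics; the name/code map is bijective.
#'
#' @return A tibble with columns `name`, `code` and `default_cdr`, the
#'   cup-to-disc ratio used by the phantom generator for that class.
#' @export
#' @examples
#' glaucoma_classes()
glaucoma_classes <- function() {
  tibble::tibble(
    name = c("glaucoma", "normal", "POAG/NTG", "referable", "suspect"),
    code = 0:4,
    # clinically plausible ordering of cupping severity; fixture constants,
    # overridable per phantom spec
    default_cdr = c(0.70, 0.30, 0.60, 0.55, 0.45)
  )
}

#' @rdname glaucoma_classes
#' @param name Class name.
#' @export
label_code <- function(name) {
  cl <- glaucoma_classes()
  i <- match(name, cl$name)
  if (anyNA(i)) {
    rlang::abort(paste0("unknown class label: ", paste(name[is.na(i)], collapse = ", ")),
                 class = "fundusvit_bad_label")
  }
  cl$code[i]
}

#' @rdname glaucoma_classes
#' @param code Integer class code (0-4).
#' @export
label_name <- function(code) {
  cl <- glaucoma_classes()
  i <- match(code, cl$code)
  if (anyNA(i)) {
    rlang::abort("class code outside 0-4", class = "fundusvit_bad_label")
  }
  cl$name[i]
}

#' Default cup-to-disc ratio for a class
#'
#' Encodes that glaucomatous eyes show larger cupping, so phantom classes are
#' geometrically separable: strictly increasing from normal through suspect,
#' referable and POAG/NTG to glaucoma, all in (0, 1).
#'
#' @param label Class name (see [glaucoma_classes()]).
#' @return The default cup-to-disc ratio.
#' @export
class_default_cdr <- function(label) {
  cl <- glaucoma_classes()
  cl$default_cdr[match(label_code(label), cl$code)]
}
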