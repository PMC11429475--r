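# Confusion-matrix construction and classification metrics: accuracy,
# precision, recall/sensitivity, specificity and F1 with one-vs-rest
# reduction and macro (optionally micro/weighted) averaging.

#' Build a 5 x 5 confusion matrix
#'
#' Rows are true classes, columns predicted classes, both coded 0-4.
#'
#' @param true_labels,predicted_labels Equal-length vectors of class codes
#'   (0-4) or class names.
#' @return A `confusion_matrix`: integer matrix with class-name dimnames.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    rlang::abort("label vectors differ in length", class = "fundusvit_bad_params")
  }
  to_code <- function(x) if (is.numeric(x)) {
    if (length(x) && (any(x < 0) || any(x > 4))) {
      rlang::abort("class code outside 0-4", class = "fundusvit_bad_label")
    }
    as.integer(x)
  } else label_code(x)
  ti <- to_code(true_labels); pi <- to_code(predicted_labels)
  cm <- matrix(0L, 5, 5, dimnames = list(true = glaucoma_classes()$name,
                                         predicted = glaucoma_classes()$name))
  for (k in seq_along(ti)) cm[ti[k] + 1L, pi[k] + 1L] <- cm[ti[k] + 1L, pi[k] + 1L] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Binary classification metrics from a 2 x 2 count table
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), recall (equals
#' sensitivity) TP/(TP+FN), specificity TN/(TN+FP) and F1, the harmonic mean
#' of precision and recall. A zero denominator yields NaN (an explicit
#' undefined-metric signal, never a silent zero).
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Named numeric vector `acc`, `pre`, `rec`, `spe`, `f1`.
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) {
    rlang::abort("counts must be non-negative", class = "fundusvit_bad_params")
  }
  if (tp + tn + fp + fn == 0) {
    rlang::abort("all counts zero: metrics undefined", class = "fundusvit_undefined_metric")
  }
  acc <- (tp + tn) / (tp + tn + fp + fn)
  pre <- if (tp + fp > 0) tp / (tp + fp) else NaN
  rec <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spe <- if (tn + fp > 0) tn / (tn + fp) else NaN
  f1 <- if (!is.nan(pre) && !is.nan(rec) && pre + rec > 0) {
    2 * pre * rec / (pre + rec)
  } else NaN
  c(acc = acc, pre = pre, rec = rec, spe = spe, f1 = f1)
}

#' Multi-class metric report from a confusion matrix
#'
#' Each class is reduced one-vs-rest; macro averages are unweighted means
#' over classes whose metric is defined (undefined entries are dropped with
#' a warning rather than counted as zero). Micro and frequency-weighted
#' averages are also reported. Overall accuracy is trace/total.
#'
#' @param cm A [confusion_matrix()].
#' @param average Averaging scheme for the headline numbers.
#' @return A `metric_report` with tibbles `per_class` and `summary`.
#' @export
multiclass_report <- function(cm, average = c("macro", "micro", "weighted")) {
  average <- match.arg(average)
  if (sum(cm) == 0) rlang::abort("empty confusion matrix", class = "fundusvit_bad_params")
  total <- sum(cm)
  per <- purrr::map_dfr(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    m <- suppressWarnings(binary_metrics(tp, tn, fp, fn))
    tibble::tibble(class = rownames(cm)[i], n = sum(cm[i, ]),
                   tp = tp, tn = tn, fp = fp, fn = fn,
                   accuracy = unname(m["acc"]), precision = unname(m["pre"]),
                   recall = unname(m["rec"]), specificity = unname(m["spe"]),
                   f1 = unname(m["f1"]))
  })
  if (anyNA(per$precision) || any(is.nan(per$precision)) ||
      any(is.nan(per$recall)) || any(is.nan(per$f1))) {
    rlang::warn("some per-class metrics are undefined; macro averages skip them")
  }
  nz_mean <- function(x) mean(x[!is.nan(x)])
  w_mean <- function(x) {
    ok <- !is.nan(x)
    sum(x[ok] * per$n[ok]) / sum(per$n[ok])
  }
  micro_tp <- sum(per$tp)
  micro <- tibble::tibble(
    average = c("macro", "weighted", "micro"),
    precision = c(nz_mean(per$precision), w_mean(per$precision),
                  micro_tp / sum(per$tp + per$fp)),
    recall = c(nz_mean(per$recall), w_mean(per$recall),
               micro_tp / sum(per$tp + per$fn)),
    specificity = c(nz_mean(per$specificity), w_mean(per$specificity),
                    sum(per$tn) / sum(per$tn + per$fp)),
    f1 = c(nz_mean(per$f1), w_mean(per$f1),
           2 * micro_tp / (2 * micro_tp + sum(per$fp) + sum(per$fn))))
  structure(list(per_class = per, summary = micro,
                 overall_accuracy = sum(diag(cm)) / total,
                 average = average, cm = cm),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Multi-class metric report (", sum(x$cm), " samples)\n", sep = "")
  cat(sprintf("overall accuracy: %.4f\n", x$overall_accuracy))
  sel <- dplyr::filter(x$summary, .data$average == x$average)
  cat(sprintf("%s precision %.4f | recall %.4f | specificity %.4f | F1 %.4f\n",
              x$average, sel$precision, sel$recall, sel$specificity, sel$f1))
  print(x$per_class[, c("class", "n", "precision", "recall", "specificity", "f1")])
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-class metrics as a tibble
#' @param x A `metric_report`.
#' @param ... Unused.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_class

#' One-row summary of a metric report
#' @param x A `metric_report`.
#' @param ... Unused.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  sel <- dplyr::filter(x$summary, .data$average == x$average)
  tibble::tibble(accuracy = x$overall_accuracy, precision = sel$precision,
                 recall = sel$recall, specificity = sel$specificity,
                 f1 = sel$f1, average = x$average, n = sum(x$cm))
}
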