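test_that("confusion matrix counts agree with brute force", {
  expect_identical(confusion_matrix(c(0, 1, 2), c(0, 1, 2)),
                   confusion_matrix(c("glaucoma", "normal", "POAG/NTG"),
                                    c("glaucoma", "normal", "POAG/NTG")))
  cm0 <- confusion_matrix(integer(), integer())
  expect_equal(sum(cm0), 0)
  set.seed(1)
  tr <- sample(0:4, 200, TRUE); pr <- sample(0:4, 200, TRUE)
  cm <- confusion_matrix(tr, pr)
  for (i in 0:4) for (j in 0:4) {
    expect_identical(cm[i + 1, j + 1], sum(tr == i & pr == j))
  }
  expect_equal(sum(cm), 200)
  expect_error(confusion_matrix(c(0, 7), c(0, 1)), class = "fundusvit_bad_label")
  expect_error(confusion_matrix(0:2, 0:1), class = "fundusvit_bad_params")
})

test_that("binary metrics match their closed forms", {
  perfect <- binary_metrics(5, 5, 0, 0)
  expect_equal(unname(perfect), rep(1, 5))
  half <- binary_metrics(1, 1, 1, 1)
  expect_equal(unname(half), rep(0.5, 5))
  # harmonic mean: Pre = 1, Rec = 0.5 -> F1 = 2/3
  m <- binary_metrics(1, 0, 0, 1)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_true(is.nan(binary_metrics(0, 5, 0, 0)["pre"]))
  expect_error(binary_metrics(0, 0, 0, 0), class = "fundusvit_undefined_metric")
  expect_error(binary_metrics(-1, 0, 0, 0), class = "fundusvit_bad_params")
})

test_that("multiclass report reduces one-vs-rest and conserves margins", {
  set.seed(2)
  tr <- sample(0:4, 300, TRUE, prob = c(0.4, 0.3, 0.1, 0.1, 0.1))
  pr <- ifelse(runif(300) < 0.6, tr, sample(0:4, 300, TRUE))
  cm <- confusion_matrix(tr, pr)
  rep <- multiclass_report(cm)
  per <- rep$per_class
  for (i in seq_len(5)) {
    expect_equal(per$tp[i] + per$fn[i], sum(cm[i, ]))     # row margin
    expect_equal(per$tp[i] + per$fp[i], sum(cm[, i]))     # column margin
    bm <- binary_metrics(per$tp[i], per$tn[i], per$fp[i], per$fn[i])
    expect_equal(per$precision[i], unname(bm["pre"]))
    expect_equal(per$recall[i], unname(bm["rec"]))
  }
  expect_equal(rep$overall_accuracy, mean(tr == pr))
  # diagonal matrix gives all ones
  repd <- multiclass_report(confusion_matrix(0:4, 0:4))
  expect_equal(dplyr::filter(repd$summary, average == "macro")$f1, 1)
  expect_equal(repd$overall_accuracy, 1)
})

test_that("macro averaging skips undefined classes with a warning", {
  tr <- c(0, 0, 1, 1, 2)
  pr <- c(0, 1, 1, 1, 1)          # classes 2..4 never predicted
  cm <- confusion_matrix(tr, pr)
  expect_warning(rep <- multiclass_report(cm), "undefined")
  mac <- dplyr::filter(rep$summary, average == "macro")
  expect_false(is.nan(mac$precision))
})

test_that("macro metrics are invariant under class relabelling", {
  set.seed(5)
  tr <- sample(0:4, 200, TRUE); pr <- sample(0:4, 200, TRUE)
  perm <- c(2L, 0L, 4L, 1L, 3L)
  r1 <- suppressWarnings(multiclass_report(confusion_matrix(tr, pr)))
  r2 <- suppressWarnings(multiclass_report(confusion_matrix(perm[tr + 1],
                                                            perm[pr + 1])))
  m1 <- dplyr::filter(r1$summary, average == "macro")
  m2 <- dplyr::filter(r2$summary, average == "macro")
  expect_equal(m1$precision, m2$precision)
  expect_equal(m1$recall, m2$recall)
  expect_equal(r1$overall_accuracy, r2$overall_accuracy)
})

test_that("per-class metrics agree with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(3)
  tr <- factor(sample(0:4, 250, TRUE), levels = 0:4)
  pr <- factor(sample(0:4, 250, TRUE), levels = 0:4)
  ours <- suppressWarnings(
    multiclass_report(confusion_matrix(as.integer(as.character(tr)),
                                       as.integer(as.character(pr)))))
  ref <- caret::confusionMatrix(pr, tr)
  expect_equal(unname(ours$overall_accuracy),
               unname(ref$overall["Accuracy"]))
  refclass <- ref$byClass            # rows: classes, cols incl Precision/Recall
  for (i in 1:5) {
    if (!is.nan(ours$per_class$precision[i]) && !is.na(refclass[i, "Precision"])) {
      expect_equal(ours$per_class$precision[i],
                   unname(refclass[i, "Precision"]))
    }
    expect_equal(ours$per_class$recall[i],
                 unname(refclass[i, "Sensitivity"]))
    expect_equal(ours$per_class$specificity[i],
                 unname(refclass[i, "Specificity"]))
  }
})

test_that("tidy and glance expose the report as tibbles", {
  rep <- multiclass_report(confusion_matrix(0:4, 0:4))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep)), 5)
  g <- glance(rep)
  expect_equal(g$accuracy, 1)
  expect_equal(g$n, 5)
})
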