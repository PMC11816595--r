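test_that("confusion counts follow the one-vs-rest convention", {
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  cc <- confusion_from_predictions(truth, truth, positive_class = 1)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 4L, TN = 6L, FP = 0L, FN = 0L))

  cc2 <- confusion_from_predictions(truth, rep(1, 10), positive_class = 1)
  expect_equal(unclass(cc2)[c("TP", "TN", "FP", "FN")],
               list(TP = 4L, TN = 0L, FP = 6L, FN = 0L))

  expect_error(confusion_from_predictions(integer(0), integer(0), 1),
               "empty")
  expect_error(confusion_from_predictions(c(1, 0), c(1), 1), "length")

  # permutation invariance
  set.seed(1)
  t3 <- sample(0:1, 40, replace = TRUE)
  p3 <- sample(0:1, 40, replace = TRUE)
  ord <- sample(40)
  expect_identical(
    unclass(confusion_from_predictions(t3, p3, 1)),
    unclass(confusion_from_predictions(t3[ord], p3[ord], 1)))
})

test_that("the six statistics match direct arithmetic on printed counts", {
  # liquid-based cytology benchmark confusion counts
  m <- compute_metrics(confusion_counts(TP = 895, TN = 1225, FP = 12,
                                        FN = 20))
  expect_equal(m$accuracy, 2120 / 2152, tolerance = 1e-12)
  expect_equal(m$recall, 895 / 915, tolerance = 1e-12)
  expect_equal(m$precision, 895 / 907, tolerance = 1e-12)
  expect_equal(m$specificity, 1225 / 1237, tolerance = 1e-12)
  expect_equal(m$f_measure,
               2 * (895 / 915) * (895 / 907) / (895 / 915 + 895 / 907),
               tolerance = 1e-12)
  expect_equal(m$g_means, sqrt((895 / 915) * (1225 / 1237)),
               tolerance = 1e-12)

  m2 <- compute_metrics(confusion_counts(TP = 912, TN = 1180, FP = 20,
                                         FN = 18))
  expect_equal(m2$recall, 912 / 930, tolerance = 1e-12)

  perfect <- compute_metrics(confusion_counts(5, 5, 0, 0))
  expect_true(all(vapply(perfect, identical, logical(1), 1)))
})

test_that("undefined ratios are reported as missing, never zero", {
  m <- compute_metrics(confusion_counts(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_equal(m$accuracy, 1)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "at least one")
})

test_that("G-means and F-measure satisfy their algebraic identities", {
  set.seed(7)
  for (i in 1:25) {
    cc <- confusion_counts(sample(0:30, 1), sample(0:30, 1),
                           sample(0:30, 1), sample(0:30, 1))
    tot <- cc$TP + cc$TN + cc$FP + cc$FN
    if (tot == 0) next
    m <- compute_metrics(cc)
    if (!is.na(m$g_means)) {
      expect_equal(m$g_means^2, m$recall * m$specificity, tolerance = 1e-12)
    }
    mp <- compute_metrics(cc, g_means_as_printed = TRUE)
    if (!is.na(mp$g_means)) {
      expect_equal(mp$g_means, m$recall * m$specificity, tolerance = 1e-12)
    }
    if (!is.na(m$f_measure)) {
      # harmonic mean is bounded by the geometric mean
      expect_lte(m$f_measure,
                 sqrt(m$recall * m$precision) + 1e-12)
      if (isTRUE(all.equal(m$recall, m$precision))) {
        expect_equal(m$f_measure, m$recall, tolerance = 1e-12)
      }
    }
  }
})

test_that("metrics agree with a brute-force recount on random labels", {
  set.seed(11)
  for (i in 1:10) {
    truth <- sample(0:2, 60, replace = TRUE)
    pred <- sample(0:2, 60, replace = TRUE)
    for (cl in 0:2) {
      cc <- confusion_from_predictions(truth, pred, cl)
      # independent recount by explicit enumeration
      tp <- 0; tn <- 0; fp <- 0; fn <- 0
      for (j in seq_along(truth)) {
        if (truth[j] == cl && pred[j] == cl) tp <- tp + 1
        if (truth[j] != cl && pred[j] != cl) tn <- tn + 1
        if (truth[j] != cl && pred[j] == cl) fp <- fp + 1
        if (truth[j] == cl && pred[j] != cl) fn <- fn + 1
      }
      expect_equal(cc$TP, tp)
      expect_equal(cc$TN, tn)
      expect_equal(cc$FP, fp)
      expect_equal(cc$FN, fn)
      m <- compute_metrics(cc)
      expect_equal(m$accuracy, (tp + tn) / 60, tolerance = 1e-12)
      if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn),
                                    tolerance = 1e-12)
    }
  }
})

test_that("macro metrics average the per-class one-vs-rest reports", {
  truth <- c(0, 0, 1, 1, 2, 2)
  pred <- c(0, 1, 1, 1, 2, 0)
  mm <- metrics_macro(truth, pred)
  expect_named(mm$per_class, c("0", "1", "2"))
  accs <- vapply(mm$per_class, function(m) m$accuracy, numeric(1))
  expect_equal(unname(mm$macro["accuracy"]), mean(accs))
  tbl <- format_metrics_table(c(mm$per_class, list(macro = as.list(mm$macro))))
  expect_match(tbl, "accuracy")
  expect_equal(length(strsplit(tbl, "\n")[[1]]), 5L)  # header + 3 + macro
})
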