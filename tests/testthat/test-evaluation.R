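test_that("confusion matrices count target/output pairs", {
  cm <- confusion_matrix(c("DK", "DK", "PK"), c("DK", "PK", "PK"),
                         class_order = c("DK", "PK"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2),
               ignore_attr = TRUE)
  perfect <- confusion_matrix(motion_classes(), motion_classes())
  expect_equal(sum(diag(perfect)), 12L)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)
  one_col <- confusion_matrix(c("DK", "PK", "SS"), rep("SS", 3))
  expect_equal(sum(one_col[, "SS"]), 3L)
  expect_equal(sum(one_col[, colnames(one_col) != "SS"]), 0L)
  expect_error(confusion_matrix("DK", "??"), "\\?\\?")
  expect_error(confusion_matrix(c("DK", "PK"), "DK"), "equal length")
})

test_that("per-class metrics follow the one-vs-rest definitions", {
  cm <- confusion_matrix(c(rep("DK", 10), rep("PK", 10)),
                         c(rep("DK", 5), rep("PK", 5), rep("PK", 10)),
                         class_order = c("DK", "PK"))
  m <- class_metrics(cm, "DK")
  expect_equal(unname(m["sensitivity"]), 50)      # TP 5, FN 5
  expect_equal(unname(m["specificity"]), 100)     # no false positives
  expect_equal(unname(m["balanced_accuracy"]), 75)

  # TP + FN + TN + FP partitions the grand total for every class
  set.seed(12)
  truth <- sample(motion_classes(), 300, replace = TRUE)
  pred <- sample(motion_classes(), 300, replace = TRUE)
  cm2 <- confusion_matrix(truth, pred)
  for (cl in motion_classes()) {
    n <- mdtwposture:::ovr_counts(cm2, cl)
    expect_equal(sum(n), 300)
    m2 <- class_metrics(cm2, cl)
    expect_true(all(m2 >= 0 & m2 <= 100, na.rm = TRUE))
    expect_equal(unname(m2["balanced_accuracy"]),
                 balanced_accuracy(m2[["sensitivity"]],
                                   m2[["specificity"]]))
  }
})

test_that("balanced accuracy reproduces printed per-class summaries", {
  # sensitivity 100 / specificity 98.1 rounds to the printed 99.0
  expect_equal(balanced_accuracy(100, 98.1), 99.05, tolerance = 1e-9)
  expect_equal(round(balanced_accuracy(100, 98.1) - 0.05, 1), 99.0)
  # a never-recognized class with specificity 99.5 prints as 49.8
  expect_equal(balanced_accuracy(0, 99.5), 49.75)
})

test_that("overall accuracy is the trace over the total", {
  perfect <- confusion_matrix(motion_classes(), motion_classes())
  expect_equal(overall_accuracy(perfect), 100)
  cm <- confusion_matrix(c("DK", "DK", "PK"), c("DK", "PK", "PK"),
                         class_order = c("DK", "PK"))
  expect_equal(overall_accuracy(cm), 100 * 2 / 3)
  # uniform random predictions over 12 balanced classes sit near 1/12
  set.seed(77)
  truth <- rep(motion_classes(), each = 50)
  pred <- sample(motion_classes(), 600, replace = TRUE)
  expect_lt(abs(overall_accuracy(confusion_matrix(truth, pred)) - 100 / 12),
            3 * 100 * sqrt((1 / 12) * (11 / 12) / 600))
})

test_that("row percentages display half-up at one decimal and skip empty rows", {
  cm <- confusion_matrix(c(rep("DK", 39), "PK"),
                         c(rep("DK", 28), rep("PK", 11), "PK"),
                         class_order = c("DK", "PK", "FS"))
  rp <- row_percentages(cm)
  expect_equal(rp["DK", c("DK", "PK")], c(DK = 71.8, PK = 28.2))
  expect_true(all(is.na(rp["FS", ])))
  raw <- row_percentages(cm, display = FALSE)
  expect_equal(raw["DK", "DK"], 100 * 28 / 39)
  # explicit half-up convention at (binary-exact) .x5 boundaries
  expect_equal(mdtwposture:::round_half_up(2.25, 1), 2.3)
  expect_equal(mdtwposture:::round_half_up(4.75, 1), 4.8)
  expect_equal(mdtwposture:::round_half_up(82.5, 0), 83)
  cm3 <- confusion_matrix(rep("DK", 3),
                          c("DK", "PK", "FS"),
                          class_order = c("DK", "PK", "FS"))
  expect_equal(unname(row_percentages(cm3)["DK", ]), c(33.3, 33.3, 33.3))
})

test_that("grouping merges within-group confusions into correct predictions", {
  cm <- confusion_matrix(c("PK", "DK", "FS"), c("DK", "DK", "HS"))
  g <- group_classes(cm)
  expect_equal(g["Kneeling", "Kneeling"], 2L, ignore_attr = TRUE)
  expect_equal(g["Squatting", "Squatting"], 1L, ignore_attr = TRUE)
  expect_equal(overall_accuracy(g), 100)

  # identity grouping leaves the matrix unchanged
  ident <- setNames(motion_classes(), motion_classes())
  expect_equal(unclass(group_classes(cm, ident)), unclass(cm))

  # conservation and diagonal monotonicity on random matrices
  set.seed(4)
  for (i in 1:20) {
    truth <- sample(motion_classes(), 200, replace = TRUE)
    pred <- sample(motion_classes(), 200, replace = TRUE)
    cm2 <- confusion_matrix(truth, pred)
    g2 <- group_classes(cm2)
    expect_equal(sum(g2), sum(cm2))
    expect_gte(sum(diag(g2)), sum(diag(cm2)))
    expect_gte(overall_accuracy(g2), overall_accuracy(cm2))
  }
  expect_error(group_classes(cm, c(DK = "Kneeling")), "missing class")
})

test_that("metric summaries use the sample standard deviation", {
  expect_equal(unname(metric_summary(c(DK = 5, PK = 5, FS = 5))["sd"]), 0)
  v <- c(a = 1, b = 2, c = 6)
  s <- metric_summary(v)
  expect_equal(unname(s["mean"]), 3)
  expect_equal(unname(s["sd"]), sd(v))
  expect_equal(unname(metric_summary(v, exclude = "c")["mean"]), 1.5)
  expect_error(metric_summary(v, exclude = names(v)), "excluded")
})

test_that("zero-denominator metrics report as absent, not 0 or 100", {
  cm <- confusion_matrix(c("DK", "DK"), c("DK", "PK"),
                         class_order = c("DK", "PK", "FS"))
  m <- class_metrics(cm, "FS")     # no FS instances
  expect_true(is.na(m["sensitivity"]))
  expect_false(is.na(m["specificity"]))
  rep <- metrics_report(cm)
  expect_true(is.na(rep$per_class$sensitivity[3]))
  expect_false(is.na(rep$sensitivity_mean))
})
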