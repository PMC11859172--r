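# A compact stratified library built from the synthetic cohort.
selection_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- small_cohort()$library
    cache
  }
})

test_that("stratified holdout withholds the per-class fraction reproducibly", {
  lib <- selection_library()
  plan <- stratified_holdout(lib, seed = 42L)
  expect_setequal(c(plan$train_ids, plan$test_ids), lib$ids)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0L)
  # per class: round-half-up(0.2 n), minimum 1
  for (cl in unique(lib$labels)) {
    n <- sum(lib$labels == cl)
    n_test <- sum(lib$labels[match(plan$test_ids, lib$ids)] == cl)
    expect_identical(n_test, max(1L, as.integer(floor(0.2 * n + 0.5))))
  }
  # fold sizes differ by <= 1 within each class
  train_labels <- lib$labels[match(plan$train_ids, lib$ids)]
  for (cl in unique(train_labels)) {
    sizes <- tabulate(plan$folds[train_labels == cl], 5L)
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_identical(stratified_holdout(lib, seed = 42L), plan)
  expect_false(identical(stratified_holdout(lib, seed = 43L)$test_ids,
                         plan$test_ids))
})

test_that("20% of 100 is 80/20 and 20% of 11 withholds 2", {
  mk <- function(n, label) lapply(seq_len(n), function(i)
    flat_template(c(i / n, 0, 0, 0, 0, 0), label, paste0(label, i)))
  lib100 <- template_library(mk(100, "DK"))
  p <- stratified_holdout(lib100, seed = 1L)
  expect_length(p$train_ids, 80L)
  expect_length(p$test_ids, 20L)
  lib11 <- template_library(mk(11, "DK"))
  expect_length(stratified_holdout(lib11, seed = 1L)$test_ids, 2L)
  expect_error(stratified_holdout(template_library(mk(4, "DK"))),
               "fewer than 5")
})

test_that("split plans serialize round-trip exactly", {
  plan <- stratified_holdout(selection_library(), seed = 5L)
  f <- tempfile(fileext = ".json")
  write_split_plan(plan, f)
  back <- read_split_plan(f)
  expect_identical(back$train_ids, plan$train_ids)
  expect_identical(back$test_ids, plan$test_ids)
  expect_identical(back$folds, plan$folds)
  expect_identical(back$seed, plan$seed)
})

test_that("five-fold CV is perfect on separable classes and exact on duplicates", {
  # cleanly separated shape classes cross-validate perfectly
  toy <- toy_library(n_per_class = 10)
  toy_plan <- stratified_holdout(toy, seed = 8L)
  expect_equal(as.numeric(five_fold_cv_accuracy(toy, toy_plan)), 1.0)

  # the synthetic cohort (cross-subject folds, subject idiosyncrasy)
  # stays well above chance but below the separable ceiling
  lib <- selection_library()
  plan <- stratified_holdout(lib, seed = 3L)
  acc <- five_fold_cv_accuracy(lib, plan, w = weights_tuned())
  expect_gte(as.numeric(acc), 0.7)
  expect_length(attr(acc, "folds"), 5L)
  # cached pairwise distances reproduce the uncached evaluation exactly
  pw <- mdtwposture:::pairwise_channel_distances(lib, plan, 50L)
  acc2 <- five_fold_cv_accuracy(lib, plan, w = weights_tuned(),
                                pairwise = pw)
  expect_identical(as.numeric(acc), as.numeric(acc2))
})

test_that("band tuning evaluates the whole grid; wide bands match unbounded", {
  lib <- subset_library(selection_library(),
                        selection_library()$labels %in%
                          c("DK", "PK", "FS", "HS", "SS"))
  plan <- stratified_holdout(lib, seed = 2L)
  rep <- tune_band(lib, plan, grid = seq(0L, 100L, 10L))
  expect_length(rep$accuracy, 11L)
  expect_true(rep$selected %in% rep$grid)
  expect_equal(max(rep$accuracy),
               as.numeric(five_fold_cv_accuracy(
                 lib, plan, w = weights_initial(),
                 band_halfwidth = rep$selected)))
  # band >= sequence length behaves like an unbounded band
  a101 <- five_fold_cv_accuracy(lib, plan, band_halfwidth = 101L)
  ainf <- five_fold_cv_accuracy(lib, plan, band_halfwidth = Inf)
  expect_identical(as.numeric(a101), as.numeric(ainf))
})

test_that("the band trades off timing tolerance against discrimination", {
  # classes differing in a small shape feature (a notch on the bump top)
  # under heavy within-class temporal jitter: a diagonal-only band cannot
  # align the jitter, drowning the feature, while a generous band aligns
  # the bumps and lets the notch decide
  set.seed(14)
  u <- seq_len(101)
  mk <- function(notch, label, i) {
    centre <- 50 + runif(1, -25, 25)
    x <- 2 * exp(-((u - centre)^2) / (2 * 12^2)) - 1
    if (notch) x <- x - 1.2 * exp(-((u - centre)^2) / (2 * 2.5^2))
    a <- matrix(rep(x, each = 6), 6) + matrix(rnorm(606, 0, 0.02), 6)
    as_template(scale_normalize(movement_sequence(a, label = label,
                                                  time_normalized = TRUE)),
                id = paste0(label, i))
  }
  tpl <- c(lapply(1:10, function(i) mk(FALSE, "DK", i)),
           lapply(1:10, function(i) mk(TRUE, "FS", i)))
  lib <- template_library(tpl)
  plan <- stratified_holdout(lib, seed = 1L)
  acc0 <- as.numeric(five_fold_cv_accuracy(lib, plan, band_halfwidth = 0L))
  acc40 <- as.numeric(five_fold_cv_accuracy(lib, plan, band_halfwidth = 40L))
  expect_gt(acc40, acc0)

  # conversely, when the *class* difference is purely a temporal shift, an
  # over-generous band warps it away while a tight band preserves it
  mk2 <- function(centre, label, i) {
    x <- exp(-((u - centre - rnorm(1, 0, 4))^2) / 50) * 2 - 1
    a <- matrix(rep(x, each = 6), 6) + matrix(rnorm(606, 0, 0.02), 6)
    as_template(scale_normalize(movement_sequence(a, label = label,
                                                  time_normalized = TRUE)),
                id = paste0(label, i))
  }
  tpl2 <- c(lapply(1:10, function(i) mk2(30, "DK", i)),
            lapply(1:10, function(i) mk2(70, "FS", i)))
  lib2 <- template_library(tpl2)
  plan2 <- stratified_holdout(lib2, seed = 1L)
  accs <- vapply(c(5L, 90L), function(b)
    as.numeric(five_fold_cv_accuracy(lib2, plan2, band_halfwidth = b)),
    numeric(1))
  expect_gte(accs[1], accs[2])
})

test_that("the k grid spans 1 to the training size and k = n votes the mode", {
  expect_identical(log_k_grid(1911L)[1], 1)
  expect_identical(max(log_k_grid(1911L)), 1911)
  lib <- selection_library()
  plan <- stratified_holdout(lib, seed = 9L)
  rep <- tune_k(lib, plan, k_grid = c(1L, 5L, 25L))
  expect_identical(rep$grid, c(1L, 5L, 25L))
  expect_identical(rep$selected, 1L)   # separable classes favour k = 1
  expect_equal(max(rep$accuracy), rep$accuracy[rep$grid == 1L])

  # with k equal to the whole library, every prediction is the globally
  # most frequent label (on a deliberately imbalanced library)
  mkf <- function(v, label, i)
    flat_template(c(v, 0, 0, 0, 0, 0), label, paste0(label, i))
  imb <- template_library(c(
    lapply(1:9, function(i) mkf(i / 10, "SS", i)),
    lapply(1:3, function(i) mkf(-i / 4, "DK", i))))
  for (q in list(flat_norm_seq(c(-0.4, 0, 0, 0, 0, 0)),
                 flat_norm_seq(c(0.55, 0, 0, 0, 0, 0))))
    expect_identical(knn_classify(q, imb, k = 12L)$predicted, "SS")
})

test_that("weight tuning reuses cached distances and caps the grid size", {
  lib <- subset_library(selection_library(),
                        selection_library()$labels %in% c("DK", "PK", "SS"))
  plan <- stratified_holdout(lib, seed = 4L)
  # degenerate grid: single evaluation equals CV at the base weights
  rep0 <- suppressMessages(
    tune_weights(lib, plan, deltas = 0, rknee_grid = 1.0))
  expect_length(rep0$accuracy, 1L)
  expect_equal(rep0$accuracy,
               as.numeric(five_fold_cv_accuracy(lib, plan,
                                                w = weights_initial())))
  expect_equal(unname(unlist(rep0$selected)),
               unname(weights_initial()[mdtw_channels()]))
  # the full default grid exceeds a small cap and is refused with its size
  expect_error(suppressMessages(tune_weights(lib, plan, max_grid = 100L)),
               "117649")
  # the default delta grid has the stated 7 offsets
  expect_length(seq(-0.045, 0.045, by = 0.015), 7L)
})

test_that("cached weight-grid evaluation equals naive recomputation", {
  lib <- template_library(list(
    flat_template(c(0, 0, 0, 0, 0, 0), "STD", "a"),
    flat_template(c(0.3, 0.1, 0, 0, 0.2, 0), "STP", "b"),
    flat_template(c(0.6, 0.5, 0.4, 0.1, 0, 0), "DK", "c")))
  q <- flat_norm_seq(c(0.25, 0.05, 0, 0, 0.1, 0))
  arr <- channel_distance_array(list(q), lib, 50L)
  for (w in list(weights_initial(), weights_tuned(),
                 weight_vector(0.4, 0.1, 0.9, 0.7, 0.3, 0.2))) {
    cached <- combine_distance_array(arr, w)[1, ]
    naive <- vapply(lib$templates, function(t)
      mdtw_distance(q, t, w)$combined, numeric(1))
    expect_equal(unname(cached), unname(naive), tolerance = 1e-9)
  }
})

test_that("weight search prefers informative channels", {
  # only the knees separate the two classes; ankles are pure noise
  set.seed(19)
  u <- seq(0, 1, length.out = 101)
  mk <- function(label, i) {
    knee <- if (label == "DK") sin(2 * pi * u) else 2 * u - 1
    a <- rbind(r_knee = knee, l_knee = knee,
               r_ankle = rnorm(101, 0, 0.5), l_ankle = rnorm(101, 0, 0.5),
               r_hip = 0.5 * knee, l_hip = 0.5 * knee)
    a <- a + matrix(rnorm(606, 0, 0.02), 6)
    as_template(scale_normalize(movement_sequence(a, label = label,
                                                  time_normalized = TRUE)),
                id = paste0(label, i))
  }
  lib <- template_library(c(lapply(1:8, function(i) mk("DK", i)),
                            lapply(1:8, function(i) mk("FS", i))))
  plan <- stratified_holdout(lib, seed = 6L)
  rep <- suppressMessages(
    tune_weights(lib, plan, deltas = c(-0.045, 0, 0.045),
                 rknee_grid = c(0.7, 1.0)))
  w_sel <- unlist(rep$selected)
  expect_gte(w_sel[["r_knee"]] + w_sel[["l_knee"]],
             w_sel[["r_ankle"]] + w_sel[["l_ankle"]])
})
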