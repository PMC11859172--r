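test_that("named weight vectors carry the published coefficients", {
  wi <- weights_initial()
  wt <- weights_tuned()
  expect_equal(sum(wi), 3.75)
  expect_equal(sum(wt), 3.61)
  expect_equal(unname(wi["r_knee"]), 1.00)
  expect_equal(unname(wt["r_knee"]), 1.00)  # unwritten coefficient = 1
  expect_equal(unname(wt[c("l_ankle", "r_ankle", "l_knee", "l_hip", "r_hip")]),
               c(0.26, 0.20, 0.72, 0.67, 0.76))
  expect_error(weight_vector(0, 0, 0, 0, 0, 0), "positive")
  expect_error(weight_vector(-1, 1, 1, 1, 1, 1), "non-negative")
})

test_that("distance fusion is the weighted sum over the six channels", {
  zeros <- setNames(rep(0, 6), mdtw_channels())
  expect_equal(combine_distances(zeros, weights_tuned()), 0)
  expect_equal(combine_distances(zeros + 2, weights_tuned()), 7.22)
  expect_equal(combine_distances(zeros + 1, weights_initial()), 3.75)
  # linear in each input
  d <- setNames(runif(6), mdtw_channels())
  e5 <- d; e5["l_hip"] <- d["l_hip"] + 5
  expect_equal(combine_distances(e5, weights_tuned()) -
                 combine_distances(d, weights_tuned()),
               5 * 0.67)
  expect_error(combine_distances(d[-2]), names(d)[2])
})

test_that("mdtw distance pairs channels left-to-left and fuses linearly", {
  tpl <- flat_template(rep(0, 6), "STD")
  expect_equal(mdtw_distance(tpl, tpl)$combined, 0)

  # one channel offset by a constant: diagonal path, 101 unit costs
  seqq <- flat_norm_seq(c(1, 0, 0, 0, 0, 0))   # r_knee differs by 1
  br <- mdtw_distance(seqq, tpl, weights_tuned())
  expect_equal(unname(br$per_channel["r_knee"]), 101)
  expect_equal(sum(br$per_channel[-1]), 0)
  expect_equal(br$combined, 1.00 * 101)

  # uniform amplitude scaling of both inputs scales the fused distance
  lib <- toy_library()
  q <- lib$templates[[1]]
  t2 <- lib$templates[[4]]
  d1 <- mdtw_distance(q, t2)$combined
  q2 <- q; q2$angles <- 2 * q$angles
  t2b <- t2; t2b$angles <- 2 * t2$angles
  expect_equal(mdtw_distance(q2, t2b)$combined, 2 * d1, tolerance = 1e-9)

  raw <- generate_trial("DK", seed = 1)
  expect_error(mdtw_distance(raw, tpl), "normalized")
})

test_that("1-NN returns the minimum-distance template's label", {
  lib <- toy_library()
  q <- lib$templates[[2]]          # leave-in identity
  res <- knn_classify(q, lib)
  expect_identical(res$predicted, "DK")
  expect_equal(res$ranked$combined[1], 0)
  expect_identical(res$ranked$template_id[1], q$id)

  # two templates, argmin wins
  lib2 <- template_library(list(flat_template(rep(0, 6), "STD", "a"),
                                flat_template(rep(0.5, 6), "STP", "b")))
  q2 <- flat_norm_seq(rep(0.1, 6))
  expect_identical(knn_classify(q2, lib2)$predicted, "STD")

  expect_error(knn_classify(q, lib, k = 99), "between 1 and")
})

test_that("leave-in consistency holds for every library template", {
  lib <- toy_library(n_per_class = 4)
  for (i in seq_along(lib$templates))
    expect_identical(knn_classify(lib$templates[[i]], lib)$predicted,
                     lib$labels[i])
})

test_that("well-separated synthetic classes classify perfectly", {
  lib <- toy_library(n_per_class = 10)
  set.seed(33)
  u <- seq(0, 1, length.out = 101)
  correct <- 0L
  for (i in 1:20) {
    shape <- if (i <= 10) sin(2 * pi * u) else 2 * u - 1
    truth <- if (i <= 10) "DK" else "FS"
    a <- matrix(rep(shape, each = 6), nrow = 6) +
      matrix(rnorm(606, 0, 0.01), nrow = 6)
    q <- scale_normalize(movement_sequence(a, time_normalized = TRUE))
    pred <- knn_classify(q, lib)$predicted
    # brute-force check: prediction equals argmin over naive per-template
    # recomputation
    naive <- vapply(lib$templates, function(t)
      mdtw_distance(q, t)$combined, numeric(1))
    expect_identical(pred, lib$labels[which.min(naive)])
    correct <- correct + (pred == truth)
  }
  expect_identical(correct, 20L)
})

test_that("predictions are invariant to global weight rescaling", {
  lib <- toy_library(n_per_class = 3, jitter = 0.05)
  set.seed(8)
  q <- lib$templates[[sample(6, 1)]]
  q$angles <- q$angles + matrix(rnorm(606, 0, 0.05), 6)
  q$scale_normalized <- FALSE
  q <- scale_normalize(q)
  for (c_scale in c(0.2, 1, 13)) {
    expect_identical(knn_classify(q, lib, w = c_scale * weights_tuned())$predicted,
                     knn_classify(q, lib, w = weights_tuned())$predicted)
  }
})

test_that("per-channel distances are non-increasing in the band half-width", {
  lib <- toy_library(n_per_class = 2)
  q <- lib$templates[[1]]
  arrs <- lapply(c(5L, 20L, 50L, 101L), function(b)
    channel_distance_array(list(q), lib, b))
  for (i in seq_len(length(arrs) - 1L))
    expect_true(all(arrs[[i + 1L]] <= arrs[[i]] + 1e-12))
})

test_that("k > 1 majority vote breaks ties deterministically", {
  # counts win first
  expect_identical(mdtwposture:::vote_labels(c("DK", "FS", "FS"),
                                             c(0, 1, 2)), "FS")
  # tied counts: smaller mean distance wins
  expect_identical(mdtwposture:::vote_labels(c("DK", "FS", "DK", "FS"),
                                             c(1, 0, 3, 0.5)), "FS")
  # fully tied: canonical class order (DK before FS)
  expect_identical(mdtwposture:::vote_labels(c("FS", "DK"), c(1, 1)), "DK")

  lib2 <- template_library(list(flat_template(rep(0, 6), "STD", "a"),
                                flat_template(rep(0, 6), "STD", "b"),
                                flat_template(rep(0.4, 6), "STP", "c")))
  q <- flat_norm_seq(rep(0.05, 6))
  expect_identical(knn_classify(q, lib2, k = 3)$predicted, "STD")
})

test_that("batch classification matches one-by-one classification", {
  lib <- toy_library(n_per_class = 2, jitter = 0.05)
  qs <- lib$templates[c(1, 3, 2)]
  batch <- classify_batch(qs, lib)
  single <- vapply(qs, function(q) knn_classify(q, lib)$predicted,
                   character(1))
  expect_identical(batch$predicted, single)
  # cached per-channel array reuse gives identical fused distances
  again <- classify_batch(qs, lib, arr = batch$arr)
  expect_identical(again$combined, batch$combined)
})
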