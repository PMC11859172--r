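# Run code with a local RNG state: deterministic given `seed`, and the
# caller's global RNG stream is left untouched.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Stratified holdout split with five-fold partition of the training set
#'
#' Per class, a random `test_fraction` of templates (rounded half up,
#' minimum one) is withheld for testing; the remainder is partitioned into
#' five folds whose sizes differ by at most one within each class.
#' Deterministic given `seed`.
#'
#' @param lib A `template_library`; every class present must have at least
#'   5 templates so the folds are non-degenerate.
#' @param test_fraction Withheld fraction (default 0.2).
#' @param seed Integer RNG seed.
#' @return A `split_plan`: list with `train_ids`, `test_ids`, `folds`
#'   (named integer vector, fold 1-5 per training template id), `seed`,
#'   `test_fraction` and `stratification` (per-class train/test counts).
#' @export
stratified_holdout <- function(lib, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(lib, "template_library"))
  counts <- table(lib$labels)
  small <- names(counts)[counts < 5L]
  if (length(small))
    stop("class(es) with fewer than 5 templates: ",
         paste(small, collapse = ", "))
  with_local_seed(seed, {
    test <- character(0)
    folds <- integer(0)
    for (cl in names(counts)) {
      ids <- lib$ids[lib$labels == cl]
      n_test <- max(1L, round_half_up(test_fraction * length(ids)))
      ids <- sample(ids)
      test <- c(test, ids[seq_len(n_test)])
      tr <- ids[-seq_len(n_test)]
      f <- rep_len(1:5, length(tr))       # sizes differ by <= 1 per class
      folds <- c(folds, stats::setNames(f, tr))
    }
    train <- setdiff(lib$ids, test)
    folds <- folds[train]                  # library order within train
    strat <- data.frame(
      class = names(counts),
      n_train = vapply(names(counts), function(cl)
        sum(lib$labels[match(train, lib$ids)] == cl), integer(1)),
      n_test = vapply(names(counts), function(cl)
        sum(lib$labels[match(test, lib$ids)] == cl), integer(1)),
      row.names = NULL)
    structure(list(train_ids = train, test_ids = sort(test), folds = folds,
                   seed = seed, test_fraction = test_fraction,
                   stratification = strat),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (seed %d), 5 folds\n",
              length(x$train_ids), length(x$test_ids), x$seed))
  invisible(x)
}

#' Serialize and restore a split plan
#'
#' Round-trips exactly: `read_split_plan(write_split_plan(plan, f))`
#' reproduces the plan.
#'
#' @param plan A `split_plan`.
#' @param path JSON file path.
#' @return `write_split_plan` returns `path` invisibly; `read_split_plan`
#'   the restored `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(train_ids = plan$train_ids, test_ids = plan$test_ids,
         fold_ids = names(plan$folds), fold = unname(plan$folds),
         seed = plan$seed, test_fraction = plan$test_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = j$train_ids, test_ids = j$test_ids,
                 folds = stats::setNames(as.integer(j$fold), j$fold_ids),
                 seed = as.integer(j$seed),
                 test_fraction = j$test_fraction,
                 stratification = NULL),
            class = "split_plan")
}

# Pairwise per-channel distances among the training templates of `plan`,
# as an n_train x n_train x 6 array (queries = rows).
pairwise_channel_distances <- function(lib, plan, band_halfwidth = 50L) {
  train <- subset_library(lib, match(plan$train_ids, lib$ids))
  channel_distance_array(train$templates, train, band_halfwidth)
}

#' Five-fold cross-validated classification accuracy
#'
#' For each of the five folds, the other four populate the template
#' library and the held-out fold is classified; the returned accuracy is
#' the unweighted mean of the five per-fold accuracies (correct / total).
#'
#' @param lib A `template_library` (the full library; only the training
#'   ids in `plan` are used).
#' @param plan A `split_plan` from [stratified_holdout()].
#' @param w Weight vector.
#' @param k Number of neighbours.
#' @param band_halfwidth Band half-width.
#' @param pairwise Optional precomputed array from the training templates
#'   (rows and columns in `plan$train_ids` order) to reuse across grid
#'   evaluations; must match `band_halfwidth`.
#' @return Mean fold accuracy in \eqn{[0, 1]}; per-fold accuracies in
#'   attribute `"folds"`.
#' @export
five_fold_cv_accuracy <- function(lib, plan, w = weights_initial(),
                                  k = 1L, band_halfwidth = 50L,
                                  pairwise = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  if (is.null(pairwise))
    pairwise <- pairwise_channel_distances(lib, plan, band_halfwidth)
  labels <- lib$labels[match(plan$train_ids, lib$ids)]
  folds <- plan$folds[plan$train_ids]
  if (any(tabulate(folds, 5L) == 0L)) stop("empty cross-validation fold")
  combined <- combine_distance_array(pairwise, w)
  acc <- vapply(1:5, function(f) {
    q <- which(folds == f); r <- which(folds != f)
    if (k > length(r)) stop("k exceeds fold training size")
    pred <- predict_from_combined(combined[q, r, drop = FALSE],
                                  labels[r], k)
    mean(pred == labels[q])
  }, numeric(1))
  structure(mean(acc), folds = acc)
}

new_tuning_report <- function(axis, grid, accuracy, selected, seed = NA) {
  structure(list(axis = axis, grid = grid, accuracy = accuracy,
                 selected = selected, seed = seed),
            class = "tuning_report")
}

#' @export
print.tuning_report <- function(x, ...) {
  cat(sprintf("<tuning_report> axis %s: %d settings, best accuracy %.4f\n",
              x$axis, length(x$accuracy), max(x$accuracy)))
  cat("selected:", format(x$selected), "\n")
  invisible(x)
}

#' Grid-search the Sakoe-Chiba band half-width
#'
#' Evaluates five-fold cross-validated accuracy at each band in the grid
#' (default 0 to 100 in steps of 10) and selects the maximizer; ties go to
#' the smallest band (the least-warped model).
#'
#' @param lib,plan,w,k As in [five_fold_cv_accuracy()].
#' @param grid Integer vector of band half-widths.
#' @return A `tuning_report` with per-band accuracies and the selection.
#' @export
tune_band <- function(lib, plan, grid = seq(0L, 100L, 10L),
                      w = weights_initial(), k = 1L) {
  if (!length(grid)) stop("band grid must be non-empty")
  acc <- vapply(grid, function(b)
    as.numeric(five_fold_cv_accuracy(lib, plan, w, k, b)), numeric(1))
  best <- grid[which(acc == max(acc))]
  new_tuning_report("band_halfwidth",
                    grid, acc, min(best), seed = plan$seed)
}

#' Default logarithmic k grid
#'
#' Integers logarithmically spaced between 1 and `n_train`, rounded and
#' deduplicated (so both endpoints are always included).
#'
#' @param n_train Training-set size.
#' @param n_points Number of grid points before deduplication.
#' @return Increasing integer vector.
#' @export
log_k_grid <- function(n_train, n_points = 20L) {
  stopifnot(n_train >= 1)
  unique(pmin(n_train,
              round(exp(seq(0, log(n_train), length.out = n_points)))))
}

#' Grid-search the number of nearest neighbours
#'
#' Cross-validated accuracy at each k (default: a 20-point logarithmic
#' grid between 1 and the training size); ties select the smallest k.
#' The per-channel distance array is computed once and reused.
#'
#' @param lib,plan,w,band_halfwidth As in [five_fold_cv_accuracy()].
#' @param k_grid Integer vector of k values; each must be at most the
#'   smallest four-fold training size.
#' @return A `tuning_report`.
#' @export
tune_k <- function(lib, plan, k_grid = NULL, w = weights_initial(),
                   band_halfwidth = 50L) {
  n_train <- length(plan$train_ids)
  if (is.null(k_grid)) k_grid <- log_k_grid(n_train)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid > n_train))
    stop("k values must lie in [1, ", n_train, "]")
  min_fold_train <- min(vapply(1:5, function(f)
    sum(plan$folds != f), integer(1)))
  k_grid <- k_grid[k_grid <= min_fold_train]
  pw <- pairwise_channel_distances(lib, plan, band_halfwidth)
  acc <- vapply(k_grid, function(k)
    as.numeric(five_fold_cv_accuracy(lib, plan, w, k, band_halfwidth,
                                     pairwise = pw)), numeric(1))
  best <- k_grid[which(acc == max(acc))]
  new_tuning_report("k", k_grid, acc, min(best), seed = plan$seed)
}

#' Grid-search the channel weights
#'
#' Joint grid over the six weights: the five free channels vary within
#' `deltas` of their base value (default \eqn{\pm 0.045} in steps of
#' 0.015, i.e. 7 values each) while the right-knee weight takes the
#' values in `rknee_grid` (default 0.7 to 1.0 in steps of 0.05).  Because
#' the weights enter only the linear fusion, the per-channel distances are
#' computed once and every combination reuses them.  The full default
#' grid is \eqn{7^5 \times 7 = 117{,}649} combinations; a cap guards
#' against accidental explosions (pass `max_grid = Inf` to override, or
#' shorter `deltas` for a reduced desk-scale grid).  Ties select the
#' vector closest to `base` in L1 distance, then the first in grid order.
#'
#' @param lib,plan,k,band_halfwidth As in [five_fold_cv_accuracy()].
#' @param base Base weight vector (default [weights_initial()]).
#' @param deltas Offsets applied to each non-right-knee channel.
#' @param rknee_grid Absolute grid for the right-knee weight.
#' @param max_grid Refuse larger grids than this without override.
#' @return A `tuning_report`; `selected` is a weight vector.
#' @export
tune_weights <- function(lib, plan, base = weights_initial(),
                         deltas = seq(-0.045, 0.045, by = 0.015),
                         rknee_grid = seq(0.7, 1.0, by = 0.05),
                         k = 1L, band_halfwidth = 50L,
                         max_grid = 20000L) {
  free <- setdiff(mdtw_channels(), "r_knee")
  size <- length(deltas)^length(free) * length(rknee_grid)
  message("weight grid: ", size, " combinations")
  if (size > max_grid)
    stop("weight grid size ", size, " exceeds max_grid = ", max_grid,
         "; pass a larger max_grid or a reduced deltas grid")
  grid <- do.call(expand.grid, c(stats::setNames(
    lapply(free, function(ch) base[[ch]] + deltas), free),
    list(r_knee = rknee_grid)))
  grid <- grid[, mdtw_channels()]
  if (any(grid < 0)) stop("weight grid contains negative weights")
  pw <- pairwise_channel_distances(lib, plan, band_halfwidth)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    w <- stats::setNames(as.numeric(grid[i, ]), mdtw_channels())
    as.numeric(five_fold_cv_accuracy(lib, plan, w, k, band_halfwidth,
                                     pairwise = pw))
  }, numeric(1))
  best <- which(acc == max(acc))
  if (length(best) > 1L) {
    l1 <- rowSums(abs(sweep(grid[best, , drop = FALSE], 2L,
                            base[mdtw_channels()])))
    best <- best[which.min(l1)]
  } else best <- best[1L]
  new_tuning_report("weights", grid, acc,
                    stats::setNames(as.numeric(grid[best, ]),
                                    mdtw_channels()),
                    seed = plan$seed)
}
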