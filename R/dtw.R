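#' Local cost matrix between a template channel and a sequence channel
#'
#' Entry \eqn{(m, n)} is the Euclidean norm of the scalar difference,
#' \eqn{|t_m - s_n|}: small where the waveforms are locally similar.  The
#' top row compares the start of the template against the whole sequence,
#' the bottom row its end.
#'
#' @param template_channel,sequence_channel Non-empty finite numeric
#'   vectors (lengths M and N).
#' @return M x N numeric matrix of non-negative local distances.
#' @export
local_cost_matrix <- function(template_channel, sequence_channel) {
  if (!length(template_channel) || !length(sequence_channel))
    stop("channels must be non-empty")
  if (!all(is.finite(template_channel), is.finite(sequence_channel)))
    stop("channels must be finite")
  abs(outer(template_channel, sequence_channel, "-"))
}

#' Banded dynamic time warping between two channels
#'
#' Computes the DTW distance and warp path between a template channel (M
#' samples) and a sequence channel (N samples) under a Sakoe-Chiba band
#' \eqn{|m - n| \le} `band_halfwidth`.  The path starts at (1, 1), ends at
#' (M, N) and advances by the moves (+1, 0), (0, +1), (+1, +1); the
#' reported distance is the sum of local costs \eqn{|t_m - s_n|} over the
#' path cells.
#'
#' Two path rules are available.  `mode = "optimal"` (default) solves the
#' full accumulated-cost dynamic programme
#' \deqn{C(m,n) = d_{mn} + \min\{C(m-1,n),\ C(m,n-1),\ C(m-1,n-1)\}}
#' and backtracks (ties prefer the diagonal, then the vertical, then the
#' horizontal move, so paths are deterministic).  `mode = "greedy"`
#' advances step by step to whichever admissible neighbour has the
#' smallest *local* cost; it is cheaper but never beats the optimal
#' distance, and is retained for fidelity experiments with the literal
#' local-move formulation.
#'
#' @param template_channel,sequence_channel Non-empty finite numeric
#'   vectors.
#' @param band_halfwidth Non-negative integer band half-width, or `Inf`
#'   for unbounded.  Must be at least `|M - N|` to be feasible.
#' @param mode `"optimal"` or `"greedy"`.
#' @param normalize Optional normalization of the reported distance:
#'   `"none"` (default, the raw accumulated path cost), `"mn"` (divided by
#'   M*N) or `"path_len"` (divided by the path length).  With all
#'   comparisons at M = N = 101 the choice cannot change nearest-neighbour
#'   rankings.
#' @return A `warp_result`: list with `distance`, `ix`/`iy` (the two
#'   isometric warped index sequences, template and sequence), `path`
#'   (two-column matrix of (m, n) pairs), `band_halfwidth`, `mode`,
#'   `normalize`.
#' @export
dtw_distance <- function(template_channel, sequence_channel,
                         band_halfwidth = 50L,
                         mode = c("optimal", "greedy"),
                         normalize = c("none", "mn", "path_len")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  if (!length(template_channel) || !length(sequence_channel))
    stop("channels must be non-empty")
  if (!all(is.finite(template_channel), is.finite(sequence_channel)))
    stop("channels must be finite")
  M <- length(template_channel); N <- length(sequence_channel)
  if (is.infinite(band_halfwidth)) band <- -1L
  else {
    band <- as.integer(band_halfwidth)
    if (band < 0L) stop("band_halfwidth must be >= 0")
    if (band < abs(M - N))
      stop("band half-width ", band, " infeasible for lengths ", M, " x ",
           N, "; minimum feasible band is ", abs(M - N))
  }
  res <- cpp_dtw(as.numeric(template_channel),
                 as.numeric(sequence_channel),
                 band, mode == "greedy", TRUE)
  dist <- res$distance
  dist <- switch(normalize,
                 none = dist,
                 mn = dist / (M * N),
                 path_len = dist / length(res$ix))
  structure(
    list(distance = dist, ix = res$ix, iy = res$iy,
         path = cbind(m = res$ix, n = res$iy),
         band_halfwidth = band_halfwidth, mode = mode,
         normalize = normalize),
    class = "warp_result")
}

#' @export
print.warp_result <- function(x, ...) {
  cat(sprintf("<warp_result> distance %.6g (%s, band %s), path length %d\n",
              x$distance, x$mode,
              ifelse(is.infinite(x$band_halfwidth), "unbounded",
                     format(x$band_halfwidth)),
              length(x$ix)))
  invisible(x)
}

#' Exhaustive-path DTW oracle for short channels
#'
#' Recursively explores every monotone warp path from (1, 1) to (M, N)
#' with moves (+1, 0), (0, +1), (+1, +1) and returns the minimum
#' accumulated cost.  Exponential in the input length, hence restricted to
#' vectors of length at most 8; it exists as an independent correctness
#' oracle for [dtw_distance()].
#'
#' @param template_channel,sequence_channel Numeric vectors, length <= 8.
#' @return A `warp_result` with the minimizing path (same tie-break order
#'   as the dynamic programme: diagonal, vertical, horizontal).
#' @export
brute_force_dtw <- function(template_channel, sequence_channel) {
  M <- length(template_channel); N <- length(sequence_channel)
  if (M < 1L || N < 1L) stop("channels must be non-empty")
  if (M > 8L || N > 8L)
    stop("brute_force_dtw is restricted to lengths <= 8")
  d <- local_cost_matrix(template_channel, sequence_channel)
  # explore moves in tie-break preference order so that on equal cost the
  # first-found (diagonal-preferring) path is kept
  explore <- function(m, n) {
    if (m == M && n == N) return(list(cost = 0, path = list(c(m, n))))
    best <- NULL
    steps <- list(c(1L, 1L), c(1L, 0L), c(0L, 1L))
    for (s in steps) {
      mm <- m + s[1L]; nn <- n + s[2L]
      if (mm > M || nn > N) next
      sub <- explore(mm, nn)
      cost <- d[mm, nn] + sub$cost
      if (is.null(best) || cost < best$cost)
        best <- list(cost = cost, path = c(list(c(m, n)), sub$path))
    }
    best
  }
  res <- explore(1L, 1L)
  path <- do.call(rbind, res$path)
  structure(
    list(distance = d[1L, 1L] + res$cost,
         ix = path[, 1L], iy = path[, 2L],
         path = cbind(m = path[, 1L], n = path[, 2L]),
         band_halfwidth = Inf, mode = "brute_force", normalize = "none"),
    class = "warp_result")
}

#' Serialize and restore a warp result
#'
#' Plain-text (JSON) record of a [dtw_distance()] result — distance, band,
#' mode, normalization and the warp path as index pairs — for debugging
#' and for regenerating warp-path plots.  Round-trips exactly.
#'
#' @param x A `warp_result`.
#' @param path Output file path.
#' @return `write_warp_result` returns `path` invisibly;
#'   `read_warp_result` the restored `warp_result`.
#' @export
write_warp_result <- function(x, path) {
  stopifnot(inherits(x, "warp_result"))
  jsonlite::write_json(
    list(distance = x$distance,
         band_halfwidth = if (is.infinite(x$band_halfwidth)) "unbounded"
                          else x$band_halfwidth,
         mode = x$mode, normalize = x$normalize,
         ix = x$ix, iy = x$iy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_warp_result
#' @export
read_warp_result <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  band <- if (identical(j$band_halfwidth, "unbounded")) Inf
          else as.integer(j$band_halfwidth)
  structure(
    list(distance = j$distance, ix = as.integer(j$ix),
         iy = as.integer(j$iy),
         path = cbind(m = as.integer(j$ix), n = as.integer(j$iy)),
         band_halfwidth = band, mode = j$mode, normalize = j$normalize),
    class = "warp_result")
}

#' Maximum warping admitted by a band half-width
#'
#' The Sakoe-Chiba constraint \eqn{|m - n| \le r} limits how far a warp
#' path may deviate from the diagonal; expressed relative to the sequence
#' length this is a maximum warping of \eqn{100 r / N} percent.  At the
#' pipeline defaults (r = 50, N = 101) that is 49.5%.
#'
#' @param band_halfwidth Non-negative integer r.
#' @param seq_len Sequence length N >= 1.
#' @return Percentage, `100 * band_halfwidth / seq_len`.
#' @export
max_warp_fraction <- function(band_halfwidth, seq_len) {
  stopifnot(seq_len >= 1, band_halfwidth >= 0)
  100 * band_halfwidth / seq_len
}
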