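# Shared fixture builders.  Everything is generated in code; no stored
# binary data.

# A movement sequence from a single channel value pattern, all six
# channels identical unless `angles` is a full 6 x N matrix.
make_seq <- function(x, ..., label = NA_character_) {
  a <- if (is.matrix(x)) x else matrix(rep(x, each = 6), nrow = 6,
                                       byrow = FALSE)
  movement_sequence(a, label = label, ...)
}

# A normalized "sequence" with constant per-channel values, bypassing the
# resampling pipeline (constant channels are exempt from the [-1, 1] span
# rule), handy for closed-form DTW arithmetic.
flat_norm_seq <- function(values, label = NA_character_) {
  stopifnot(length(values) == 6L)
  movement_sequence(matrix(values, nrow = 6, ncol = 101),
                    label = label, time_normalized = TRUE,
                    scale_normalized = TRUE)
}

flat_template <- function(values, label, id = label) {
  as_template(flat_norm_seq(values, label = label), id = id)
}

# Tiny two-class library with well-separated sinusoid-vs-ramp shapes.
toy_library <- function(n_per_class = 3, jitter = 0.01, seed = 7) {
  set.seed(seed)
  u <- seq(0, 1, length.out = 101)
  mk <- function(shape, label, i) {
    base <- if (shape == "a") sin(2 * pi * u) else 2 * u - 1
    a <- matrix(rep(base, each = 6), nrow = 6) +
      matrix(rnorm(6 * 101, 0, jitter), nrow = 6)
    s <- scale_normalize(movement_sequence(a, label = label,
                                           time_normalized = TRUE))
    as_template(s, id = paste0(label, i))
  }
  tpl <- c(lapply(seq_len(n_per_class), function(i) mk("a", "DK", i)),
           lapply(seq_len(n_per_class), function(i) mk("b", "FS", i)))
  template_library(tpl)
}

# Small cached synthetic cohort shared across test files (built once per
# test run; modest sizes keep the suite quick).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(n_subjects = 4L, trials_per_class = 2L,
                                n_novel = 1L, master_seed = 11L)
    cache
  }
})
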