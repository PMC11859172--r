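#' Collapse raw recording codes into the canonical 12-class vocabulary
#'
#' Recordings distinguish single- and double-arm supported kneeling (SAK,
#' DAK) and side leaning (SL); for classification these collapse into
#' supported kneeling (SK) and side sitting (SS) because their lower-limb
#' kinematics are near-identical.  Canonical codes map to themselves, so
#' the map is a projection onto the 12 canonical classes.
#'
#' @param raw_label Character vector of raw motion codes.
#' @return Character vector of canonical class codes.
#' @export
relabel_class <- function(raw_label) {
  bad <- setdiff(raw_label, raw_motion_codes())
  if (length(bad))
    stop("unknown motion code(s): ", paste(unique(bad), collapse = ", "))
  map <- c(SAK = "SK", DAK = "SK", SL = "SS")
  out <- ifelse(raw_label %in% names(map), map[raw_label], raw_label)
  unname(out)
}

#' Linearly resample a trial to a fixed length
#'
#' Each channel is independently linearly interpolated onto a uniform grid
#' in normalized time \eqn{[0, 1]} spanning the original first and last
#' samples inclusively (101 points gives step 0.01).  Endpoints are
#' preserved exactly.
#'
#' @param seq A `movement_sequence` with N >= 2 samples.
#' @param target_len Output length (default 101; must be >= 2).
#' @return The resampled sequence; `time_normalized` is set when
#'   `target_len` is 101.
#' @export
resample_to_length <- function(seq, target_len = 101L) {
  validate_movement_sequence(seq)
  if (target_len < 2L) stop("target_len must be >= 2")
  n <- n_samples(seq)
  old <- seq(0, 1, length.out = n)
  new <- seq(0, 1, length.out = target_len)
  out <- t(apply(seq$angles, 1L, function(ch)
    stats::approx(old, ch, xout = new)$y))
  # guard against interpolation drift at the endpoints
  out[, 1L] <- seq$angles[, 1L]
  out[, target_len] <- seq$angles[, n]
  seq$angles <- out
  seq$time_normalized <- target_len == 101L
  # interpolation can miss the extrema, so an exact [-1, 1] span is no
  # longer guaranteed; re-normalize after resampling if needed
  seq$scale_normalized <- FALSE
  validate_movement_sequence(seq)
}

#' Scale-normalize a trial to \eqn{[-1, 1]}
#'
#' Maps each channel affinely, \eqn{x \mapsto 2(x - \min)/(\max - \min) - 1},
#' using extrema computed within the trial.  The default scope is
#' per-channel (each channel's own min/max), which preserves each joint's
#' discriminative shape regardless of its angular range; `"per_trial"`
#' instead uses the extrema across all six channels, preserving relative
#' amplitudes between joints.  Constant channels (no shape information)
#' map to all zeros, the midpoint of \eqn{[-1, 1]}.
#'
#' @param seq A `movement_sequence` with finite angles.
#' @param scope `"per_channel"` (default) or `"per_trial"`.
#' @return The normalized sequence with `scale_normalized` set.  The
#'   chosen scope is recorded in the `scale_scope` field.
#' @export
scale_normalize <- function(seq, scope = c("per_channel", "per_trial")) {
  scope <- match.arg(scope)
  validate_movement_sequence(seq)
  a <- seq$angles
  if (scope == "per_trial") {
    lo <- min(a); hi <- max(a)
    a <- if (hi > lo) 2 * (a - lo) / (hi - lo) - 1 else a * 0
  } else {
    for (ch in seq_len(nrow(a))) {
      lo <- min(a[ch, ]); hi <- max(a[ch, ])
      a[ch, ] <- if (hi > lo) 2 * (a[ch, ] - lo) / (hi - lo) - 1
                 else a[ch, ] * 0
    }
  }
  seq$angles <- a
  seq$scale_normalized <- TRUE
  seq$scale_scope <- scope
  if (scope == "per_channel") validate_movement_sequence(seq)
  seq
}

# Prominence of each peak index in `x`: height above the higher of the two
# minima separating it from the nearest higher terrain (or the signal edge).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p)]
    right <- x[p:length(x)]
    higher_l <- which(left > x[p])
    higher_r <- which(right > x[p])
    base_l <- if (length(higher_l)) min(x[max(higher_l):p]) else min(left)
    base_r <- if (length(higher_r))
      min(right[1:min(higher_r)]) else min(right)
    x[p] - max(base_l, base_r)
  }, numeric(1))
}

# Strict-ish local maxima (plateau midpoints count once).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

#' Split a walking trial into gait cycles
#'
#' Gait-cycle boundaries are the instants of maximum knee extension
#' (minimum knee flexion), which coincide with heel strike.  The detector
#' finds prominent flexion peaks (the swing-phase bumps) on the chosen
#' knee channel and places a boundary at the flexion minimum between
#' consecutive peaks, plus one before the first and after the last peak.
#' Peaks need a minimum prominence (default 5 degrees) and a minimum
#' separation (default 0.4 s at the trial's sample rate) to be counted.
#'
#' @param seq An unsegmented walking `movement_sequence`.
#' @param knee_channel `"r_knee"` (default) or `"l_knee"`.
#' @param min_prominence Minimum flexion-peak prominence in degrees.
#' @param min_separation Minimum peak separation in seconds.
#' @return A list of `movement_sequence` cycles (contiguous,
#'   non-overlapping), with attribute `"boundaries"` giving the boundary
#'   sample indices into the input.  Fewer than two boundaries yield an
#'   empty list with a warning.
#' @export
segment_gait_cycles <- function(seq, knee_channel = c("r_knee", "l_knee"),
                                min_prominence = 5,
                                min_separation = 0.4) {
  knee_channel <- match.arg(knee_channel)
  validate_movement_sequence(seq)
  x <- seq$angles[knee_channel, ]
  pk <- local_maxima(x)
  if (length(pk)) {
    pk <- pk[peak_prominence(x, pk) >= min_prominence]
  }
  # enforce minimum separation, keeping the higher peak
  min_gap <- ceiling(min_separation * seq$sample_rate)
  if (length(pk) > 1L) {
    keep <- pk[1L]
    for (p in pk[-1L]) {
      if (p - keep[length(keep)] < min_gap) {
        if (x[p] > x[keep[length(keep)]]) keep[length(keep)] <- p
      } else keep <- c(keep, p)
    }
    pk <- keep
  }
  if (length(pk) < 1L) {
    warning("no prominent knee-flexion peaks; cannot segment gait cycles")
    return(structure(list(), boundaries = integer(0)))
  }
  # boundaries: flexion minima between consecutive peaks and flanking them
  bounds <- integer(length(pk) + 1L)
  bounds[1L] <- which.min(x[1:pk[1L]])
  if (length(pk) > 1L) {
    for (i in seq_len(length(pk) - 1L)) {
      seg <- pk[i]:pk[i + 1L]
      bounds[i + 1L] <- seg[which.min(x[seg])]
    }
  }
  seg <- pk[length(pk)]:length(x)
  bounds[length(bounds)] <- seg[which.min(x[seg])]
  bounds <- unique(bounds)
  if (length(bounds) < 2L) {
    warning("fewer than 2 gait-cycle boundaries detected")
    return(structure(list(), boundaries = bounds))
  }
  cycles <- lapply(seq_len(length(bounds) - 1L), function(i) {
    s <- seq
    s$angles <- seq$angles[, bounds[i]:bounds[i + 1L], drop = FALSE]
    s$time_normalized <- FALSE
    validate_movement_sequence(s)
  })
  structure(cycles, boundaries = bounds)
}

#' Build a template from a segmented trial
#'
#' Applies the standard template pipeline: relabel to the canonical
#' vocabulary, linearly resample to 101 points, scale-normalize to
#' \eqn{[-1, 1]}, and stamp as a template.
#'
#' @param seq A labelled, segmented `movement_sequence`.
#' @param id Optional template id.
#' @param scope Scale-normalization scope, see [scale_normalize()].
#' @return A `template`.
#' @export
build_template <- function(seq, id = NULL,
                           scope = c("per_channel", "per_trial")) {
  scope <- match.arg(scope)
  seq$label <- relabel_class(seq$label)
  seq <- resample_to_length(seq, 101L)
  seq <- scale_normalize(seq, scope)
  as_template(seq, id = id)
}

#' Normalize an unsegmented movement sequence for classification
#'
#' Same time and scale normalization as [build_template()] but without
#' requiring a label, for query sequences.
#'
#' @inheritParams build_template
#' @return A normalized `movement_sequence`.
#' @export
normalize_sequence <- function(seq, scope = c("per_channel", "per_trial")) {
  scope <- match.arg(scope)
  if (!is.na(seq$label)) seq$label <- relabel_class(seq$label)
  scale_normalize(resample_to_length(seq, 101L), scope)
}
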