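#' Joint-angle channel names, in canonical order
#'
#' The six lower-limb flexion-extension channels used throughout the
#' package, in the fixed order (right knee, left knee, right ankle, left
#' ankle, right hip, left hip).  Every angle matrix, weight vector and
#' serialized trial uses this order; keeping it explicit prevents silent
#' left/right swaps.
#'
#' @return Character vector of length 6.
#' @export
mdtw_channels <- function() {
  c("r_knee", "l_knee", "r_ankle", "l_ankle", "r_hip", "l_hip")
}

#' Motion-class vocabularies
#'
#' `motion_classes()` returns the twelve canonical posture codes in their
#' canonical order: dorsiflexed kneeling (DK), plantarflexed kneeling (PK),
#' flatfoot squatting (FS), heels-up squatting (HS), child-chair sitting
#' (CCS), adult-chair sitting (ACS), supported kneeling (SK), stooping
#' (STP), standing (STD), crossed-leg sitting (CLS), side sitting (SS) and
#' walking (WLK).  `raw_motion_codes()` additionally includes the three
#' recording-time codes (SAK, DAK, SL) that are collapsed into the
#' canonical vocabulary by [relabel_class()].
#'
#' @return Character vector of class codes.
#' @export
motion_classes <- function() {
  c("DK", "PK", "FS", "HS", "CCS", "ACS", "SK", "STP", "STD", "CLS",
    "SS", "WLK")
}

#' @rdname motion_classes
#' @export
raw_motion_codes <- function() {
  c(motion_classes(), "SAK", "DAK", "SL")
}

#' Construct a movement sequence
#'
#' A movement sequence is one recorded (or synthesized) trial: a 6 x N
#' matrix of flexion-extension angles in degrees, rows ordered as
#' [mdtw_channels()], plus label and subject metadata and a pair of
#' normalization flags.  Templates (see [as_template()]) are movement
#' sequences that have been segmented, time-normalized to 101 samples and
#' scale-normalized to \eqn{[-1, 1]}.
#'
#' @param angles Numeric matrix, 6 rows (channels) by N >= 2 columns
#'   (samples); rownames, if present, must equal `mdtw_channels()`.
#' @param label Motion-class code, or `NA` for an unlabelled trial.
#' @param subject_id Opaque subject identifier string.
#' @param sample_rate Sampling rate in Hz (nominal 60).
#' @param time_normalized,scale_normalized Logical normalization flags;
#'   set by [resample_to_length()] and [scale_normalize()].
#' @param validate Check invariants (finite angles, channel count,
#'   normalization consistency)?
#' @return An object of class `movement_sequence`.
#' @export
movement_sequence <- function(angles, label = NA_character_,
                              subject_id = NA_character_,
                              sample_rate = 60,
                              time_normalized = FALSE,
                              scale_normalized = FALSE,
                              validate = TRUE) {
  angles <- as.matrix(angles)
  rownames(angles) <- mdtw_channels()
  x <- structure(
    list(angles = angles,
         label = as.character(label),
         subject_id = as.character(subject_id),
         sample_rate = sample_rate,
         time_normalized = isTRUE(time_normalized),
         scale_normalized = isTRUE(scale_normalized)),
    class = "movement_sequence")
  if (validate) validate_movement_sequence(x)
  x
}

#' Validate a movement sequence's invariants
#'
#' Checks: exactly six channels of equal length N >= 2, all values finite,
#' N = 101 when time-normalized, and every non-constant channel spanning
#' exactly \eqn{[-1, 1]} (tolerance 1e-9) when scale-normalized.
#'
#' @param x A `movement_sequence`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_movement_sequence <- function(x) {
  stopifnot(inherits(x, "movement_sequence"))
  a <- x$angles
  if (!is.matrix(a) || nrow(a) != 6L)
    stop("angles must be a 6-channel matrix (rows = ",
         paste(mdtw_channels(), collapse = ", "), ")")
  if (ncol(a) < 2L)
    stop("a movement sequence needs at least 2 samples, got ", ncol(a))
  if (!all(is.finite(a)))
    stop("angles contain non-finite values")
  if (x$time_normalized && ncol(a) != 101L)
    stop("time-normalized sequences must have 101 samples, got ", ncol(a))
  if (x$scale_normalized &&
      (is.null(x$scale_scope) || x$scale_scope == "per_channel")) {
    for (ch in seq_len(6L)) {
      v <- a[ch, ]
      if (diff(range(v)) > 0 &&
          (abs(min(v) + 1) > 1e-9 || abs(max(v) - 1) > 1e-9))
        stop("scale-normalized channel ", mdtw_channels()[ch],
             " does not span [-1, 1]")
    }
  }
  if (!is.na(x$label) && !(x$label %in% raw_motion_codes()))
    stop("unknown motion class '", x$label, "'")
  invisible(x)
}

#' @export
print.movement_sequence <- function(x, ...) {
  cat(sprintf(
    "<movement_sequence> %s, subject %s: 6 x %d @ %g Hz%s%s\n",
    ifelse(is.na(x$label), "(unlabelled)", x$label),
    ifelse(is.na(x$subject_id), "?", x$subject_id),
    ncol(x$angles), x$sample_rate,
    if (x$time_normalized) ", time-normalized" else "",
    if (x$scale_normalized) ", scale-normalized" else ""))
  invisible(x)
}

#' Number of samples in a movement sequence
#' @param x A `movement_sequence`.
#' @return Integer N.
#' @export
n_samples <- function(x) ncol(x$angles)

#' Mark a fully normalized, labelled sequence as a template
#'
#' A template is a segmented exemplar trial: 101 samples, scale-normalized,
#' with a mandatory canonical class label.  It populates the labelled
#' feature space of the nearest-neighbour classifier.
#'
#' @param x A `movement_sequence` with both normalization flags set and a
#'   canonical label.
#' @param id Optional template identifier (defaults to label/subject).
#' @return The sequence with class `template` prepended and an `id` field.
#' @export
as_template <- function(x, id = NULL) {
  validate_movement_sequence(x)
  if (is.na(x$label) || !(x$label %in% motion_classes()))
    stop("a template needs one of the 12 canonical class labels")
  if (!x$time_normalized || n_samples(x) != 101L)
    stop("a template must be time-normalized to 101 samples")
  if (!x$scale_normalized)
    stop("a template must be scale-normalized to [-1, 1]")
  x$id <- if (is.null(id)) paste(x$label, x$subject_id, sep = "_") else id
  class(x) <- c("template", class(x))
  x
}

#' Assemble templates into a library
#'
#' The template library is the classifier's labelled feature space.  Its
#' ordering is stable and serialized, so classification ties resolve
#' deterministically across runs.
#'
#' @param templates List of `template` objects.
#' @param provenance Optional list of split/seed metadata carried along.
#' @return An object of class `template_library`.
#' @export
template_library <- function(templates, provenance = list()) {
  if (length(templates) == 0L) stop("template library cannot be empty")
  ok <- vapply(templates, inherits, logical(1), what = "template")
  if (!all(ok)) stop("all elements must be templates (see as_template)")
  ids <- vapply(templates, function(t) t$id, character(1))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "#")
    for (i in seq_along(templates)) templates[[i]]$id <- ids[i]
  }
  structure(
    list(templates = templates,
         ids = ids,
         labels = vapply(templates, function(t) t$label, character(1)),
         provenance = provenance),
    class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d templates, %d classes\n",
              length(x$templates), length(unique(x$labels))))
  print(class_counts(x))
  invisible(x)
}

#' @export
length.template_library <- function(x) length(x$templates)

#' Per-class template counts of a library
#' @param lib A `template_library`.
#' @return Named integer vector over the classes present.
#' @export
class_counts <- function(lib) {
  table(factor(lib$labels, levels = motion_classes()))
}

#' Subset a template library by position
#' @param lib A `template_library`.
#' @param idx Integer or logical index into the library order.
#' @return A `template_library` preserving relative order and provenance.
#' @export
subset_library <- function(lib, idx) {
  template_library(lib$templates[idx], provenance = lib$provenance)
}
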