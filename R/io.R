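trial_columns <- function() c("time_s", mdtw_channels())

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Read and write trial files
#'
#' A trial is a comma-separated text file with header columns `time_s,
#' r_knee, l_knee, r_ankle, l_ankle, r_hip, l_hip` (angles in degrees at
#' full precision) plus a JSON sidecar (`<name>.json`) carrying
#' `subject_id`, the raw motion `label`, `sample_rate` and the
#' normalization flags.  The round-trip is lossless; readers validate
#' column presence and finiteness and name the offending row/column on
#' failure.
#'
#' @param path Trial CSV path (sidecar derived from it).
#' @param seq A `movement_sequence` (for `write_trial`).
#' @return `read_trial` returns a `movement_sequence`; `write_trial`
#'   returns `path` invisibly.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(trial_columns(), names(df))
  if (length(miss))
    stop("trial file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in trial_columns()) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || !all(is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric or non-finite value in ", path, ", column '",
           col, "', row ", bad)
    }
  }
  if (nrow(df) < 2L)
    stop("trial ", path, " has fewer than 2 samples")
  meta <- list(subject_id = NA_character_, label = NA_character_,
               sample_rate = 60, time_normalized = FALSE,
               scale_normalized = FALSE)
  sc <- sidecar_path(path)
  if (file.exists(sc))
    meta <- utils::modifyList(meta, jsonlite::read_json(sc,
                                                        simplifyVector = TRUE))
  movement_sequence(t(as.matrix(df[mdtw_channels()])),
                    label = meta$label, subject_id = meta$subject_id,
                    sample_rate = meta$sample_rate,
                    time_normalized = isTRUE(meta$time_normalized),
                    scale_normalized = isTRUE(meta$scale_normalized))
}

#' @rdname read_trial
#' @export
write_trial <- function(seq, path) {
  validate_movement_sequence(seq)
  n <- n_samples(seq)
  df <- data.frame(time_s = seq(0, by = 1 / seq$sample_rate,
                                length.out = n))
  for (ch in mdtw_channels()) df[[ch]] <- seq$angles[ch, ]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(subject_id = seq$subject_id, label = seq$label,
         sample_rate = seq$sample_rate,
         time_normalized = seq$time_normalized,
         scale_normalized = seq$scale_normalized),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

library_format_version <- "1.0"

#' Persist and restore a template library
#'
#' A library directory holds one CSV per template plus `manifest.json`
#' recording the format version, normalization settings and the ordered
#' template entries (id, class label, subject, file, optional split
#' assignment).  Order, labels and settings round-trip exactly, so
#' classification results are identical before and after a save/load.
#'
#' @param lib A `template_library`.
#' @param dir Library directory.
#' @return `save_library` returns `dir` invisibly; `load_library` the
#'   restored `template_library`.
#' @export
save_library <- function(lib, dir) {
  stopifnot(inherits(lib, "template_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(lib$templates), function(i) {
    t <- lib$templates[[i]]
    file <- sprintf("template_%04d.csv", i)
    write_trial(t, file.path(dir, file))
    list(id = t$id, label = t$label, subject_id = t$subject_id,
         file = file)
  })
  jsonlite::write_json(
    list(format_version = library_format_version,
         n_templates = length(lib$templates),
         provenance = lib$provenance,
         entries = entries),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' @rdname save_library
#' @export
load_library <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mf, simplifyVector = FALSE)
  major <- sub("\\..*$", "", as.character(man$format_version))
  if (!identical(major, sub("\\..*$", "", library_format_version)))
    stop("unsupported library format version ", man$format_version)
  missing <- Filter(function(e)
    !file.exists(file.path(dir, e$file)), man$entries)
  if (length(missing))
    stop("manifest references missing template file(s): ",
         paste(vapply(missing, `[[`, character(1), "id"),
               collapse = ", "))
  templates <- lapply(man$entries, function(e) {
    if (!(e$label %in% motion_classes()))
      stop("unknown class code '", e$label, "' in manifest")
    s <- read_trial(file.path(dir, e$file))
    s$label <- e$label
    s$subject_id <- e$subject_id
    as_template(s, id = e$id)
  })
  prov <- if (is.null(man$provenance)) list()
          else jsonlite::read_json(mf, simplifyVector = TRUE)$provenance
  template_library(templates, provenance = prov)
}

#' Default run configuration
#'
#' The published operating point of the classifier: band half-width 50,
#' k = 1, the tuned channel weights, the optimal-path DTW rule,
#' per-channel scale normalization and no path-sum normalization.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(band_halfwidth = 50L, k = 1L, weights = weights_tuned(),
       mode = "optimal", scale_scope = "per_channel",
       dtw_normalize = "none", seed = 1L)
}

#' Read a run configuration file
#'
#' Plain-text YAML key/value document; keys absent from the file keep
#' their [default_config()] values.  `weights` may be `"tuned"`,
#' `"initial"`, or a map of the six channel names to numbers.
#'
#' @param path Config file path.
#' @return Configuration list as [default_config()].
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  y <- yaml::read_yaml(path)
  if (!is.null(y$weights)) y$weights <- resolve_weights(y$weights)
  utils::modifyList(cfg, y)
}

resolve_weights <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    if (spec == "tuned") return(weights_tuned())
    if (spec == "initial") return(weights_initial())
    if (file.exists(spec)) {
      y <- yaml::read_yaml(spec)
      return(do.call(weight_vector, as.list(y)[
        c("l_ankle", "r_ankle", "l_knee", "r_knee", "l_hip", "r_hip")]))
    }
    stop("unknown weights spec '", spec, "'")
  }
  do.call(weight_vector, as.list(spec)[
    c("l_ankle", "r_ankle", "l_knee", "r_knee", "l_hip", "r_hip")])
}

#' Published reference performance tables
#'
#' Row-percentage sensitivity confusion matrices, per-class specificities
#' and balanced accuracies, and grouped-posture metrics as published for
#' the original twelve-posture study of this classifier (its recordings
#' are available on request only, so these printed tables are the
#' reproducible arithmetic reference).  Shipped as plain-text CSVs under
#' `inst/extdata`.
#'
#' @return A list of data frames: `sensitivity` (model, target, output,
#'   percent), `specificity` (model, class, specificity),
#'   `balanced_accuracy` (model, class, balanced_accuracy), `grouped`
#'   (group, sensitivity, specificity, balanced_accuracy).  `model` is
#'   one of `cv` (five-fold cross-validated), `test_segmented`,
#'   `test_sequences`, `validation` (novel participants).
#' @export
reference_metrics <- function() {
  rd <- function(f)
    utils::read.csv(system.file("extdata", f, package = "mdtwposture"),
                    check.names = FALSE)
  list(sensitivity = rd("reference_sensitivity.csv"),
       specificity = rd("reference_specificity.csv"),
       balanced_accuracy = rd("reference_balanced_accuracy.csv"),
       grouped = rd("reference_grouped.csv"))
}
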