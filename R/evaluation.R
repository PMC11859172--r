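#' Confusion matrix of true versus predicted classes
#'
#' Rows are target (true) classes, columns output (predicted) classes, in
#' a fixed class order; entry (i, j) counts items of class i predicted as
#' class j.
#'
#' @param true_labels,predicted_labels Equal-length character vectors of
#'   class codes.
#' @param class_order Class vocabulary and display order (default the
#'   canonical twelve).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             class_order = motion_classes()) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  bad <- setdiff(c(true_labels, predicted_labels), class_order)
  if (length(bad))
    stop("label(s) outside the class vocabulary: ",
         paste(unique(bad), collapse = ", "))
  m <- table(factor(true_labels, levels = class_order),
             factor(predicted_labels, levels = class_order))
  structure(unclass(m), class = "confusion_matrix",
            dimnames = list(target = class_order, output = class_order))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = target, cols = output)\n")
  print(unclass(x))
  invisible(x)
}

ovr_counts <- function(cm, class_id) {
  i <- match(class_id, rownames(cm))
  if (is.na(i)) stop("class ", class_id, " not in matrix")
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Per-class sensitivity, specificity and balanced accuracy
#'
#' One-vs-rest reduction of the confusion matrix: sensitivity (recall) is
#' \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)}, balanced accuracy
#' their mean — all in percent.  A zero denominator (a class with no
#' instances, or one covering every instance) leaves the affected metric
#' `NA` ("absent") rather than 0 or 100.
#'
#' @param cm A `confusion_matrix`.
#' @param class_id Class code present in the matrix.
#' @return Named numeric vector `(sensitivity, specificity,
#'   balanced_accuracy)` in percent.
#' @export
class_metrics <- function(cm, class_id) {
  if (sum(cm) == 0L) stop("empty confusion matrix")
  n <- ovr_counts(cm, class_id)
  sens <- if ((n["TP"] + n["FN"]) > 0)
    100 * n[["TP"]] / (n[["TP"]] + n[["FN"]]) else NA_real_
  spec <- if ((n["TN"] + n["FP"]) > 0)
    100 * n[["TN"]] / (n[["TN"]] + n[["FP"]]) else NA_real_
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = mean(c(sens, spec)))
}

#' Balanced accuracy from a sensitivity/specificity pair
#'
#' \eqn{(\mathrm{sensitivity} + \mathrm{specificity}) / 2}, the summary
#' used to correct per-class accuracy for unequal class sizes.
#'
#' @param sensitivity,specificity Percentages.
#' @return Percentage.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Overall classification accuracy
#'
#' The ratio of correct classifications (the trace) to the total number
#' of classifications, in percent.
#'
#' @param cm A `confusion_matrix`.
#' @return Percentage.
#' @export
overall_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0L) stop("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' Row-normalized percentage view of a confusion matrix
#'
#' Each row is expressed as percentages of its total; `display = TRUE`
#' rounds half-up to one decimal for table rendering while the raw ratios
#' stay available with `display = FALSE`.  Rows with no items are
#' reported as `NA` (absent), not as zeros.
#'
#' @param cm A `confusion_matrix`.
#' @param display Round half-up to one decimal?
#' @return Numeric matrix of percentages.
#' @export
row_percentages <- function(cm, display = TRUE) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1L, rs, "/") * 100
  out[rs == 0L, ] <- NA_real_
  if (display) out <- round_half_up(out, 1L)
  out
}

#' Default posture grouping by movement similarity
#'
#' Kneeling variants (DK, PK, SK), squatting variants (FS, HS), chair
#' sitting (ACS, CCS) and floor sitting (CLS, SS) merge; stooping,
#' standing and walking stay singleton.
#'
#' @return Named character vector mapping class code to group name.
#' @export
default_grouping <- function() {
  c(DK = "Kneeling", PK = "Kneeling", SK = "Kneeling",
    FS = "Squatting", HS = "Squatting",
    ACS = "Chair Sitting", CCS = "Chair Sitting",
    CLS = "Floor Sitting", SS = "Floor Sitting",
    STP = "Stooping", STD = "Standing", WLK = "WLK")
}

#' Merge confusion-matrix classes into groups
#'
#' Rows and columns are summed within groups, so within-group confusions
#' become correct predictions; the grand total is conserved and the
#' diagonal sum can only grow.
#'
#' @param cm A `confusion_matrix`.
#' @param grouping Named character vector, class code -> group name; must
#'   cover every class in the matrix.
#' @return A grouped `confusion_matrix` (group order: first appearance in
#'   `grouping` restricted to the matrix's class order).
#' @export
group_classes <- function(cm, grouping = default_grouping()) {
  classes <- rownames(cm)
  miss <- setdiff(classes, names(grouping))
  if (length(miss))
    stop("grouping is missing class(es): ", paste(miss, collapse = ", "))
  g <- grouping[classes]
  groups <- unique(unname(g))
  out <- matrix(0L, length(groups), length(groups),
                dimnames = list(target = groups, output = groups))
  for (i in classes) for (j in classes)
    out[g[[i]], g[[j]]] <- out[g[[i]], g[[j]]] + cm[i, j]
  structure(out, class = "confusion_matrix")
}

#' Full metrics report for a confusion matrix
#'
#' Per-class sensitivity, specificity and balanced accuracy plus the
#' overall accuracy and the mean and sample (n-1) standard deviation of
#' the per-class sensitivities and specificities.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report`: list with `per_class` (data frame),
#'   `overall_accuracy`, `sensitivity_mean`/`_sd`,
#'   `specificity_mean`/`_sd` (all percent).
#' @export
metrics_report <- function(cm) {
  per <- t(vapply(rownames(cm), function(cl) class_metrics(cm, cl),
                  numeric(3)))
  df <- data.frame(class = rownames(cm), per, row.names = NULL)
  structure(
    list(per_class = df,
         overall_accuracy = overall_accuracy(cm),
         sensitivity_mean = mean(df$sensitivity, na.rm = TRUE),
         sensitivity_sd = stats::sd(df$sensitivity, na.rm = TRUE),
         specificity_mean = mean(df$specificity, na.rm = TRUE),
         specificity_sd = stats::sd(df$specificity, na.rm = TRUE)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> overall accuracy %.1f%%\n",
              x$overall_accuracy))
  df <- x$per_class
  df[-1L] <- lapply(df[-1L], round_half_up, digits = 1L)
  print(df, row.names = FALSE)
  cat(sprintf("mean sensitivity %.1f%% +/- %.1f, mean specificity %.1f%% +/- %.1f\n",
              x$sensitivity_mean, x$sensitivity_sd,
              x$specificity_mean, x$specificity_sd))
  invisible(x)
}

#' Mean and standard deviation of a per-class metric
#'
#' Arithmetic mean and sample (n-1) standard deviation of per-class
#' values, optionally excluding classes (e.g. walking when summarizing
#' the remaining eleven postures).
#'
#' @param values Named numeric vector of per-class percentages.
#' @param exclude Class codes to drop.
#' @return Named vector `(mean, sd)`.
#' @export
metric_summary <- function(values, exclude = character(0)) {
  keep <- setdiff(names(values), exclude)
  if (!length(keep)) stop("all classes excluded")
  v <- values[keep]
  c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
}
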