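# Sample-tick confusion matrices and precision/recall/accuracy for
# behavioral classifier evaluation.

#' Construct a confusion matrix object
#'
#' Rows are predicted classes, columns are ground-truth classes; cells
#' count sample ticks (one tick per logged data point).
#'
#' @param counts Square non-negative numeric matrix.
#' @param classes Class names (defaults to the matrix dimnames).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, classes = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0),
            !is.null(classes), length(classes) == nrow(counts))
  dimnames(counts) <- list(predicted = classes, truth = classes)
  structure(list(classes = classes, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: %d classes, %s ticks>\n",
              length(x$classes), format(sum(x$counts), big.mark = ",")))
  print(x$counts)
  invisible(x)
}

# Internal: class at given times from an interval table; NA outside any
# interval (gaps count as unlabeled).
interval_class_at <- function(intervals, times) {
  idx <- findInterval(times, intervals$t_start)
  cls <- rep(NA_character_, length(times))
  ok <- idx >= 1L
  ok[ok] <- times[ok] < intervals$t_end[idx[ok]]
  cls[ok] <- intervals$behavior[idx[ok]]
  cls
}

#' Confusion matrix from predicted events and ground-truth labels
#'
#' Evaluates on an event-by-event basis, i.e. per sample tick at rate
#' `fs`: every tick of the common time span increments the cell
#' `(predicted class, truth class)`. Ticks where the ground truth is
#' unlabeled (gaps between marked epochs) are excluded; evaluation
#' covers marked epochs only.
#'
#' @param pred_events Data frame of predicted events (`behavior`,
#'   `t_start`, `t_end`).
#' @param truth_labels Data frame of ground-truth labels, same columns.
#' @param fs Sampling rate, Hz (ticks of `1/fs` seconds).
#' @return A [confusion_matrix()].
#' @export
confusion_from_streams <- function(pred_events, truth_labels, fs) {
  lo <- max(min(pred_events$t_start), min(truth_labels$t_start))
  hi <- min(max(pred_events$t_end), max(truth_labels$t_end))
  if (hi <= lo) stop("prediction and truth streams do not overlap in time")
  dt <- 1 / fs
  n <- floor((hi - lo) * fs + 1e-9)
  ticks <- lo + (seq_len(n) - 0.5) * dt  # tick midpoints
  pred <- interval_class_at(pred_events, ticks)
  truth <- interval_class_at(truth_labels, ticks)
  keep <- !is.na(truth) & !is.na(pred)
  classes <- canonical_class_order(unique(c(pred[keep], truth[keep])))
  counts <- table(factor(pred[keep], levels = classes),
                  factor(truth[keep], levels = classes))
  confusion_matrix(unclass(counts) * 1, classes)
}

#' Precision, recall and overall accuracy of a confusion matrix
#'
#' Per class: precision is the diagonal cell over the row (predicted)
#' total, recall the diagonal cell over the column (truth) total;
#' overall accuracy is the trace over the grand total. Ratios with a
#' zero denominator are reported as `NA`.
#'
#' @param matrix A [confusion_matrix()].
#' @return List with named vectors `precision` and `recall`
#'   (fractions in `[0, 1]`), scalar `accuracy`, and `n` (total ticks).
#' @export
precision_recall_accuracy <- function(matrix) {
  cm <- matrix$counts
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  d <- diag(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  precision <- ifelse(rs > 0, d / rs, NA_real_)
  recall <- ifelse(cs > 0, d / cs, NA_real_)
  list(precision = stats::setNames(precision, matrix$classes),
       recall = stats::setNames(recall, matrix$classes),
       accuracy = sum(d) / total, n = total)
}

#' Collapse subclass rows/columns into their parent classes
#'
#' Sums `Root` into `Forage`, `Trot` into `Run` and `Vigilance` into
#' `Stand` along both dimensions. Totals are conserved. A matrix with
#' no subclasses is returned unchanged.
#'
#' @param matrix A [confusion_matrix()].
#' @return A [confusion_matrix()] over the collapsed classes.
#' @export
collapse_subclasses <- function(matrix) {
  parents <- collapse_classes(matrix$classes)
  if (identical(parents, matrix$classes)) return(matrix)
  out_classes <- canonical_class_order(unique(parents))
  agg <- base::matrix(0, length(out_classes), length(out_classes),
                      dimnames = list(out_classes, out_classes))
  for (i in seq_along(matrix$classes)) {
    for (j in seq_along(matrix$classes)) {
      agg[parents[i], parents[j]] <- agg[parents[i], parents[j]] +
        matrix$counts[i, j]
    }
  }
  confusion_matrix(agg, out_classes)
}

#' Round half-up to a number of decimals
#'
#' Report-style rounding (0.05 rounds to 0.1), matching how percentage
#' tables are conventionally printed; R's `round()` rounds half to
#' even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluation report for predicted events against ground truth
#'
#' @param pred_events,truth_labels Interval data frames as in
#'   [confusion_from_streams()].
#' @param fs Sampling rate, Hz.
#' @return List with the confusion `counts`, per-class `precision_pct`
#'   and `recall_pct` (one-decimal percent), and `accuracy_pct`.
#' @export
evaluate_events <- function(pred_events, truth_labels, fs) {
  cm <- confusion_from_streams(pred_events, truth_labels, fs)
  m <- precision_recall_accuracy(cm)
  list(counts = cm$counts,
       precision_pct = round_half_up(100 * m$precision, 1),
       recall_pct = round_half_up(100 * m$recall, 1),
       accuracy_pct = round_half_up(100 * m$accuracy, 1),
       n = m$n)
}

#' Published confusion-matrix counts bundled with the package
#'
#' Sample-tick confusion counts from the wild-boar collar validation
#' study this pipeline re-implements, bundled as plain-text tables so
#' the metric arithmetic can be verified against the printed results.
#' `"core"` is the 6-class matrix, `"expanded"` the 9-class matrix
#' including the Root/Trot/Vigilance subclasses.
#'
#' @param which `"core"` or `"expanded"`.
#' @return A [confusion_matrix()].
#' @export
reference_confusion <- function(which = c("core", "expanded")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("boar_confusion_", which, ".csv"),
                      package = "boarlogger", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  confusion_matrix(as.matrix(df), rownames(df))
}

#' Published class summaries bundled with the package
#'
#' Per-class durations and window/epoch counts of the training and
#' testing ethograms from the same study, for window-arithmetic checks.
#' Subclass rows carry their parent in `parent` and are nested within
#' (already included in) the parent rows' totals.
#'
#' @param which `"training"` (columns `class`, `parent`, `duration_s`,
#'   `observations`, `percent`) or `"testing"` (columns `class`,
#'   `parent`, `duration_s`, `epochs`).
#' @return Data frame.
#' @export
reference_class_summary <- function(which = c("training", "testing")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("boar_", which, "_summary.csv"),
                      package = "boarlogger", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
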