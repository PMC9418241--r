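#' Confusion matrix
#'
#' Counts of actual class (rows) against predicted class (columns) over
#' the full class alphabet.
#'
#' @param y_true,y_pred Label vectors of equal length; every label must
#'   appear in `class_names`.
#' @param class_names Ordered class alphabet.
#' @return Integer matrix, `C x C`, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length.", call. = FALSE)
  }
  unknown <- setdiff(unique(c(y_true, y_pred)), class_names)
  if (length(unknown)) {
    stop("Label(s) outside the class alphabet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- table(factor(y_true, levels = class_names),
             factor(y_pred, levels = class_names))
  matrix(as.integer(m), nrow = length(class_names),
         dimnames = list(actual = class_names, predicted = class_names))
}

#' One-vs-rest precision, recall and F1 per class
#'
#' From a confusion matrix: precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, F1 the harmonic mean `2PR / (P + R)`. A zero
#' denominator yields 0 with `zero_denominator = TRUE` so the table stays
#' total.
#'
#' @param confusion A square count matrix (rows actual, columns predicted).
#' @return A tibble: `class`, `precision`, `recall`, `f1`,
#'   `zero_denominator`.
#' @export
precision_recall_f1 <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  zero_p <- (tp + fp) == 0
  zero_r <- (tp + fn) == 0
  precision <- ifelse(zero_p, 0, tp / (tp + fp))
  recall <- ifelse(zero_r, 0, tp / (tp + fn))
  zero_f <- (precision + recall) == 0
  f1 <- ifelse(zero_f, 0, 2 * precision * recall / (precision + recall))
  tibble::tibble(class = rownames(confusion) %||% as.character(seq_along(tp)),
                 precision = unname(precision), recall = unname(recall),
                 f1 = unname(f1),
                 zero_denominator = unname(zero_p | zero_r))
}

#' Overall classification accuracy
#'
#' Number of correct predictions over the total number of predictions.
#'
#' @param y_true,y_pred Label vectors of equal, non-zero length.
#' @return Fraction in [0, 1].
#' @export
overall_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("Empty input.", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length.", call. = FALSE)
  }
  mean(as.character(y_true) == as.character(y_pred))
}

#' Assemble a classification report
#'
#' Bundles the confusion matrix, per-class one-vs-rest metrics and the
#' overall accuracy, with the retained fraction recorded so that metrics
#' computed after uncertainty filtering always show the accuracy/coverage
#' trade-off.
#'
#' @param y_true,y_pred Label vectors (after any filtering).
#' @param class_names Ordered class alphabet.
#' @param retained_fraction Fraction of the original samples these metrics
#'   cover (1 when unfiltered).
#' @param provenance Optional named list (seeds, config digest) echoed
#'   into the report.
#' @return A list of class `classification_report`.
#' @export
classification_report <- function(y_true, y_pred, class_names,
                                  retained_fraction = 1,
                                  provenance = list()) {
  conf <- confusion_matrix(y_true, y_pred, class_names)
  structure(
    list(confusion = conf,
         per_class = precision_recall_f1(conf),
         overall_accuracy = overall_accuracy(y_true, y_pred),
         retained_fraction = retained_fraction,
         n = length(y_true),
         provenance = provenance),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> n = ", x$n, ", accuracy = ",
      format(x$overall_accuracy, digits = 4), ", retained fraction = ",
      format(x$retained_fraction, digits = 4), "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(n = x$n,
                 overall_accuracy = x$overall_accuracy,
                 retained_fraction = x$retained_fraction,
                 macro_f1 = mean(x$per_class$f1))
}

#' Write a classification report to disk
#'
#' Confusion matrix and per-class metrics as TSV, summary (accuracy,
#' retained fraction, provenance) as JSON.
#'
#' @param report A [classification_report()].
#' @param dir Output directory.
#' @param prefix File-name prefix (e.g. `"uncorrected"`).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf <- tibble::as_tibble(report$confusion, rownames = "actual")
  readr::write_tsv(conf, file.path(dir, paste0(prefix, "_confusion.tsv")),
                   progress = FALSE)
  readr::write_tsv(report$per_class,
                   file.path(dir, paste0(prefix, "_per_class.tsv")),
                   progress = FALSE)
  jsonlite::write_json(
    list(overall_accuracy = report$overall_accuracy,
         retained_fraction = report$retained_fraction,
         n = report$n, provenance = report$provenance),
    file.path(dir, paste0(prefix, "_summary.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
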