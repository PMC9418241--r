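#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_histogram geom_text scale_fill_gradient labs theme_minimal
NULL

#' @export
autoplot.accuracy_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$n_genes, y = .data$accuracy)) +
    geom_line() +
    geom_point() +
    labs(x = "number of genes", y = "cross-validated accuracy") +
    theme_minimal()
}

#' @export
autoplot.feature_selection_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$n_genes, y = .data$accuracy,
                 colour = factor(.data$step))) +
    geom_line() +
    geom_point() +
    labs(x = "number of genes", y = "cross-validated accuracy",
         colour = "selection step") +
    theme_minimal()
}

#' @export
autoplot.bnn_model <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "epoch-mean variational loss") +
    theme_minimal()
}

#' @export
autoplot.uncertainty_estimate <- function(object, bins = 30, ...) {
  ggplot(object$samples, aes(x = .data$xi)) +
    geom_histogram(bins = bins) +
    labs(x = "epistemic uncertainty (predicted-class variance)",
         y = "samples") +
    theme_minimal()
}

#' @export
autoplot.classification_report <- function(object, ...) {
  df <- tibble::as_tibble(object$confusion, rownames = "actual")
  df <- tidyr::pivot_longer(df, -"actual", names_to = "predicted",
                            values_to = "count")
  df$actual <- factor(df$actual, levels = rev(rownames(object$confusion)))
  df$predicted <- factor(df$predicted, levels = colnames(object$confusion))
  ggplot(df, aes(x = .data$predicted, y = .data$actual,
                 fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted class", y = "actual class", fill = "count") +
    theme_minimal()
}

#' Compare uncertainty of correct and incorrect predictions
#'
#' Histograms of the scalar epistemic uncertainty split by whether the
#' prediction matched the true label — incorrect calls typically sit in
#' the high-uncertainty tail, the pattern that motivates filtering and
#' correction.
#'
#' @param est An [epistemic_scalar()] result.
#' @param y_true True labels for the same samples.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_uncertainty_by_correctness <- function(est, y_true, bins = 30) {
  stopifnot(inherits(est, "uncertainty_estimate"))
  df <- dplyr::mutate(
    est$samples,
    outcome = ifelse(.data$predicted_class == as.character(y_true),
                     "correct", "incorrect"))
  ggplot(df, aes(x = .data$xi, fill = .data$outcome)) +
    geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    labs(x = "epistemic uncertainty (predicted-class variance)",
         y = "samples", fill = NULL) +
    theme_minimal()
}
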