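#' Rank genes by absolute PCA loading
#'
#' Runs principal components analysis on the gene-wise centered (not
#' variance-scaled) expression matrix and, for each of the first
#' `n_components` components, takes the `genes_per_component` genes with
#' the largest absolute loading. The result is the deduplicated union,
#' ordered by (component index, |loading| descending); a gene appearing
#' under several components is kept at its first (lowest-index) component.
#'
#' @param x Numeric matrix, samples x genes.
#' @param n_components Number of leading components to scan (<=
#'   `min(n_samples, n_genes)`); up to 10 by default.
#' @param genes_per_component Genes taken per component.
#' @return Ordered character vector of gene ids, length at most
#'   `n_components * genes_per_component`.
#' @export
pca_top_loading_genes <- function(x, n_components = 10L,
                                  genes_per_component = 10L) {
  validate_expression_matrix(x)
  n_components <- as.integer(n_components)
  genes_per_component <- as.integer(genes_per_component)
  if (n_components < 1 || genes_per_component < 1) {
    stop("`n_components` and `genes_per_component` must be >= 1.",
         call. = FALSE)
  }
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  if (n_components < 1) stop("Not enough samples for PCA.", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  genes <- character(0)
  for (k in seq_len(n_components)) {
    load_k <- abs(pc$rotation[, k])
    top <- names(sort(load_k, decreasing = TRUE))[
      seq_len(min(genes_per_component, length(load_k)))]
    genes <- c(genes, setdiff(top, genes))
  }
  genes
}

# Total ordering of all genes for the accuracy trace: by the largest
# absolute loading each gene attains across the first n_components
# principal components. Unlike the per-component quota union above, this
# never lets one dominant component crowd the others out of the ranking.
pca_loading_ranking <- function(x, n_components = 10L) {
  n_components <- min(as.integer(n_components), nrow(x) - 1L, ncol(x))
  if (n_components < 1) stop("Not enough samples for PCA.", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  best <- apply(abs(pc$rotation), 1, max)
  names(sort(best, decreasing = TRUE))
}

#' Cross-validated accuracy over a grid of gene counts
#'
#' For each count `m` in the grid, fits an L2-regularized multinomial
#' logistic-regression classifier on the first `m` genes of the ranking
#' under stratified k-fold cross-validation and records the mean held-out
#' accuracy.
#'
#' @param dataset A [labeled_dataset()].
#' @param gene_ranking Ordered character vector of gene ids.
#' @param counts_grid Increasing integer vector of gene counts, each `<=
#'   length(gene_ranking)`.
#' @param k Number of CV folds.
#' @param seed Integer seed (drives the fold assignment).
#' @param l2_strength Ridge penalty passed to the classifier.
#' @return A tibble of class `accuracy_trace`: `n_genes`, `accuracy`.
#' @export
cv_accuracy_for_gene_counts <- function(dataset, gene_ranking, counts_grid,
                                        k = 5L, seed = 1L,
                                        l2_strength = 1e-4) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  counts_grid <- sort(unique(as.integer(counts_grid)))
  if (length(counts_grid) == 0) stop("Empty `counts_grid`.", call. = FALSE)
  if (any(counts_grid < 1) || any(counts_grid > length(gene_ranking))) {
    stop("`counts_grid` values must lie in [1, length(gene_ranking)].",
         call. = FALSE)
  }
  folds <- kfold_indices(dataset, k = k, seed = seed)
  acc <- vapply(counts_grid, function(m) {
    genes <- gene_ranking[seq_len(m)]
    correct <- 0L
    for (fold in folds) {
      train <- subset_samples(dataset, setdiff(seq_len(n_samples(dataset)),
                                               fold))
      test <- subset_samples(dataset, fold)
      xtr <- train$x[, genes, drop = FALSE]
      xte <- test$x[, genes, drop = FALSE]
      fit <- fit_multinomial(xtr, factor(as.character(train$labels)),
                             lambda = l2_strength)
      probs <- predict_multinomial(fit, xte, dataset$class_names)
      pred <- dataset$class_names[max.col(probs, ties.method = "first")]
      correct <- correct + sum(pred == as.character(test$labels))
    }
    correct / n_samples(dataset)
  }, numeric(1))
  out <- tibble::tibble(n_genes = counts_grid, accuracy = acc)
  class(out) <- c("accuracy_trace", class(out))
  out
}

#' Smallest gene count on the accuracy plateau
#'
#' The explicit form of "the minimum number of genes beyond which accuracy
#' does not increase much": the smallest count whose accuracy is within
#' `tolerance` of the best accuracy on the trace.
#'
#' @param trace An [cv_accuracy_for_gene_counts()] trace (or any tibble
#'   with `n_genes`, `accuracy`).
#' @param tolerance Non-negative accuracy tolerance (default 0.01).
#' @return The selected gene count (integer).
#' @export
choose_plateau_count <- function(trace, tolerance = 0.01) {
  if (nrow(trace) == 0) stop("Empty accuracy trace.", call. = FALSE)
  if (tolerance < 0) stop("`tolerance` must be >= 0.", call. = FALSE)
  ord <- order(trace$n_genes)
  n_genes <- trace$n_genes[ord]
  accuracy <- trace$accuracy[ord]
  ok <- accuracy >= max(accuracy) - tolerance
  n_genes[which(ok)[1]]
}

#' Two-step PCA + logistic-regression feature selection
#'
#' Step 1 ranks all genes by the largest absolute PCA loading they attain
#' across the leading components and picks the smallest gene count on the
#' cross-validated accuracy plateau; step 2 refits the PCA on the matrix
#' restricted to the step-1 genes and repeats ranking and plateau
#' selection there, yielding an even smaller set. Both accuracy traces
#' are retained.
#'
#' @param dataset A [labeled_dataset()].
#' @param n_components Leading components scanned in each PCA (default 10).
#' @param step1_grid,step2_grid Increasing gene-count grids for the two
#'   stages; `NULL` uses `c(1, 2, 5, 10, 20, 50) * n_components`, capped
#'   at the stage's gene-pool size.
#' @param k CV folds.
#' @param tolerance Plateau tolerance (default 0.01).
#' @param seed Integer seed.
#' @param l2_strength Ridge penalty of the CV classifier.
#' @return A list of class `feature_selection_result`: `step1_genes`,
#'   `selected_genes`, `trace_step1`, `trace_step2`, `n_components`,
#'   `plateau_tolerance`.
#' @export
two_step_select <- function(dataset, n_components = 10L,
                            step1_grid = NULL, step2_grid = NULL,
                            k = 5L, tolerance = 0.01, seed = 1L,
                            l2_strength = 1e-4) {
  stopifnot(inherits(dataset, "labeled_dataset"))

  default_grid <- function(pool) {
    g <- unique(pmin(c(1, 2, 5, 10, 20, 50) * n_components, pool))
    sort(g)
  }

  rank1 <- pca_loading_ranking(dataset$x, n_components)
  grid1 <- step1_grid %||% default_grid(length(rank1))
  trace1 <- cv_accuracy_for_gene_counts(dataset, rank1, grid1, k = k,
                                        seed = seed,
                                        l2_strength = l2_strength)
  m1 <- choose_plateau_count(trace1, tolerance)
  step1_genes <- rank1[seq_len(m1)]

  restricted <- subset_genes(dataset, step1_genes)
  rank2 <- pca_loading_ranking(restricted$x, n_components)
  grid2 <- step2_grid %||% default_grid(length(rank2))
  grid2 <- grid2[grid2 <= length(rank2)]
  trace2 <- cv_accuracy_for_gene_counts(restricted, rank2, grid2, k = k,
                                        seed = seed,
                                        l2_strength = l2_strength)
  m2 <- choose_plateau_count(trace2, tolerance)
  selected_genes <- rank2[seq_len(m2)]

  structure(
    list(step1_genes = step1_genes, selected_genes = selected_genes,
         trace_step1 = trace1, trace_step2 = trace2,
         n_components = as.integer(n_components),
         plateau_tolerance = tolerance, seed = seed),
    class = "feature_selection_result"
  )
}

subset_genes <- function(dataset, genes) {
  structure(
    list(x = dataset$x[, genes, drop = FALSE],
         labels = dataset$labels,
         class_names = dataset$class_names),
    class = "labeled_dataset"
  )
}

#' @export
print.feature_selection_result <- function(x, ...) {
  cat("<feature_selection_result> step 1: ", length(x$step1_genes),
      " genes; final: ", length(x$selected_genes), " genes (",
      x$n_components, " components, tolerance ", x$plateau_tolerance,
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.feature_selection_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$trace_step1, step = 1L),
    dplyr::mutate(x$trace_step2, step = 2L)
  )
}

#' @export
glance.feature_selection_result <- function(x, ...) {
  tibble::tibble(
    n_step1 = length(x$step1_genes),
    n_selected = length(x$selected_genes),
    best_accuracy_step1 = max(x$trace_step1$accuracy),
    best_accuracy_step2 = max(x$trace_step2$accuracy)
  )
}

#' Write feature-selection artifacts
#'
#' Gene lists as one-id-per-line text, traces as TSV, parameters as a JSON
#' sidecar.
#'
#' @param result A [two_step_select()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_feature_selection <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(result$step1_genes, file.path(dir, "step1_genes.txt"))
  writeLines(result$selected_genes, file.path(dir, "selected_genes.txt"))
  readr::write_tsv(tidy(result), file.path(dir, "accuracy_traces.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(n_components = result$n_components,
         plateau_tolerance = result$plateau_tolerance, seed = result$seed),
    file.path(dir, "selection_params.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Single-gene classification screen
#'
#' Evaluates every gene on its own: a one-gene L2 logistic-regression
#' classifier under stratified k-fold cross-validation, with one-vs-rest
#' precision, recall and F1 per (gene, class) computed from the pooled
#' held-out predictions. Pairs where both precision and recall exceed the
#' threshold are flagged as qualifying single-gene markers.
#'
#' @param dataset A [labeled_dataset()].
#' @param pr_threshold Qualification threshold on both precision and
#'   recall (default 0.75).
#' @param k CV folds.
#' @param seed Integer seed.
#' @param genes Genes to screen (default: all genes in the dataset).
#' @param l2_strength Ridge penalty of the one-gene classifier.
#' @return A tibble: `gene`, `class`, `precision`, `recall`, `f1`,
#'   `qualifies`.
#' @export
single_feature_screen <- function(dataset, pr_threshold = 0.75, k = 5L,
                                  seed = 1L, genes = NULL,
                                  l2_strength = 1e-4) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  genes <- genes %||% colnames(dataset$x)
  folds <- kfold_indices(dataset, k = k, seed = seed)
  y_true <- as.character(dataset$labels)
  purrr::map_dfr(genes, function(g) {
    pred <- character(n_samples(dataset))
    for (fold in folds) {
      tr_idx <- setdiff(seq_len(n_samples(dataset)), fold)
      xtr <- dataset$x[tr_idx, g, drop = FALSE]
      xte <- dataset$x[fold, g, drop = FALSE]
      fit <- fit_multinomial(xtr, factor(y_true[tr_idx]),
                             lambda = l2_strength)
      probs <- predict_multinomial(fit, xte, dataset$class_names)
      pred[fold] <- dataset$class_names[max.col(probs,
                                                ties.method = "first")]
    }
    conf <- confusion_matrix(y_true, pred, dataset$class_names)
    metrics <- precision_recall_f1(conf)
    tibble::tibble(gene = g, class = metrics$class,
                   precision = metrics$precision, recall = metrics$recall,
                   f1 = metrics$f1,
                   qualifies = metrics$precision > pr_threshold &
                     metrics$recall > pr_threshold)
  })
}
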