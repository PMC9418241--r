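#' Labeled expression dataset
#'
#' Bundles an expression matrix (samples x genes, `log2(x + 1)`-scale
#' normalized counts) with one class label per sample. This is the container
#' every training, selection and evaluation function in the package consumes.
#'
#' @param x Numeric matrix, samples in rows and genes in columns, with
#'   non-empty unique rownames (sample ids) and colnames (gene ids). Values
#'   must be finite and non-negative (the `log2(x + 1)` convention).
#' @param labels Character or factor vector, one class label per row of `x`.
#' @param class_names Optional ordered class alphabet. Defaults to the sorted
#'   unique labels. Every label must appear in it.
#' @return An object of class `labeled_dataset`: a list with elements `x`
#'   (the matrix), `labels` (a factor with levels `class_names`) and
#'   `class_names`.
#' @examples
#' x <- matrix(abs(rnorm(20, 6)), 5, 4,
#'             dimnames = list(paste0("s", 1:5), paste0("g", 1:4)))
#' ds <- labeled_dataset(x, c("A", "A", "B", "B", "B"))
#' n_samples(ds)
#' @export
labeled_dataset <- function(x, labels, class_names = NULL) {
  validate_expression_matrix(x)
  if (length(labels) != nrow(x)) {
    stop("`labels` must have one entry per sample (row of `x`): got ",
         length(labels), " labels for ", nrow(x), " samples.", call. = FALSE)
  }
  labels <- as.character(labels)
  if (anyNA(labels)) stop("`labels` contains missing values.", call. = FALSE)
  if (is.null(class_names)) class_names <- sort(unique(labels))
  class_names <- as.character(class_names)
  if (anyDuplicated(class_names)) {
    stop("`class_names` contains duplicates.", call. = FALSE)
  }
  unknown <- setdiff(unique(labels), class_names)
  if (length(unknown)) {
    stop("Labels not in `class_names`: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  present <- intersect(class_names, unique(labels))
  if (length(present) < 2) {
    stop("A labeled dataset needs at least 2 classes with samples; found ",
         length(present), ".", call. = FALSE)
  }
  structure(
    list(x = x,
         labels = factor(labels, levels = class_names),
         class_names = class_names),
    class = "labeled_dataset"
  )
}

#' Validate an expression matrix
#'
#' Checks the invariants every expression matrix in the package must satisfy:
#' numeric, no missing or negative entries (values are `log2(x + 1)` of
#' non-negative normalized counts), and unique non-empty sample and gene ids.
#'
#' @param x Numeric matrix, samples x genes.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("Expression data must be a numeric matrix (samples x genes).",
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("Expression matrix must have sample ids as rownames and gene ids ",
         "as colnames.", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("Duplicate sample ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop("Duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("Expression matrix contains missing or non-finite values; ",
         "impute or drop them upstream.", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("Expression matrix contains negative values; expected ",
         "log2(x + 1)-scale non-negative data.", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("<labeled_dataset> ", nrow(x$x), " samples x ", ncol(x$x), " genes, ",
      length(x$class_names), " classes\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname labeled_dataset
#' @param dataset A `labeled_dataset`.
#' @export
n_samples <- function(dataset) nrow(dataset$x)

#' @rdname labeled_dataset
#' @export
n_genes <- function(dataset) ncol(dataset$x)

#' Subset a labeled dataset by sample
#'
#' @param dataset A `labeled_dataset`.
#' @param idx Integer or logical index into the samples.
#' @return A `labeled_dataset` with the selected samples, keeping the full
#'   class alphabet (classes may become empty in a subset).
#' @export
subset_samples <- function(dataset, idx) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  structure(
    list(x = dataset$x[idx, , drop = FALSE],
         labels = dataset$labels[idx],
         class_names = dataset$class_names),
    class = "labeled_dataset"
  )
}

#' @export
tidy.labeled_dataset <- function(x, ...) {
  tibble::tibble(sample_id = rownames(x$x), class = as.character(x$labels))
}

#' @export
glance.labeled_dataset <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$x),
    n_genes = ncol(x$x),
    n_classes = length(x$class_names),
    min_class_size = min(table(x$labels)),
    max_class_size = max(table(x$labels))
  )
}
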