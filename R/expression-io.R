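#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression matrix with one header row and one id column
#' and returns it in the package's fixed internal orientation, samples x
#' genes, whatever the orientation on disk. Xena-style pan-cancer matrices
#' are stored genes x samples; per-cohort exports are often samples x genes.
#'
#' @param path Path to a delimited text file.
#' @param orientation Orientation of the file on disk: `"samples_by_genes"`
#'   (rows are samples) or `"genes_by_samples"` (rows are genes; the matrix
#'   is transposed after reading).
#' @param delimiter Field delimiter. `NULL` (default) picks `\t` for
#'   `.tsv`/`.txt` and `,` for `.csv`.
#' @return A numeric matrix, samples x genes, with ids preserved verbatim.
#' @seealso [write_expression_table()], [read_labels()]
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_by_genes",
                                                  "genes_by_samples"),
                                  delimiter = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  delimiter <- delimiter %||% delimiter_for(path)
  tab <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE,
                           name_repair = "minimal")
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    stop("Empty or malformed expression table: ", path, call. = FALSE)
  }
  header <- names(tab)[-1]
  if (anyDuplicated(header)) {
    kind <- if (orientation == "samples_by_genes") "gene" else "sample"
    stop("Duplicate ", kind, " ids in the header of ", path, ".",
         call. = FALSE)
  }
  ids <- as.character(tab[[1]])
  body <- tab[-1]
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad)) {
    stop("Non-numeric expression values in column(s): ",
         paste(utils::head(names(body)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "genes_by_samples") m <- t(m)
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as delimited text
#'
#' @param x Numeric matrix, samples x genes, with dimnames.
#' @param path Output path; delimiter chosen from the extension unless given.
#' @param orientation Orientation to write (`"samples_by_genes"` default).
#' @param delimiter Field delimiter; `NULL` picks it from the extension.
#' @param id_column Name of the leading id column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path,
                                   orientation = c("samples_by_genes",
                                                   "genes_by_samples"),
                                   delimiter = NULL,
                                   id_column = "sample_id") {
  orientation <- match.arg(orientation)
  validate_expression_matrix(x)
  delimiter <- delimiter %||% delimiter_for(path)
  m <- if (orientation == "genes_by_samples") t(x) else x
  tab <- tibble::as_tibble(m, rownames = id_column)
  readr::write_delim(tab, path, delim = delimiter, progress = FALSE)
  invisible(path)
}

#' Read / write per-sample class labels
#'
#' Labels travel as two-column delimited text: `sample_id` and `class`.
#'
#' @param path Path to a two-column delimited file.
#' @param delimiter Field delimiter; `NULL` picks it from the extension.
#' @return For `read_labels()`, a tibble with columns `sample_id`, `class`.
#' @export
read_labels <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  delimiter <- delimiter %||% delimiter_for(path)
  tab <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 2) stop("Label file needs two columns: sample id, class.",
                          call. = FALSE)
  out <- tibble::tibble(sample_id = as.character(tab[[1]]),
                        class = as.character(tab[[2]]))
  if (anyDuplicated(out$sample_id)) {
    stop("Duplicate sample ids in label file.", call. = FALSE)
  }
  out
}

#' @rdname read_labels
#' @param labels Tibble with columns `sample_id`, `class`, or a
#'   `labeled_dataset`.
#' @export
write_labels <- function(labels, path, delimiter = NULL) {
  if (inherits(labels, "labeled_dataset")) labels <- tidy(labels)
  delimiter <- delimiter %||% delimiter_for(path)
  readr::write_delim(labels, path, delim = delimiter, progress = FALSE)
  invisible(path)
}

#' Assemble a labeled dataset from matrix and label files
#'
#' @param expression_path Expression table path.
#' @param labels_path Label table path.
#' @inheritParams read_expression_table
#' @return A [labeled_dataset()] containing the samples present in both
#'   files, in expression-matrix order.
#' @export
read_labeled_dataset <- function(expression_path, labels_path,
                                 orientation = "samples_by_genes",
                                 delimiter = NULL) {
  x <- read_expression_table(expression_path, orientation, delimiter)
  lab <- read_labels(labels_path, delimiter)
  keep <- intersect(rownames(x), lab$sample_id)
  if (length(keep) == 0) {
    stop("No samples shared between expression and label files.",
         call. = FALSE)
  }
  x <- x[keep, , drop = FALSE]
  labels <- lab$class[match(keep, lab$sample_id)]
  labeled_dataset(x, labels)
}

#' Align an expression matrix to a reference gene list
#'
#' Restricts and reorders the columns of a matrix to a reference gene list,
#' the harmonization step needed before scoring an external cohort with a
#' model trained on different annotation (genes absent from the new cohort
#' are either dropped from the model's view or raised as an error).
#'
#' @param x Numeric matrix, samples x genes.
#' @param reference_genes Ordered character vector of gene ids.
#' @param missing_policy `"drop"` silently omits reference genes absent from
#'   `x` (they are reported in the `dropped_genes` attribute); `"error"`
#'   fails listing them.
#' @return The matrix restricted to the reference genes present, in
#'   reference order, with attribute `dropped_genes`.
#' @export
align_features <- function(x, reference_genes,
                           missing_policy = c("drop", "error")) {
  missing_policy <- match.arg(missing_policy)
  validate_expression_matrix(x)
  reference_genes <- as.character(reference_genes)
  if (length(reference_genes) == 0) {
    stop("`reference_genes` must be non-empty.", call. = FALSE)
  }
  missing <- setdiff(reference_genes, colnames(x))
  if (length(missing) && missing_policy == "error") {
    stop("Genes absent from the matrix: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10),
         call. = FALSE)
  }
  keep <- reference_genes[reference_genes %in% colnames(x)]
  if (length(keep) == 0) {
    stop("No reference genes found in the matrix.", call. = FALSE)
  }
  out <- x[, keep, drop = FALSE]
  attr(out, "dropped_genes") <- missing
  out
}

delimiter_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
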