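#' Stratified train/test split
#'
#' Splits a labeled dataset into train and test partitions whose per-class
#' proportions each match the full dataset within one sample. Allocation is
#' deterministic: within each class the samples are shuffled under the seed,
#' the train count is `floor(n_class * train_fraction)`, and the leftover
#' fractional seats are assigned by largest remainder (ties broken by class
#' order) so that the total train size is `round(n * train_fraction)` as
#' closely as the per-class floors allow.
#'
#' @param dataset A [labeled_dataset()]. Every class needs at least 2
#'   samples so both partitions can be stratified.
#' @param train_fraction Fraction of samples for training, in (0, 1).
#'   Defaults to 0.8, the conventional 80:20 split for this kind of cohort.
#' @param seed Integer seed; the split is a pure function of
#'   `(dataset, train_fraction, seed)`.
#' @return A list of class `split_result`: `train` and `test` (both
#'   `labeled_dataset`), plus `seed` and `train_fraction`.
#' @export
stratified_split <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("`train_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  tab <- table(dataset$labels)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    stop("Cannot stratify: class(es) with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  idx_by_class <- split(seq_len(n_samples(dataset)), dataset$labels)
  idx_by_class <- idx_by_class[vapply(idx_by_class, length, 0L) > 0]

  exact <- vapply(idx_by_class, length, 0L) * train_fraction
  base <- floor(exact)
  # every class keeps at least one sample on each side
  base <- pmin(pmax(base, 1L), vapply(idx_by_class, length, 0L) - 1L)
  remainder <- exact - base
  total_target <- round(n_samples(dataset) * train_fraction)
  extra <- total_target - sum(base)
  n_train <- base
  if (extra > 0) {
    ord <- order(-remainder, seq_along(remainder))
    room <- vapply(idx_by_class, length, 0L) - 1L - base
    for (j in ord) {
      if (extra <= 0) break
      if (room[j] > 0) {
        n_train[j] <- n_train[j] + 1L
        extra <- extra - 1L
      }
    }
  }

  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  train_idx <- integer(0)
  for (j in seq_along(idx_by_class)) {
    shuffled <- sample(idx_by_class[[j]])
    train_idx <- c(train_idx, shuffled[seq_len(n_train[j])])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_samples(dataset)), train_idx)

  structure(
    list(train = subset_samples(dataset, train_idx),
         test = subset_samples(dataset, test_idx),
         seed = seed,
         train_fraction = train_fraction),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> train ", n_samples(x$train), " / test ",
      n_samples(x$test), " samples (fraction ", x$train_fraction,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.split_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$train), partition = "train"),
    dplyr::mutate(tidy(x$test), partition = "test")
  )
}

#' Stratified cross-validation folds
#'
#' Partitions the samples into `k` disjoint folds whose sizes differ by at
#' most one and whose per-fold class proportions match the global ones
#' within one sample per class: within each class the shuffled samples are
#' dealt round-robin across folds, with the starting fold rotating by class
#' so fold sizes balance.
#'
#' @param dataset A [labeled_dataset()].
#' @param k Number of folds (default 5, the conventional choice for
#'   hyperparameter tuning on cohorts of this size). Every class needs at
#'   least `k` samples.
#' @param seed Integer seed.
#' @return A list of `k` integer vectors of sample indices (the held-out
#'   fold memberships), with attribute `fold_id` giving each sample's fold.
#' @export
kfold_indices <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  k <- as.integer(k)
  if (k < 2) stop("`k` must be at least 2.", call. = FALSE)
  tab <- table(dataset$labels)
  tab <- tab[tab > 0]
  small <- names(tab)[tab < k]
  if (length(small)) {
    stop("Class(es) smaller than k = ", k, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  fold_id <- integer(n_samples(dataset))
  offset <- 0L
  for (cls in names(tab)) {
    idx <- which(dataset$labels == cls)
    shuffled <- sample(idx)
    ids <- ((seq_along(shuffled) - 1L + offset) %% k) + 1L
    fold_id[shuffled] <- ids
    offset <- (offset + length(shuffled)) %% k
  }
  folds <- split(seq_len(n_samples(dataset)), fold_id)
  names(folds) <- NULL
  attr(folds, "fold_id") <- fold_id
  folds
}

# Seed the global RNG for a deterministic block, returning the previous
# state so callers can restore it (keeps split/fold functions pure).
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
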