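#' Specification of a synthetic expression cohort
#'
#' Describes a multi-class Gaussian cohort in log2(x + 1) expression space:
#' a minority of informative genes carry class-specific mean shifts while
#' the remaining genes share a common baseline, so the statistical structure
#' (class separation, imbalance, confusable class pairs) is fully
#' controlled and closed-form error oracles exist.
#'
#' For class `k` and informative gene `g`, the class mean is
#' `baseline_mean + s[k, g] * mean_shift` with signs `s[k, g]` drawn i.i.d.
#' Rademacher from the seed; any informative gene whose sign happens to be
#' identical across all classes is redrawn so every informative gene
#' separates at least one class pair. A confusable pair `(a, b, omega)`
#' blends class `b`'s informative shifts towards class `a`'s:
#' `(1 - omega) * own + omega * partner`, so `omega = 1` makes the pair
#' indistinguishable — emulating anatomically adjacent tumour types (rectal
#' vs colon, cholangio vs hepatocellular) that real classifiers confuse.
#' Observations are class mean plus independent Gaussian noise, clipped at 0
#' to preserve the log2(x + 1) convention.
#'
#' @param n_classes Number of classes.
#' @param samples_per_class Integer vector of class sizes (imbalance
#'   allowed), length `n_classes`.
#' @param n_genes Total number of genes.
#' @param n_informative Number of informative genes (the first
#'   `n_informative` gene columns).
#' @param mean_shift Class-mean displacement on the log2 scale, >= 0.
#' @param noise_sd Within-class standard deviation, log2 units, > 0.
#' @param confusable_pairs List of `(class_a, class_b, overlap)` triples;
#'   classes given as 1-based indices or class names, overlap in [0, 1].
#' @param baseline_mean Baseline log2 expression shared by all
#'   non-informative genes (default 6, a typical mid-range log2 RSEM value
#'   far enough from 0 that clipping is negligible).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @seealso [generate_cohort()], [theoretical_pairwise_bayes_error()]
#' @export
synthetic_spec <- function(n_classes = 5L,
                           samples_per_class = rep(200L, n_classes),
                           n_genes = 100L,
                           n_informative = 20L,
                           mean_shift = 2,
                           noise_sd = 1,
                           confusable_pairs = list(),
                           baseline_mean = 6,
                           seed = 1L) {
  n_classes <- as.integer(n_classes)
  samples_per_class <- as.integer(samples_per_class)
  if (n_classes < 2) stop("Need at least 2 classes.", call. = FALSE)
  if (length(samples_per_class) != n_classes || any(samples_per_class < 1)) {
    stop("`samples_per_class` must have length `n_classes`, all >= 1.",
         call. = FALSE)
  }
  if (n_informative > n_genes || n_informative < 1) {
    stop("`n_informative` must lie in [1, n_genes].", call. = FALSE)
  }
  if (mean_shift < 0) stop("`mean_shift` must be >= 0.", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be > 0.", call. = FALSE)
  if (baseline_mean < 0) stop("`baseline_mean` must be >= 0.", call. = FALSE)
  class_names <- sprintf("C%02d", seq_len(n_classes))
  confusable_pairs <- lapply(confusable_pairs, function(p) {
    if (length(p) != 3) stop("Each confusable pair is (a, b, overlap).",
                             call. = FALSE)
    a <- resolve_class(p[[1]], class_names)
    b <- resolve_class(p[[2]], class_names)
    w <- as.numeric(p[[3]])
    if (a == b) stop("A confusable pair needs two distinct classes.",
                     call. = FALSE)
    if (w < 0 || w > 1) stop("Overlap must lie in [0, 1].", call. = FALSE)
    list(a = a, b = b, overlap = w)
  })
  structure(
    list(n_classes = n_classes, samples_per_class = samples_per_class,
         n_genes = as.integer(n_genes), n_informative = as.integer(n_informative),
         mean_shift = mean_shift, noise_sd = noise_sd,
         confusable_pairs = confusable_pairs, baseline_mean = baseline_mean,
         seed = as.integer(seed), class_names = class_names),
    class = "synthetic_spec"
  )
}

resolve_class <- function(cls, class_names) {
  if (is.numeric(cls)) {
    cls <- as.integer(cls)
    if (cls < 1 || cls > length(class_names)) {
      stop("Class index out of range: ", cls, call. = FALSE)
    }
    return(cls)
  }
  i <- match(as.character(cls), class_names)
  if (is.na(i)) stop("Unknown class: ", cls, call. = FALSE)
  i
}

#' Class-mean matrix of a synthetic spec
#'
#' Deterministic (seeded) map from a [synthetic_spec()] to the matrix of
#' true class means, classes x genes, after Rademacher sign draws and
#' confusable-pair blending. Shared by the generator and the Bayes-error
#' oracle so both see exactly the same means.
#'
#' @param spec A `synthetic_spec`.
#' @return Numeric matrix, `n_classes` x `n_genes`, rownames the class
#'   names.
#' @export
class_mean_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- local_rng(spec$seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  k <- spec$n_classes
  gi <- spec$n_informative
  signs <- matrix(sample(c(-1, 1), k * gi, replace = TRUE), k, gi)
  # redraw any informative gene whose sign is constant across classes:
  # such a gene would carry no between-class signal at all
  for (g in seq_len(gi)) {
    while (length(unique(signs[, g])) == 1L) {
      signs[, g] <- sample(c(-1, 1), k, replace = TRUE)
    }
  }
  shifts <- signs * spec$mean_shift
  for (p in spec$confusable_pairs) {
    shifts[p$b, ] <- (1 - p$overlap) * shifts[p$b, ] + p$overlap * shifts[p$a, ]
  }
  means <- matrix(spec$baseline_mean, k, spec$n_genes)
  means[, seq_len(gi)] <- means[, seq_len(gi), drop = FALSE] + shifts
  rownames(means) <- spec$class_names
  colnames(means) <- sprintf("gene_%04d", seq_len(spec$n_genes))
  means
}

#' Generate a synthetic labeled cohort
#'
#' Draws a [labeled_dataset()] from a [synthetic_spec()]: per-class Gaussian
#' observations around the spec's class means, clipped at 0. Deterministic
#' given the spec (including its seed).
#'
#' @param spec A `synthetic_spec`.
#' @return A `labeled_dataset` with attributes `informative_genes` (gene
#'   ids of the planted informative genes) and `spec`.
#' @examples
#' ds <- generate_cohort(synthetic_spec(n_classes = 3,
#'                                      samples_per_class = c(30, 50, 20),
#'                                      seed = 7))
#' table(ds$labels)
#' @export
generate_cohort <- function(spec) {
  means <- class_mean_matrix(spec)
  old_seed <- local_rng(spec$seed + 1L)
  on.exit(restore_rng(old_seed), add = TRUE)
  n <- sum(spec$samples_per_class)
  labels <- rep(spec$class_names, times = spec$samples_per_class)
  x <- means[rep(seq_len(spec$n_classes), times = spec$samples_per_class), ,
             drop = FALSE] +
    matrix(stats::rnorm(n * spec$n_genes, sd = spec$noise_sd), n, spec$n_genes)
  x[x < 0] <- 0
  rownames(x) <- sprintf("sample_%05d", seq_len(n))
  colnames(x) <- colnames(means)
  ds <- labeled_dataset(x, labels, class_names = spec$class_names)
  attr(ds, "informative_genes") <- colnames(means)[seq_len(spec$n_informative)]
  attr(ds, "spec") <- spec
  ds
}

#' Closed-form two-class Bayes error for a synthetic spec
#'
#' Equal-prior misclassification probability of the optimal classifier for
#' two spherical Gaussian classes: `pnorm(-d / 2)` where `d` is the
#' Euclidean distance between the class mean vectors in noise-sd units.
#' Truncation at zero is ignored, which is negligible for baselines several
#' noise-sds above 0. Serves as the analytic oracle against which simulated
#' classifiers are calibrated.
#'
#' @param spec A [synthetic_spec()].
#' @param class_a,class_b Two distinct classes (index or name).
#' @return Misclassification probability in (0, 0.5].
#' @export
theoretical_pairwise_bayes_error <- function(spec, class_a, class_b) {
  stopifnot(inherits(spec, "synthetic_spec"))
  a <- resolve_class(class_a, spec$class_names)
  b <- resolve_class(class_b, spec$class_names)
  if (a == b) stop("Classes must be distinct.", call. = FALSE)
  means <- class_mean_matrix(spec)
  d <- sqrt(sum((means[a, ] - means[b, ])^2)) / spec$noise_sd
  stats::pnorm(-d / 2)
}

#' Nearest-true-centroid classification error (simulation oracle)
#'
#' Classifies every sample of a cohort by the nearest class-mean vector of
#' its generating spec (Euclidean distance) and returns the error rate.
#' For two equal-size spherical Gaussian classes this estimator converges
#' to [theoretical_pairwise_bayes_error()].
#'
#' @param dataset A cohort produced by [generate_cohort()].
#' @return A tibble with `error_rate`, `n`, and the Monte-Carlo standard
#'   error of the estimate.
#' @export
nearest_centroid_error <- function(dataset) {
  spec <- attr(dataset, "spec")
  if (is.null(spec)) stop("Dataset carries no synthetic spec.", call. = FALSE)
  means <- class_mean_matrix(spec)
  # squared distance to each centroid via the expansion ||x||^2 - 2 x.m + ||m||^2
  cross <- dataset$x %*% t(means)
  m2 <- rowSums(means^2)
  d2 <- sweep(-2 * cross, 2, m2, `+`)
  pred <- spec$class_names[max.col(-d2, ties.method = "first")]
  err <- mean(pred != as.character(dataset$labels))
  tibble::tibble(error_rate = err,
                 n = n_samples(dataset),
                 mc_se = sqrt(err * (1 - err) / n_samples(dataset)))
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression matrix and labels in the package's delimited-text
#' dialect plus a JSON sidecar recording the full generating spec and seed.
#'
#' @param dataset A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(dataset$x, file.path(dir, "expression.tsv"))
  write_labels(dataset, file.path(dir, "labels.tsv"))
  spec <- attr(dataset, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
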