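#' Monte-Carlo predictive sampling from the weight posterior
#'
#' Draws `T` weight samples from the fitted variational posterior and runs
#' the forward pass for each, yielding the tensor of softmax draws from
#' which epistemic uncertainty is computed. The default of 500 iterations
#' follows the convention for this estimator; smaller values trade
#' Monte-Carlo precision for time.
#'
#' @param model A fitted `bnn_model`.
#' @param newdata Feature matrix (samples x genes, aligned to
#'   `model$feature_genes`) or a `labeled_dataset`.
#' @param T Number of Monte-Carlo iterations (>= 1).
#' @param seed Integer seed.
#' @return A list of class `mc_predictions`: `draws` (array `T x N x C`),
#'   `mean_probs` (`N x C` matrix, the arithmetic mean over draws),
#'   `predicted_class` (character, argmax of the mean), `class_names`,
#'   `sample_ids`, `T`, `seed`.
#' @export
mc_predict <- function(model, newdata, T = 500L, seed = 1L) {
  stopifnot(inherits(model, "bnn_model"))
  T <- as.integer(T)
  if (T < 1) stop("`T` must be >= 1.", call. = FALSE)
  x <- feature_matrix_for(model, newdata)
  xs <- apply_scaling(x, model$scaling)
  n <- nrow(xs)
  C <- length(model$class_names)
  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  draws <- array(NA_real_, c(T, n, C),
                 dimnames = list(NULL, rownames(x), model$class_names))
  for (t in seq_len(T)) {
    w <- sample_weights(model$params)
    draws[t, , ] <- forward(w, xs)
  }
  mean_probs <- apply(draws, c(2, 3), mean)
  predicted <- model$class_names[max.col(mean_probs, ties.method = "first")]
  structure(
    list(draws = draws, mean_probs = mean_probs,
         predicted_class = predicted, class_names = model$class_names,
         sample_ids = rownames(x), T = T, seed = seed),
    class = "mc_predictions"
  )
}

#' @export
print.mc_predictions <- function(x, ...) {
  cat("<mc_predictions> ", x$T, " draws x ", length(x$sample_ids),
      " samples x ", length(x$class_names), " classes\n", sep = "")
  invisible(x)
}

#' Epistemic-uncertainty matrix for one sample
#'
#' The empirical second-moment matrix of the softmax draws around their
#' mean, `(1/T) * sum_t (p_t - pbar)(p_t - pbar)^T`, a symmetric positive
#' semidefinite `C x C` matrix whose diagonal entries are the per-class
#' variances of the predictive draws.
#'
#' @param mcpred An [mc_predict()] result.
#' @param sample Sample index (integer) or sample id.
#' @return A `C x C` numeric matrix.
#' @export
epistemic_matrix <- function(mcpred, sample) {
  stopifnot(inherits(mcpred, "mc_predictions"))
  if (is.character(sample)) sample <- match(sample, mcpred$sample_ids)
  if (is.na(sample) || sample < 1 || sample > length(mcpred$sample_ids)) {
    stop("Invalid sample index.", call. = FALSE)
  }
  p <- mcpred$draws[, sample, , drop = TRUE]
  if (is.null(dim(p))) p <- matrix(p, nrow = mcpred$T)  # C == 1 edge
  centered <- sweep(p, 2, mcpred$mean_probs[sample, ], `-`)
  m <- crossprod(centered) / mcpred$T
  dimnames(m) <- list(mcpred$class_names, mcpred$class_names)
  m
}

#' Scalar epistemic uncertainty per sample
#'
#' For each sample, the variance of the Monte-Carlo softmax draws at the
#' predicted class: `xi_i = (1/T) * sum_t (p_t_i - pbar_i)^2` with `i` the
#' argmax of the mean probabilities — the predicted-class diagonal element
#' of [epistemic_matrix()]. Being the variance of a [0, 1]-bounded
#' quantity, `xi` is at most 0.25.
#'
#' @param mcpred An [mc_predict()] result.
#' @return A list of class `uncertainty_estimate`: `samples` (tibble with
#'   `sample_id`, `predicted_class`, `xi`), `class_variance` (`N x C`
#'   matrix of all per-class diagonal variances), `mean_probs`,
#'   `class_names`, `T`.
#' @export
epistemic_scalar <- function(mcpred) {
  stopifnot(inherits(mcpred, "mc_predictions"))
  centered <- sweep(mcpred$draws, c(2, 3), mcpred$mean_probs, `-`)
  class_variance <- apply(centered^2, c(2, 3), mean)
  if (is.null(dim(class_variance))) {
    class_variance <- matrix(class_variance, nrow = 1,
                             dimnames = list(mcpred$sample_ids,
                                             mcpred$class_names))
  }
  pred_idx <- match(mcpred$predicted_class, mcpred$class_names)
  xi <- class_variance[cbind(seq_along(pred_idx), pred_idx)]
  structure(
    list(samples = tibble::tibble(sample_id = mcpred$sample_ids,
                                  predicted_class = mcpred$predicted_class,
                                  xi = xi),
         class_variance = class_variance,
         mean_probs = mcpred$mean_probs,
         class_names = mcpred$class_names,
         T = mcpred$T),
    class = "uncertainty_estimate"
  )
}

#' @export
print.uncertainty_estimate <- function(x, ...) {
  cat("<uncertainty_estimate> ", nrow(x$samples), " samples; xi in [",
      format(min(x$samples$xi), digits = 3), ", ",
      format(max(x$samples$xi), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @export
tidy.uncertainty_estimate <- function(x, ...) x$samples

#' @export
glance.uncertainty_estimate <- function(x, ...) {
  tibble::tibble(n = nrow(x$samples),
                 mean_xi = mean(x$samples$xi),
                 max_xi = max(x$samples$xi),
                 T = x$T)
}

#' Uncertainty threshold from correct training predictions
#'
#' The mean scalar uncertainty over training samples whose predicted class
#' equals the true class — the reference level below which a test
#' prediction is considered trustworthy. A per-class variant returns one
#' threshold per predicted class.
#'
#' @param est An [epistemic_scalar()] result on training data.
#' @param y_true True labels for the same samples.
#' @param per_class Return per-class thresholds instead of one global mean.
#' @return A scalar threshold, or a named vector (per-class mode; classes
#'   with no correct prediction are `NA`).
#' @export
training_uncertainty_threshold <- function(est, y_true, per_class = FALSE) {
  stopifnot(inherits(est, "uncertainty_estimate"))
  y_true <- as.character(y_true)
  if (length(y_true) != nrow(est$samples)) {
    stop("`y_true` length must match the number of samples.", call. = FALSE)
  }
  correct <- est$samples$predicted_class == y_true
  if (!any(correct)) {
    stop("No correctly classified samples; cannot derive a threshold.",
         call. = FALSE)
  }
  if (!per_class) return(mean(est$samples$xi[correct]))
  vapply(est$class_names, function(cls) {
    sel <- correct & est$samples$predicted_class == cls
    if (any(sel)) mean(est$samples$xi[sel]) else NA_real_
  }, numeric(1))
}

#' Filter predictions by uncertainty
#'
#' Retains a sample iff its scalar uncertainty is strictly below the
#' threshold (boundary values are dropped); discarded predictions are the
#' ones the model itself flags as unreliable.
#'
#' @param est An [epistemic_scalar()] result.
#' @param threshold Non-negative uncertainty threshold, typically from
#'   [training_uncertainty_threshold()].
#' @return A list of class `filter_result`: `threshold`, `retained`
#'   (logical mask), `retained_fraction`, and the per-sample tibble with a
#'   `retained` column. An empty retained set is allowed and flagged.
#' @export
filter_predictions <- function(est, threshold) {
  stopifnot(inherits(est, "uncertainty_estimate"))
  if (!is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be a non-negative number.", call. = FALSE)
  }
  retained <- est$samples$xi < threshold
  structure(
    list(threshold = threshold,
         retained = retained,
         retained_fraction = mean(retained),
         samples = dplyr::mutate(est$samples, retained = retained),
         empty = !any(retained)),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> threshold ", format(x$threshold, digits = 4),
      "; retained ", sum(x$retained), "/", length(x$retained),
      " (", format(x$retained_fraction, digits = 3), ")\n", sep = "")
  if (x$empty) cat("  note: no samples retained\n")
  invisible(x)
}

#' Log-odds transform and its inverse
#'
#' `logit(p) = log(p / (1 - p))` with `p` clipped into
#' `[1e-7, 1 - 1e-7]` first, since softmax outputs can saturate
#' numerically; `inv_logit` is the logistic sigmoid.
#'
#' @param p Probability (vector allowed).
#' @param z Real number (vector allowed).
#' @param eps Clipping bound.
#' @return Numeric vector.
#' @export
logit <- function(p, eps = 1e-7) {
  if (any(!is.finite(p))) stop("Non-finite probability input.", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(z) {
  if (any(!is.finite(z))) stop("Non-finite logit input.", call. = FALSE)
  1 / (1 + exp(-z))
}

#' Fit the per-class uncertainty-correction model
#'
#' For each class `c`, over the (training) samples predicted as `c`,
#' ordinary least squares of the log odds of the mean predicted
#' probability on the square root of the scalar uncertainty:
#' `logit(pbar_c) = alpha_c + beta_c * sqrt(xi) + e`, `e ~ N(0, sigma^2)`.
#' Classes with fewer than 3 points get `beta = 0` and `alpha` equal to
#' the mean response (0 when the class was never predicted) and are
#' flagged.
#'
#' @param est An [epistemic_scalar()] result on training data (carries the
#'   mean probabilities and predicted classes).
#' @return A list of class `correction_model` with a per-class coefficient
#'   tibble: `class`, `alpha`, `beta`, `sigma2`, `n_points`, `flagged`.
#' @export
fit_correction <- function(est) {
  stopifnot(inherits(est, "uncertainty_estimate"))
  rows <- purrr::map_dfr(seq_along(est$class_names), function(ci) {
    cls <- est$class_names[ci]
    sel <- est$samples$predicted_class == cls
    n_pts <- sum(sel)
    if (n_pts < 3) {
      alpha <- if (n_pts > 0) mean(logit(est$mean_probs[sel, ci])) else 0
      return(tibble::tibble(class = cls, alpha = alpha, beta = 0,
                            sigma2 = 0, n_points = n_pts, flagged = TRUE))
    }
    yv <- logit(est$mean_probs[sel, ci])
    xv <- sqrt(est$samples$xi[sel])
    fit <- stats::lm.fit(cbind(1, xv), yv)
    res <- fit$residuals
    tibble::tibble(class = cls, alpha = unname(fit$coefficients[1]),
                   beta = unname(fit$coefficients[2]),
                   sigma2 = sum(res^2) / max(n_pts - 2L, 1L),
                   n_points = n_pts, flagged = FALSE)
  })
  structure(list(coefficients = rows, class_names = est$class_names,
                 scope = "training samples grouped by predicted class"),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("<correction_model> per-class logit-scale OLS (", x$scope, ")\n",
      sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.correction_model <- function(x, ...) x$coefficients

#' @export
glance.correction_model <- function(x, ...) {
  ok <- !x$coefficients$flagged
  tibble::tibble(
    n_classes = nrow(x$coefficients),
    n_flagged = sum(!ok),
    mean_beta = if (any(ok)) mean(x$coefficients$beta[ok]) else NA_real_
  )
}

#' Apply the uncertainty correction to predictions
#'
#' Adjusts every class probability of every sample using that class's
#' fitted slope and the sample's per-class draw variance. The canonical
#' variant operates on the scale the model was fitted on,
#' `p_corr = inv_logit(logit(pbar_c) - beta_c * sqrt(xi_c))`; the literal
#' variant applies `p_corr = inv_logit(pbar_c - beta_c * xi_c)`, i.e. the
#' raw probability and the un-rooted variance inside the inverse logit.
#' Corrected probabilities are not renormalized across classes — the class
#' call is an argmax, which a common renormalization could not change.
#'
#' @param est An [epistemic_scalar()] result (test or training samples).
#' @param model A [fit_correction()] model.
#' @param variant `"canonical"` (default) or `"literal"`.
#' @return A list of class `corrected_predictions`: `probs` (`N x C`
#'   corrected matrix), `samples` tibble (`sample_id`, `predicted_class`,
#'   `corrected_class`, `corrected_prob`), and `variant`.
#' @export
apply_correction <- function(est, model, variant = c("canonical", "literal")) {
  stopifnot(inherits(est, "uncertainty_estimate"),
            inherits(model, "correction_model"))
  variant <- match.arg(variant)
  if (!setequal(model$class_names, est$class_names)) {
    stop("Correction model classes do not match the predictions.",
         call. = FALSE)
  }
  beta <- model$coefficients$beta[match(est$class_names,
                                        model$coefficients$class)]
  pbar <- est$mean_probs
  v <- est$class_variance
  z <- if (variant == "canonical") {
    matrix(logit(pbar), nrow(pbar), ncol(pbar)) - sweep(sqrt(v), 2, beta, `*`)
  } else {
    pbar - sweep(v, 2, beta, `*`)
  }
  corrected <- matrix(inv_logit(z), nrow(pbar), ncol(pbar))
  dimnames(corrected) <- list(est$samples$sample_id, est$class_names)
  corrected_class <- est$class_names[max.col(corrected, ties.method = "first")]
  structure(
    list(probs = corrected,
         samples = tibble::tibble(
           sample_id = est$samples$sample_id,
           predicted_class = est$samples$predicted_class,
           corrected_class = corrected_class,
           corrected_prob = corrected[cbind(seq_along(corrected_class),
                                            match(corrected_class,
                                                  est$class_names))]),
         variant = variant,
         class_names = est$class_names),
    class = "corrected_predictions"
  )
}

#' @export
print.corrected_predictions <- function(x, ...) {
  changed <- sum(x$samples$predicted_class != x$samples$corrected_class)
  cat("<corrected_predictions> ", nrow(x$samples), " samples (",
      x$variant, " variant); ", changed, " class call(s) changed\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.corrected_predictions <- function(x, ...) x$samples
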