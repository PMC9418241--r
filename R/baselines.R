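#' Train the point-estimate deep-network baseline
#'
#' A conventional feed-forward classifier with the same activation scheme
#' as the Bayesian network (sigmoid hidden layers, softmax output) but
#' point weights: Xavier (Glorot) uniform initialization, an L2 penalty on
#' the weights, categorical cross-entropy, Adam updates. Default hidden
#' widths are 250 and 55.
#'
#' @param train A [labeled_dataset()].
#' @param hidden_sizes Hidden-layer widths; default `c(250, 55)`.
#' @param config A [train_config()]; `l2_strength` is the penalty
#'   coefficient on the squared weight norm.
#' @return A list of class `dnn_model` with the weights, scaling, config
#'   and loss history.
#' @export
train_dnn_baseline <- function(train, hidden_sizes = c(250L, 55L),
                               config = train_config()) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(config, "train_config"))
  old_seed <- local_rng(config$seed)
  on.exit(restore_rng(old_seed), add = TRUE)

  scaling <- fit_scaling(train$x)
  x <- apply_scaling(train$x, scaling)
  y <- one_hot(train$labels, train$class_names)
  layer_sizes <- c(ncol(x), as.integer(hidden_sizes),
                   length(train$class_names))

  L <- length(layer_sizes) - 1L
  w <- list(W = vector("list", L), b = vector("list", L))
  for (l in seq_len(L)) {
    din <- layer_sizes[l]; dout <- layer_sizes[l + 1L]
    lim <- sqrt(6 / (din + dout))             # Xavier uniform
    w$W[[l]] <- matrix(stats::runif(din * dout, -lim, lim), din, dout)
    w$b[[l]] <- rep(0, dout)
  }

  n <- nrow(x)
  vec <- flatten_weights(w)
  opt <- adam_init(length(vec))
  history <- numeric(config$epochs)
  lambda <- config$l2_strength

  for (epoch in seq_len(config$epochs)) {
    batches <- epoch_batches(n, config$batch_size)
    epoch_loss <- 0
    for (idx in batches) {
      fw <- mlp_forward(w, x[idx, , drop = FALSE])
      g <- mlp_backprop(w, fw, y[idx, , drop = FALSE])
      # penalty applies to weights only, scaled per batch
      pen_scale <- lambda * length(idx) / n
      for (l in seq_len(L)) g$W[[l]] <- g$W[[l]] + pen_scale * w$W[[l]]
      loss <- nll_loss(fw$probs, y[idx, , drop = FALSE]) +
        pen_scale / 2 * sum(flatten_weights(w)[seq_len(sum(
          vapply(w$W, length, 0L)))]^2)
      if (!is.finite(loss)) {
        stop("Non-finite training loss at epoch ", epoch, ".", call. = FALSE)
      }
      opt <- adam_step(opt, flatten_weights(g), config$learning_rate)
      vec <- vec + opt$delta
      w <- unflatten_weights(vec, w)
      epoch_loss <- epoch_loss + loss
    }
    history[epoch] <- epoch_loss / length(batches)
  }

  structure(
    list(weights = w, class_names = train$class_names,
         feature_genes = colnames(train$x), scaling = scaling,
         hidden_sizes = as.integer(hidden_sizes), config = config,
         loss_history = history),
    class = "dnn_model"
  )
}

#' @export
predict.dnn_model <- function(object, newdata, ...) {
  x <- feature_matrix_for(object, newdata)
  forward(object$weights, apply_scaling(x, object$scaling))
}

#' @export
print.dnn_model <- function(x, ...) {
  cat("<dnn_model> layers ",
      paste(c(length(x$feature_genes), x$hidden_sizes,
              length(x$class_names)), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' @export
glance.dnn_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_genes),
    n_classes = length(x$class_names),
    epochs = x$config$epochs,
    l2_strength = x$config$l2_strength,
    final_loss = utils::tail(x$loss_history, 1)
  )
}

#' Train the L2-regularized multinomial logistic-regression baseline
#'
#' Ridge-penalized multinomial logistic regression (glmnet with
#' `alpha = 0` at a single fixed penalty) on standardized features.
#'
#' @param train A [labeled_dataset()].
#' @param config A [train_config()]; `l2_strength` is passed to glmnet as
#'   the `lambda` value.
#' @return A list of class `logreg_model`.
#' @export
train_logreg_baseline <- function(train, config = train_config()) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (length(unique(as.character(train$labels))) < 2) {
    stop("Logistic regression needs at least two observed classes.",
         call. = FALSE)
  }
  scaling <- fit_scaling(train$x)
  x <- apply_scaling(train$x, scaling)
  fit <- fit_multinomial(x, factor(as.character(train$labels),
                                   levels = train$class_names),
                         lambda = config$l2_strength)
  structure(
    list(fit = fit, class_names = train$class_names,
         feature_genes = colnames(train$x), scaling = scaling,
         config = config),
    class = "logreg_model"
  )
}

#' @export
predict.logreg_model <- function(object, newdata, ...) {
  x <- feature_matrix_for(object, newdata)
  predict_multinomial(object$fit, apply_scaling(x, object$scaling),
                      object$class_names)
}

#' @export
print.logreg_model <- function(x, ...) {
  cat("<logreg_model> ", length(x$feature_genes), " features, ",
      length(x$class_names), " classes, lambda ",
      x$config$l2_strength, "\n", sep = "")
  invisible(x)
}

# Internal multinomial logistic regression: glmnet ridge when >= 2
# predictors (fast, deterministic), nnet::multinom for the single-gene
# case glmnet cannot handle.
fit_multinomial <- function(x, y, lambda = 1e-4) {
  y <- droplevels(y)
  if (ncol(x) >= 2) {
    # pathwise fit down to the requested penalty: a single small lambda
    # can fail to converge without the warm starts of the path
    path <- exp(seq(log(max(1, lambda * 10)), log(lambda), length.out = 15))
    fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                          lambda = path, standardize = FALSE)
    list(kind = "glmnet", fit = fit, lambda = lambda, levels = levels(y))
  } else {
    df <- data.frame(y = y, x1 = as.numeric(x[, 1]))
    fit <- nnet::multinom(y ~ x1, data = df, decay = lambda,
                          trace = FALSE, maxit = 200)
    list(kind = "multinom", fit = fit, lambda = lambda, levels = levels(y))
  }
}

predict_multinomial <- function(model, x, class_names) {
  if (model$kind == "glmnet") {
    p <- predict(model$fit, newx = x, type = "response",
                 s = model$lambda)[, , 1]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                     dimnames = list(NULL, model$levels))
  } else {
    p <- predict(model$fit, newdata = data.frame(x1 = as.numeric(x[, 1])),
                 type = "probs")
    if (is.null(dim(p))) {
      # two-level fit returns P(second level) as a vector
      p <- cbind(1 - p, p)
      colnames(p) <- model$levels
      if (nrow(x) == 1) p <- p[1, , drop = FALSE]
    }
  }
  out <- matrix(0, nrow(x), length(class_names),
                dimnames = list(rownames(x), class_names))
  out[, colnames(p)] <- p
  out
}

# coefficient matrix (classes x features) for shrinkage checks
logreg_coef_norm <- function(model) {
  if (model$fit$kind == "glmnet") {
    cf <- stats::coef(model$fit$fit, s = model$fit$lambda)
    # drop the intercept row of each per-class coefficient column
    sqrt(sum(vapply(cf, function(b) sum(as.numeric(b)[-1]^2), 0)))
  } else {
    sqrt(sum(stats::coef(model$fit$fit)^2))
  }
}
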