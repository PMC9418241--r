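#' Initialize mean-field variational parameters
#'
#' Creates the variational posterior over all network weights and biases: an
#' independent Gaussian per parameter, location `mu` drawn from a zero-mean
#' normal with small standard deviation and raw scale `rho` set so the
#' initial standard deviation `sigma = softplus(rho)` is about 0.05.
#'
#' @param layer_sizes Integer vector of layer widths, input first, output
#'   (number of classes) last; at least two entries.
#' @param seed Integer seed.
#' @param mu_sd Standard deviation of the location initialization.
#' @param init_sigma Initial posterior standard deviation.
#' @return A list of class `variational_params` with elements `mu` and
#'   `rho` (each a `{W, b}` weight list) and `layer_sizes`.
#' @export
init_variational <- function(layer_sizes, seed = 1L, mu_sd = 0.1,
                             init_sigma = 0.05) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    stop("`layer_sizes` needs >= 2 entries, all >= 1.", call. = FALSE)
  }
  old_seed <- local_rng(seed)
  on.exit(restore_rng(old_seed), add = TRUE)
  rho0 <- log(expm1(init_sigma))      # softplus^{-1}(init_sigma)
  L <- length(layer_sizes) - 1L
  mu <- list(W = vector("list", L), b = vector("list", L))
  rho <- list(W = vector("list", L), b = vector("list", L))
  for (l in seq_len(L)) {
    din <- layer_sizes[l]; dout <- layer_sizes[l + 1L]
    mu$W[[l]] <- matrix(stats::rnorm(din * dout, sd = mu_sd), din, dout)
    mu$b[[l]] <- stats::rnorm(dout, sd = mu_sd)
    rho$W[[l]] <- matrix(rho0, din, dout)
    rho$b[[l]] <- rep(rho0, dout)
  }
  structure(list(mu = mu, rho = rho, layer_sizes = layer_sizes),
            class = "variational_params")
}

#' Draw a concrete weight sample from the variational posterior
#'
#' Reparameterized draw `w = mu + softplus(rho) * eps` with `eps` standard
#' normal, consuming (and advancing) the current RNG stream.
#'
#' @param params A [init_variational()] object.
#' @param return_eps Also return the standard-normal draws (needed for
#'   gradient computation).
#' @return A `{W, b}` weight list; with `return_eps = TRUE`, a list
#'   `list(weights, eps)`.
#' @export
sample_weights <- function(params, return_eps = FALSE) {
  stopifnot(inherits(params, "variational_params"))
  L <- length(params$mu$W)
  w <- params$mu
  eps <- params$mu
  for (l in seq_len(L)) {
    eW <- matrix(stats::rnorm(length(params$mu$W[[l]])),
                 nrow(params$mu$W[[l]]), ncol(params$mu$W[[l]]))
    eb <- stats::rnorm(length(params$mu$b[[l]]))
    eps$W[[l]] <- eW
    eps$b[[l]] <- eb
    w$W[[l]] <- params$mu$W[[l]] + softplus(params$rho$W[[l]]) * eW
    w$b[[l]] <- params$mu$b[[l]] + softplus(params$rho$b[[l]]) * eb
  }
  if (return_eps) list(weights = w, eps = eps) else w
}

# log-density sums for a weight sample under the variational posterior and
# under the standard-normal prior
log_q_density <- function(w, params) {
  s <- 0
  for (part in c("W", "b")) {
    for (l in seq_along(w[[part]])) {
      sigma <- softplus(params$rho[[part]][[l]])
      s <- s + sum(stats::dnorm(w[[part]][[l]], params$mu[[part]][[l]],
                                sigma, log = TRUE))
    }
  }
  s
}

log_prior_density <- function(w) {
  s <- 0
  for (part in c("W", "b")) {
    for (l in seq_along(w[[part]])) {
      s <- s + sum(stats::dnorm(w[[part]][[l]], 0, 1, log = TRUE))
    }
  }
  s
}

#' Monte-Carlo variational loss (negative ELBO)
#'
#' Average over `n_mc` reparameterized weight draws of
#' `kl_scale * (log q(w) - log p(w)) - log p(batch | w)`, the per-batch
#' Bayes-by-Backprop objective with a standard-normal prior: the
#' variational log density minus the prior log density (the complexity
#' term, weighted by `kl_scale`) minus the categorical log-likelihood of
#' the batch labels under the forward-pass probabilities. An empty batch
#' contributes zero likelihood.
#'
#' @param params A [init_variational()] object.
#' @param x Feature matrix, samples x features (may have zero rows).
#' @param y_onehot One-hot label matrix, samples x classes.
#' @param n_mc Number of Monte-Carlo draws (>= 1).
#' @param kl_scale Complexity-term weight.
#' @return Scalar loss; draws consume the current RNG stream.
#' @export
elbo_loss <- function(params, x, y_onehot, n_mc = 1L, kl_scale = 1) {
  if (n_mc < 1) stop("`n_mc` must be >= 1.", call. = FALSE)
  total <- 0
  for (i in seq_len(n_mc)) {
    w <- sample_weights(params)
    kl_term <- log_q_density(w, params) - log_prior_density(w)
    lik <- if (nrow(x) == 0) 0 else {
      nll_loss(mlp_forward(w, x)$probs, y_onehot)
    }
    total <- total + kl_scale * kl_term + lik
  }
  total / n_mc
}

# Loss and exact gradients (w.r.t. mu and rho) for ONE reparameterized draw
# with the standard-normal eps supplied, so finite differences with the
# same eps must agree. All three dependence paths of the objective on
# (mu, rho) are included: through w = mu + softplus(rho) * eps, and the
# direct dependence of log q on mu and rho.
elbo_loss_grad <- function(params, x, y_onehot, eps, kl_scale = 1) {
  w <- params$mu
  for (part in c("W", "b")) {
    for (l in seq_along(w[[part]])) {
      sigma <- softplus(params$rho[[part]][[l]])
      w[[part]][[l]] <- params$mu[[part]][[l]] + sigma * eps[[part]][[l]]
    }
  }
  if (nrow(x) > 0) {
    fw <- mlp_forward(w, x)
    g_lik <- mlp_backprop(w, fw, y_onehot)
    lik <- nll_loss(fw$probs, y_onehot)
  } else {
    g_lik <- rapply(w, function(m) m * 0, how = "replace")
    lik <- 0
  }
  loss <- kl_scale * (log_q_density(w, params) - log_prior_density(w)) + lik
  g_mu <- params$mu
  g_rho <- params$rho
  for (part in c("W", "b")) {
    for (l in seq_along(w[[part]])) {
      mu <- params$mu[[part]][[l]]
      rho <- params$rho[[part]][[l]]
      e <- eps[[part]][[l]]
      sigma <- softplus(rho)
      wv <- w[[part]][[l]]
      # d/dw of kl_scale*(log q - log p) + nll
      df_dw <- kl_scale * (-(wv - mu) / sigma^2 + wv) + g_lik[[part]][[l]]
      # direct partials of log q at fixed w
      dq_dmu <- (wv - mu) / sigma^2
      dq_dsigma <- -1 / sigma + (wv - mu)^2 / sigma^3
      dsig_drho <- sigmoid(rho)
      g_mu[[part]][[l]] <- df_dw + kl_scale * dq_dmu
      g_rho[[part]][[l]] <- df_dw * e * dsig_drho +
        kl_scale * dq_dsigma * dsig_drho
    }
  }
  list(loss = loss, g_mu = g_mu, g_rho = g_rho)
}

#' Train the Bayesian neural network by Bayes by Backprop
#'
#' Fits the mean-field Gaussian posterior over the weights of a
#' sigmoid-hidden, softmax-output network by stochastic minimization of the
#' Monte-Carlo variational loss with Adam. Features are standardized
#' (training mean/sd) before entering the network; the scaling is stored in
#' the model and re-applied at prediction time.
#'
#' @param train A [labeled_dataset()].
#' @param hidden_sizes Hidden-layer widths; default `c(250, 95)`.
#' @param config A [train_config()].
#' @return A list of class `bnn_model`: variational `params`, `class_names`,
#'   `feature_genes`, the input scaling, the config, and the per-epoch
#'   training-loss history.
#' @export
train_bnn <- function(train, hidden_sizes = c(250L, 95L),
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
  params <- init_variational(layer_sizes, seed = config$seed)

  n <- nrow(x)
  n_batches <- max(1L, ceiling(n / config$batch_size))
  kl_scale <- config$kl_scale %||% (1 / n_batches)

  vec_mu <- flatten_weights(params$mu)
  vec_rho <- flatten_weights(params$rho)
  opt_mu <- adam_init(length(vec_mu))
  opt_rho <- adam_init(length(vec_rho))
  history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    batches <- epoch_batches(n, config$batch_size)
    epoch_loss <- 0
    for (idx in batches) {
      acc_mu <- 0; acc_rho <- 0; acc_loss <- 0
      for (i in seq_len(config$n_mc)) {
        eps <- sample_weights(params, return_eps = TRUE)$eps
        g <- elbo_loss_grad(params, x[idx, , drop = FALSE],
                            y[idx, , drop = FALSE], eps, kl_scale)
        acc_mu <- acc_mu + flatten_weights(g$g_mu)
        acc_rho <- acc_rho + flatten_weights(g$g_rho)
        acc_loss <- acc_loss + g$loss
      }
      acc_mu <- acc_mu / config$n_mc
      acc_rho <- acc_rho / config$n_mc
      acc_loss <- acc_loss / config$n_mc
      if (!is.finite(acc_loss)) {
        stop("Non-finite training loss at epoch ", epoch,
             "; lower the learning rate or check the input scale.",
             call. = FALSE)
      }
      opt_mu <- adam_step(opt_mu, acc_mu, config$learning_rate)
      vec_mu <- vec_mu + opt_mu$delta
      opt_rho <- adam_step(opt_rho, acc_rho, config$learning_rate)
      vec_rho <- vec_rho + opt_rho$delta
      params$mu <- unflatten_weights(vec_mu, params$mu)
      params$rho <- unflatten_weights(vec_rho, params$rho)
      epoch_loss <- epoch_loss + acc_loss
    }
    history[epoch] <- epoch_loss / length(batches)
  }

  structure(
    list(params = params, class_names = train$class_names,
         feature_genes = colnames(train$x), scaling = scaling,
         hidden_sizes = as.integer(hidden_sizes), config = config,
         loss_history = history),
    class = "bnn_model"
  )
}

fit_scaling <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  list(center = mu, scale = sd)
}

apply_scaling <- function(x, scaling) {
  sweep(sweep(x, 2, scaling$center, `-`), 2, scaling$scale, `/`)
}

#' @export
print.bnn_model <- function(x, ...) {
  cat("<bnn_model> layers ",
      paste(x$params$layer_sizes, collapse = "-"),
      ", ", length(x$class_names), " classes, ",
      length(x$feature_genes), " feature genes\n", sep = "")
  cat("  final epoch-mean loss: ",
      format(utils::tail(x$loss_history, 1)), "\n", sep = "")
  invisible(x)
}

#' @export
glance.bnn_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_genes),
    n_classes = length(x$class_names),
    n_parameters = length(flatten_weights(x$params$mu)),
    epochs = x$config$epochs,
    final_loss = utils::tail(x$loss_history, 1)
  )
}

#' @export
tidy.bnn_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' Point (posterior-location) class probabilities from a BNN
#'
#' Evaluates the network at the variational location parameters `mu`. For
#' uncertainty-aware prediction use [mc_predict()].
#'
#' @param object A `bnn_model`.
#' @param newdata Matrix of features or a `labeled_dataset`.
#' @param ... Unused.
#' @return Matrix of class probabilities.
#' @export
predict.bnn_model <- function(object, newdata, ...) {
  x <- feature_matrix_for(object, newdata)
  forward(object$params$mu, apply_scaling(x, object$scaling))
}

feature_matrix_for <- function(model, newdata) {
  x <- if (inherits(newdata, "labeled_dataset")) newdata$x else newdata
  if (!identical(colnames(x), model$feature_genes)) {
    x <- align_features(x, model$feature_genes, missing_policy = "error")
  }
  x
}

#' Save / load a fitted model archive
#'
#' Serializes a fitted model (variational parameters, architecture, class
#' alphabet, feature-gene list, scaling and config) to a single archive for
#' inference-only reuse, e.g. scoring an external cohort after
#' [align_features()].
#'
#' @param model A fitted model object.
#' @param path Archive path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
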