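# Shared multilayer-perceptron machinery used by both the variational and
# the point-estimate networks: sigmoid hidden layers, softmax output,
# categorical cross-entropy, hand-rolled backprop, and Adam updates.
# Weights travel as a list with elements W (list of matrices, in_dim x
# out_dim per layer) and b (list of bias vectors).

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

softplus <- function(x) {
  # log(1 + exp(x)) computed without overflow
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Forward pass of the classifier network
#'
#' Applies the network to a feature matrix: every hidden layer is an affine
#' map followed by the logistic sigmoid, the output layer an affine map
#' followed by softmax, so each row of the result is a probability vector
#' over the classes.
#'
#' @param weights A weight sample: list with `W` (list of matrices,
#'   `in x out` per layer) and `b` (list of bias vectors).
#' @param x Numeric matrix, samples x features; feature count must match
#'   the first layer's input width.
#' @return Matrix of class probabilities, samples x classes; rows sum to 1.
#' @export
forward <- function(weights, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(weights$W[[1]])) {
    stop("Feature dimension mismatch: input has ", ncol(x),
         " features, network expects ", nrow(weights$W[[1]]), ".",
         call. = FALSE)
  }
  mlp_forward(weights, x)$probs
}

# forward pass keeping the hidden activations for backprop
mlp_forward <- function(weights, x) {
  L <- length(weights$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% weights$W[[l]]
    z <- sweep(z, 2, weights$b[[l]], `+`)
    acts[[l + 1]] <- if (l < L) sigmoid(z) else softmax_rows(z)
  }
  list(probs = acts[[L + 1]], acts = acts)
}

# Gradient of the summed categorical cross-entropy -sum(Y * log P) with
# respect to every weight and bias, given a completed forward pass.
mlp_backprop <- function(weights, fw, y_onehot) {
  L <- length(weights$W)
  acts <- fw$acts
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- fw$probs - y_onehot          # softmax + cross-entropy
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      a <- acts[[l]]
      delta <- (delta %*% t(weights$W[[l]])) * a * (1 - a)
    }
  }
  list(W = gW, b = gb)
}

nll_loss <- function(probs, y_onehot, clip = 1e-12) {
  -sum(y_onehot * log(pmax(probs, clip)))
}

one_hot <- function(labels, class_names) {
  y <- matrix(0, length(labels), length(class_names))
  y[cbind(seq_along(labels), match(as.character(labels), class_names))] <- 1
  y
}

# Adam optimizer state over an arbitrary flat numeric vector
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

# flatten / unflatten a {W, b} weight list to a single numeric vector
flatten_weights <- function(w) {
  unlist(c(lapply(w$W, as.numeric), lapply(w$b, as.numeric)),
         use.names = FALSE)
}

unflatten_weights <- function(vec, template) {
  out <- template
  pos <- 1L
  for (l in seq_along(template$W)) {
    n <- length(template$W[[l]])
    out$W[[l]] <- matrix(vec[pos:(pos + n - 1L)], nrow(template$W[[l]]),
                         ncol(template$W[[l]]))
    pos <- pos + n
  }
  for (l in seq_along(template$b)) {
    n <- length(template$b[[l]])
    out$b[[l]] <- vec[pos:(pos + n - 1L)]
    pos <- pos + n
  }
  out
}

# deterministic mini-batch index blocks for one epoch
epoch_batches <- function(n, batch_size) {
  idx <- sample(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Training configuration for the neural classifiers
#'
#' @param epochs Number of passes over the training data.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param n_mc Monte-Carlo weight draws per loss evaluation during
#'   variational training (one draw per step is standard practice).
#' @param kl_scale Weight of the complexity (KL) term per mini-batch;
#'   `NULL` uses 1 / number-of-batches so the per-epoch KL weight is 1.
#' @param l2_strength L2 penalty for the point-estimate baselines.
#' @param seed Integer seed controlling initialization, batching and
#'   weight sampling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 150L, learning_rate = 1e-3,
                         batch_size = 128L, n_mc = 1L, kl_scale = NULL,
                         l2_strength = 1e-4, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, n_mc >= 1, learning_rate > 0,
            l2_strength >= 0)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), n_mc = as.integer(n_mc),
         kl_scale = kl_scale, l2_strength = l2_strength,
         seed = as.integer(seed)),
    class = "train_config"
  )
}
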