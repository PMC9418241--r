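test_that("variational initialization has the right shapes and properties", {
  p <- init_variational(c(7L, 5L, 3L), seed = 1)
  expect_s3_class(p, "variational_params")
  expect_equal(dim(p$mu$W[[1]]), c(7, 5))
  expect_equal(dim(p$mu$W[[2]]), c(5, 3))
  expect_length(p$mu$b[[1]], 5)
  expect_length(p$mu$b[[2]], 3)
  # posterior standard deviations strictly positive at initialization
  expect_true(all(softplus(unlist(p$rho)) > 0))
  expect_identical(init_variational(c(7L, 5L, 3L), seed = 1), p)
  expect_error(init_variational(5L), ">= 2 entries")
  expect_error(init_variational(c(3L, 0L)), ">= 2 entries")
})

test_that("reparameterized sampling collapses to mu as sigma -> 0 and is unbiased", {
  p <- init_variational(c(2L, 2L), seed = 2)
  # rho = -50 gives softplus(rho) ~ 2e-22: the draw is mu to machine precision
  p_tight <- p
  p_tight$rho$W[[1]][] <- -50
  p_tight$rho$b[[1]][] <- -50
  set.seed(1)
  w <- sample_weights(p_tight)
  expect_equal(w$W[[1]], p$mu$W[[1]], tolerance = 1e-15)
  expect_equal(w$b[[1]], p$mu$b[[1]], tolerance = 1e-15)

  # Monte-Carlo mean of one coordinate approaches mu within 4 sigma/sqrt(n)
  set.seed(3)
  n_draws <- 400
  draws <- replicate(n_draws, sample_weights(p)$W[[1]][1, 1])
  sigma <- softplus(p$rho$W[[1]][1, 1])
  expect_lt(abs(mean(draws) - p$mu$W[[1]][1, 1]),
            4 * sigma / sqrt(n_draws))
})

test_that("the forward pass matches hand-computed activations", {
  # 1-input, 2-hidden, 2-output, all weights 1, biases 0, input 1:
  # hidden = (sigmoid(1), sigmoid(1)), logits equal -> probabilities (0.5, 0.5)
  w <- list(W = list(matrix(1, 1, 2), matrix(1, 2, 2)),
            b = list(c(0, 0), c(0, 0)))
  x <- matrix(1, 1, 1)
  fw <- mlp_forward(w, x)
  expect_equal(as.numeric(fw$acts[[2]]), rep(1 / (1 + exp(-1)), 2),
               tolerance = 1e-12)
  expect_equal(as.numeric(fw$probs), c(0.5, 0.5), tolerance = 1e-12)

  # zero weights give uniform class probabilities; rows always sum to 1
  w0 <- list(W = list(matrix(0, 3, 4)), b = list(rep(0, 4)))
  p0 <- forward(w0, matrix(rnorm(6), 2, 3))
  expect_equal(p0, matrix(0.25, 2, 4), ignore_attr = TRUE)
  set.seed(4)
  wr <- list(W = list(matrix(rnorm(12), 3, 4)), b = list(rnorm(4)))
  pr <- forward(wr, matrix(rnorm(15), 5, 3))
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-12)

  # softmax shift invariance: adding a constant to all output biases
  ws <- wr
  ws$b[[1]] <- wr$b[[1]] + 7
  expect_equal(forward(ws, matrix(1:3, 1, 3)),
               forward(wr, matrix(1:3, 1, 3)), tolerance = 1e-12)

  expect_error(forward(wr, matrix(0, 1, 5)), "mismatch")
})

test_that("the variational loss vanishes when the posterior equals the prior", {
  p <- init_variational(c(3L, 4L, 2L), seed = 5)
  # mu = 0, sigma = 1: q(w) is exactly the standard-normal prior
  for (part in c("W", "b")) {
    for (l in seq_along(p$mu[[part]])) {
      p$mu[[part]][[l]][] <- 0
      p$rho[[part]][[l]][] <- log(expm1(1))
    }
  }
  empty_x <- matrix(0, 0, 3)
  empty_y <- matrix(0, 0, 2)
  set.seed(6)
  for (i in 1:5) {
    expect_equal(elbo_loss(p, empty_x, empty_y, n_mc = 1, kl_scale = 1), 0,
                 tolerance = 1e-10)
  }
})

test_that("single-weight log-density difference matches the hand value", {
  # mu = 1, sigma = 1, forced draw w = 1: log q - log p = 0.5
  p <- init_variational(c(1L, 1L), seed = 7)
  p$mu$W[[1]][] <- 1
  p$rho$W[[1]][] <- log(expm1(1))
  # isolate the single weight by making the bias coordinate inert
  p$mu$b[[1]][] <- 0
  p$rho$b[[1]][] <- log(expm1(1))
  w <- list(W = list(matrix(1, 1, 1)), b = list(0))
  diff <- log_q_density(w, p) - log_prior_density(w)
  expect_equal(diff, 0.5, tolerance = 1e-12)
})

test_that("Monte-Carlo KL estimate matches the analytic Gaussian KL", {
  p <- init_variational(c(2L, 2L), seed = 8)
  # analytic KL(q || p) summed over all independent coordinates
  kl_one <- function(m, s) 0.5 * (s^2 + m^2 - 1) - log(s)
  mus <- c(unlist(p$mu$W), unlist(p$mu$b))
  sigmas <- softplus(c(unlist(p$rho$W), unlist(p$rho$b)))
  kl_true <- sum(kl_one(mus, sigmas))
  set.seed(9)
  n_draws <- 2000
  vals <- replicate(n_draws, {
    w <- sample_weights(p)
    log_q_density(w, p) - log_prior_density(w)
  })
  se <- sd(vals) / sqrt(n_draws)
  expect_lt(abs(mean(vals) - kl_true), 4 * se)
})

test_that("exact loss gradients match central finite differences", {
  set.seed(10)
  p <- init_variational(c(2L, 2L), seed = 10)
  x <- matrix(rnorm(6), 3, 2)
  y <- one_hot(c("a", "b", "a"), c("a", "b"))
  eps <- sample_weights(p, return_eps = TRUE)$eps
  g <- elbo_loss_grad(p, x, y, eps, kl_scale = 0.5)

  h <- 1e-6
  perturb <- function(params, part, slot, l, idx, delta) {
    params[[part]][[slot]][[l]][idx] <- params[[part]][[slot]][[l]][idx] +
      delta
    params
  }
  for (part in c("mu", "rho")) {
    gname <- if (part == "mu") "g_mu" else "g_rho"
    for (slot in c("W", "b")) {
      for (idx in seq_along(p[[part]][[slot]][[1]])) {
        up <- elbo_loss_grad(perturb(p, part, slot, 1, idx, h), x, y, eps,
                             kl_scale = 0.5)$loss
        dn <- elbo_loss_grad(perturb(p, part, slot, 1, idx, -h), x, y, eps,
                             kl_scale = 0.5)$loss
        fd <- (up - dn) / (2 * h)
        an <- g[[gname]][[slot]][[1]][idx]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
      }
    }
  }
})

test_that("training reduces the loss, is deterministic and learns", {
  fx <- tiny_bnn_fixture()
  model <- fx$model
  expect_s3_class(model, "bnn_model")
  n_epochs <- length(model$loss_history)
  expect_lt(mean(model$loss_history[(n_epochs - 4):n_epochs]),
            mean(model$loss_history[1:5]))

  probs <- predict(model, fx$split$test)
  expect_equal(unname(rowSums(probs)), rep(1, n_samples(fx$split$test)),
               tolerance = 1e-9)
  pred <- model$class_names[max.col(probs, ties.method = "first")]
  expect_gte(overall_accuracy(fx$split$test$labels, pred), 0.95)

  # identical config reproduces identical parameters
  again <- train_bnn(fx$split$train, hidden_sizes = c(32L, 16L),
                     config = train_config(epochs = 100, batch_size = 32,
                                           seed = 3))
  expect_equal(again$params$mu, model$params$mu, tolerance = 1e-12)
})

test_that("a model archive round-trips through disk", {
  fx <- tiny_bnn_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fx$model, path)
  loaded <- load_model(path)
  expect_equal(predict(loaded, fx$split$test),
               predict(fx$model, fx$split$test))
})
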