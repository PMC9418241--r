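test_that("mc_predict has the contracted shape and is seed-deterministic", {
  fx <- tiny_bnn_fixture()
  mcp <- mc_predict(fx$model, fx$split$test, T = 20, seed = 5)
  n <- n_samples(fx$split$test)
  C <- length(fx$model$class_names)
  expect_equal(dim(mcp$draws), c(20L, n, C))
  # every (draw, sample) probability vector sums to 1
  expect_true(all(abs(apply(mcp$draws, c(1, 2), sum) - 1) < 1e-9))
  expect_equal(mcp$mean_probs, apply(mcp$draws, c(2, 3), mean))
  expect_identical(mc_predict(fx$model, fx$split$test, T = 20, seed = 5)$draws,
                   mcp$draws)
  expect_false(identical(
    mc_predict(fx$model, fx$split$test, T = 20, seed = 6)$draws, mcp$draws))
  expect_equal(eval(formals(mc_predict)$T), 500L)
  expect_error(mc_predict(fx$model, fx$split$test, T = 0), ">= 1")
})

test_that("the uncertainty matrix matches hand computation and is PSD", {
  # two draws (0.4, 0.6) and (0.6, 0.4)
  draws <- array(c(0.4, 0.6, 0.6, 0.4), c(2, 1, 2))
  mcp <- mcpred_from_draws(draws)
  m <- epistemic_matrix(mcp, 1)
  expect_equal(unname(m), matrix(c(0.01, -0.01, -0.01, 0.01), 2, 2),
               tolerance = 1e-12)

  # T = 1: no variation, zero matrix
  one <- mcpred_from_draws(array(c(0.3, 0.2, 0.5), c(1, 1, 3)))
  expect_equal(unname(epistemic_matrix(one, 1)), matrix(0, 3, 3))

  # random tensors: symmetric and positive semidefinite
  set.seed(13)
  raw <- array(runif(15 * 4 * 3), c(15, 4, 3))
  for (t in 1:15) for (s in 1:4) raw[t, s, ] <- raw[t, s, ] / sum(raw[t, s, ])
  mcp2 <- mcpred_from_draws(raw)
  for (s in 1:4) {
    m2 <- epistemic_matrix(mcp2, s)
    expect_equal(m2, t(m2))
    expect_true(all(eigen(m2, symmetric = TRUE,
                          only.values = TRUE)$values >= -1e-12))
  }
  expect_error(epistemic_matrix(mcp2, 99), "Invalid sample")
})

test_that("the scalar uncertainty matches its definition exactly", {
  # predicted-class draws 0.4 and 0.6 -> xi = 0.01
  draws <- array(c(0.4, 0.6, 0.6, 0.4), c(2, 1, 2))
  est <- epistemic_scalar(mcpred_from_draws(draws))
  expect_equal(est$samples$xi, 0.01, tolerance = 1e-12)

  # constant draws -> zero uncertainty
  const <- array(rep(c(0.7, 0.3), each = 5), c(5, 1, 2))
  expect_equal(epistemic_scalar(mcpred_from_draws(const))$samples$xi, 0)

  # xi equals the predicted-class diagonal of the full matrix, and the
  # class_variance columns reproduce all diagonals; xi <= 0.25 always
  set.seed(14)
  raw <- array(runif(12 * 5 * 4), c(12, 5, 4))
  for (t in 1:12) for (s in 1:5) raw[t, s, ] <- raw[t, s, ] / sum(raw[t, s, ])
  mcp <- mcpred_from_draws(raw)
  est2 <- epistemic_scalar(mcp)
  for (s in 1:5) {
    m <- epistemic_matrix(mcp, s)
    expect_equal(unname(est2$class_variance[s, ]), unname(diag(m)),
                 tolerance = 1e-12)
    i <- match(est2$samples$predicted_class[s], mcp$class_names)
    expect_equal(est2$samples$xi[s], unname(m[i, i]), tolerance = 1e-12)
  }
  expect_true(all(est2$samples$xi >= 0 & est2$samples$xi <= 0.25))
})

test_that("the training threshold is the mean uncertainty of correct calls", {
  est <- est_from_parts(
    mean_probs = matrix(c(0.9, 0.1, 0.8, 0.2, 0.3, 0.7),
                        3, 2, byrow = TRUE),
    class_variance = matrix(c(0.01, 0.002, 0.03, 0.004, 0.005, 0.05),
                            3, 2, byrow = TRUE),
    class_names = c("A", "B"))
  # predictions A, A, B with xi 0.01, 0.03, 0.05
  expect_equal(training_uncertainty_threshold(est, c("A", "A", "B")),
               mean(c(0.01, 0.03, 0.05)))
  # hand case {0.01, 0.03} -> 0.02
  expect_equal(training_uncertainty_threshold(est, c("A", "A", "X")), 0.02)
  # single correct sample -> its own xi
  expect_equal(training_uncertainty_threshold(est, c("A", "X", "X")), 0.01)
  # per-class variant
  pc <- training_uncertainty_threshold(est, c("A", "A", "B"),
                                       per_class = TRUE)
  expect_equal(unname(pc), c(0.02, 0.05))
  expect_error(training_uncertainty_threshold(est, c("B", "B", "A")),
               "No correctly classified")
  expect_error(training_uncertainty_threshold(est, "A"), "length")
})

test_that("filtering retains strictly-below-threshold samples only", {
  est <- est_from_parts(
    mean_probs = matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2, byrow = TRUE),
    class_variance = matrix(c(0.01, 0.002, 0.05, 0.004), 2, 2, byrow = TRUE),
    class_names = c("A", "B"))
  # xi = {0.01, 0.05}, threshold 0.02 -> retain first only
  fr <- filter_predictions(est, 0.02)
  expect_equal(fr$retained, c(TRUE, FALSE))
  expect_equal(fr$retained_fraction, 0.5)
  # vacuous filter
  expect_equal(filter_predictions(est, 1)$retained_fraction, 1)
  # boundary value is dropped (strict inequality)
  expect_false(filter_predictions(est, 0.01)$retained[1])
  # empty retained set allowed but flagged
  empty <- filter_predictions(est, 0)
  expect_true(empty$empty)
  expect_equal(empty$retained_fraction, 0)
  expect_error(filter_predictions(est, -1), "non-negative")
})

test_that("logit and its inverse satisfy the analytic identities", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.9), log(9), tolerance = 1e-12)
  expect_equal(inv_logit(0), 0.5)
  p <- seq(1e-6, 1 - 1e-6, length.out = 50)
  expect_equal(inv_logit(logit(p)), p, tolerance = 1e-9)
  # saturated inputs clip instead of diverging
  expect_true(is.finite(logit(0)) && is.finite(logit(1)))
  expect_error(logit(NaN), "Non-finite")
  expect_error(inv_logit(Inf), "Non-finite")
})

test_that("correction fit exactly recovers noiseless coefficients", {
  # construct logit(pbar) = 2 - 3 * sqrt(xi) exactly, one class of interest
  xi <- c(0.01, 0.04, 0.09, 0.16, 0.2)
  z <- 2 - 3 * sqrt(xi)
  pbar_a <- inv_logit(z)
  mean_probs <- cbind(pbar_a, 1 - pbar_a)
  class_variance <- cbind(xi, xi / 2)
  est <- est_from_parts(mean_probs, class_variance, c("A", "B"))
  model <- fit_correction(est)
  coefs <- model$coefficients
  a_row <- coefs[coefs$class == "A", ]
  expect_equal(a_row$alpha, 2, tolerance = 1e-10)
  expect_equal(a_row$beta, -3, tolerance = 1e-10)
  expect_equal(a_row$sigma2, 0, tolerance = 1e-16)
  expect_false(a_row$flagged)
  # class B never predicted: flagged with zero slope
  b_row <- coefs[coefs$class == "B", ]
  expect_true(b_row$flagged)
  expect_equal(b_row$beta, 0)
  expect_equal(b_row$n_points, 0L)
})

test_that("correction fit agrees with the normal-equations oracle", {
  set.seed(16)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    xi <- runif(n, 0.001, 0.2)
    pbar_a <- runif(n, 0.55, 0.99)  # all rows predicted as class A
    mean_probs <- cbind(pbar_a, 1 - pbar_a)
    est <- est_from_parts(mean_probs, cbind(xi, xi), c("A", "B"))
    model <- fit_correction(est)
    a_row <- model$coefficients[model$coefficients$class == "A", ]
    X <- cbind(1, sqrt(xi))
    beta_hat <- solve(t(X) %*% X, t(X) %*% logit(pbar_a))
    expect_equal(a_row$alpha, beta_hat[1], tolerance = 1e-10)
    expect_equal(a_row$beta, beta_hat[2], tolerance = 1e-10)
  }
})

test_that("fewer than three points per class flags a zero slope", {
  mean_probs <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2, byrow = TRUE)
  est <- est_from_parts(mean_probs, matrix(0.01, 2, 2), c("A", "B"))
  coefs <- fit_correction(est)$coefficients
  expect_true(all(coefs$flagged))
  expect_true(all(coefs$beta == 0))
})

test_that("applying the correction reproduces the hand-worked value", {
  # pbar = 0.6, xi = 0.04, beta = 1, canonical:
  # inv_logit(log(0.6/0.4) - 1 * 0.2) ~ 0.55119
  mean_probs <- matrix(c(0.6, 0.4), 1, 2)
  class_variance <- matrix(c(0.04, 0), 1, 2)
  est <- est_from_parts(mean_probs, class_variance, c("A", "B"))
  model <- structure(
    list(coefficients = tibble::tibble(
           class = c("A", "B"), alpha = c(0, 0), beta = c(1, 0),
           sigma2 = c(0, 0), n_points = c(5L, 5L),
           flagged = c(FALSE, FALSE)),
         class_names = c("A", "B"), scope = "constructed"),
    class = "correction_model")
  corr <- apply_correction(est, model, variant = "canonical")
  expect_equal(unname(corr$probs[1, "A"]),
               inv_logit(log(0.6 / 0.4) - 0.2), tolerance = 1e-12)
  expect_equal(unname(corr$probs[1, "A"]), 0.55119, tolerance = 1e-5)
})

test_that("correction variants behave as fixed points where they should", {
  set.seed(17)
  pbar_a <- runif(6, 0.3, 0.95)
  mean_probs <- cbind(pbar_a, 1 - pbar_a)
  class_variance <- cbind(runif(6, 0, 0.05), runif(6, 0, 0.05))
  est <- est_from_parts(mean_probs, class_variance, c("A", "B"))
  zero_model <- structure(
    list(coefficients = tibble::tibble(
           class = c("A", "B"), alpha = c(0, 0), beta = c(0, 0),
           sigma2 = c(0, 0), n_points = c(6L, 6L),
           flagged = c(FALSE, FALSE)),
         class_names = c("A", "B"), scope = "constructed"),
    class = "correction_model")
  # zero slope leaves canonical probabilities unchanged
  canon <- apply_correction(est, zero_model, variant = "canonical")
  expect_equal(unname(canon$probs), unname(mean_probs), tolerance = 1e-9)

  # zero uncertainty leaves canonical probabilities unchanged for any slope
  est0 <- est_from_parts(mean_probs, matrix(0, 6, 2), c("A", "B"))
  slope_model <- zero_model
  slope_model$coefficients$beta <- c(2, -1)
  canon0 <- apply_correction(est0, slope_model, variant = "canonical")
  expect_equal(unname(canon0$probs), unname(mean_probs), tolerance = 1e-9)

  # the literal variant maps through a different scale, but at zero
  # uncertainty it is monotone in pbar, so the class call cannot change
  lit0 <- apply_correction(est0, slope_model, variant = "literal")
  expect_equal(lit0$samples$corrected_class, lit0$samples$predicted_class)

  # corrected probabilities always lie strictly inside (0, 1)
  any_model <- slope_model
  for (variant in c("canonical", "literal")) {
    cp <- apply_correction(est, any_model, variant = variant)
    expect_true(all(cp$probs > 0 & cp$probs < 1))
    expect_equal(cp$samples$corrected_class,
                 est$class_names[max.col(cp$probs, ties.method = "first")])
  }

  wrong <- zero_model
  wrong$class_names <- c("X", "Y")
  expect_error(apply_correction(est, wrong), "do not match")
})
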