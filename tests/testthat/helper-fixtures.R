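# Shared fixtures, all built in code.

# small matrix with ids
toy_matrix <- function(n = 3, g = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(round(abs(rnorm(n * g, 6, 2)), 3), n, g,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", seq_len(g))))
  m
}

toy_dataset <- function(n_per_class = 10, g = 6, classes = c("A", "B"),
                        seed = 42) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  m <- matrix(abs(rnorm(n * g, 6, 1)), n, g,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", seq_len(g))))
  labeled_dataset(m, rep(classes, each = n_per_class))
}

# well-separated 3-class cohort used by several training tests
separated_spec <- function(seed = 11, n_per_class = 200L) {
  synthetic_spec(n_classes = 3, samples_per_class = rep(n_per_class, 3),
                 n_genes = 50, n_informative = 10, mean_shift = 4,
                 noise_sd = 1, seed = seed)
}

# one small trained BNN shared across tests (built on first use)
.fixture_env <- new.env(parent = emptyenv())

tiny_bnn_fixture <- function() {
  if (is.null(.fixture_env$bnn)) {
    ds <- generate_cohort(separated_spec(seed = 11, n_per_class = 60L))
    split <- stratified_split(ds, 0.8, seed = 2)
    model <- train_bnn(split$train, hidden_sizes = c(32L, 16L),
                       config = train_config(epochs = 100, batch_size = 32,
                                             seed = 3))
    .fixture_env$bnn <- list(model = model, split = split)
  }
  .fixture_env$bnn
}

# hand-constructed mc_predictions object from an explicit draw tensor
mcpred_from_draws <- function(draws, class_names = NULL) {
  stopifnot(length(dim(draws)) == 3)
  Tn <- dim(draws)[1]; n <- dim(draws)[2]; C <- dim(draws)[3]
  class_names <- class_names %||% paste0("K", seq_len(C))
  sample_ids <- paste0("s", seq_len(n))
  dimnames(draws) <- list(NULL, sample_ids, class_names)
  mean_probs <- apply(draws, c(2, 3), mean)
  structure(
    list(draws = draws, mean_probs = mean_probs,
         predicted_class = class_names[max.col(mean_probs,
                                               ties.method = "first")],
         class_names = class_names, sample_ids = sample_ids,
         T = Tn, seed = NA_integer_),
    class = "mc_predictions")
}

# hand-constructed uncertainty_estimate with explicit fields
est_from_parts <- function(mean_probs, class_variance, class_names) {
  pred_idx <- max.col(mean_probs, ties.method = "first")
  xi <- class_variance[cbind(seq_len(nrow(mean_probs)), pred_idx)]
  structure(
    list(samples = tibble::tibble(
           sample_id = paste0("s", seq_len(nrow(mean_probs))),
           predicted_class = class_names[pred_idx],
           xi = xi),
         class_variance = class_variance,
         mean_probs = mean_probs,
         class_names = class_names,
         T = NA_integer_),
    class = "uncertainty_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
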