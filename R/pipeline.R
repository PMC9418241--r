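#' Default pipeline configuration
#'
#' The declarative configuration consumed by [run_pipeline()]. The default
#' describes the package's reference synthetic benchmark: 5 classes, 200
#' samples each, 100 genes of which 20 are informative, one strongly
#' confusable class pair (overlap 0.9) emulating anatomically adjacent
#' tumour types, an 80:20 stratified split, the Bayesian network plus both
#' baselines, and 100 Monte-Carlo prediction iterations.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 7L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_classes = 5L, samples_per_class = rep(200L, 5),
                  n_genes = 100L, n_informative = 20L, mean_shift = 2,
                  noise_sd = 1,
                  confusable_pairs = list(list(1L, 2L, 0.9)),
                  baseline_mean = 6),
    data = list(expression = NULL, labels = NULL,
                orientation = "samples_by_genes"),
    select = list(enabled = FALSE, n_components = 10L, tolerance = 0.01,
                  k = 5L),
    split = list(train_fraction = 0.8),
    train = list(hidden_sizes = c(250L, 95L), epochs = 120L,
                 learning_rate = 1e-3, batch_size = 128L, n_mc = 1L,
                 dnn_hidden_sizes = c(250L, 55L), l2_strength = 1e-4,
                 baselines = TRUE),
    predict = list(T = 100L),
    correct = list(variant = "canonical")
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("Config not found: ", path, call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- default_pipeline_config(seed = user$seed %||% 7L)
  for (section in names(user)) {
    if (section == "seed") next
    if (!section %in% names(config)) {
      stop("Unknown config section: ", section, call. = FALSE)
    }
    if (!is.list(user[[section]])) {
      stop("Config section `", section, "` must be an object.",
           call. = FALSE)
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(config[[section]])) {
        stop("Unknown config key: ", section, ".", key, call. = FALSE)
      }
      config[[section]][[key]] <- user[[section]][[key]]
    }
  }
  config
}

#' Run the uncertainty-aware classification pipeline
#'
#' Executes the requested stages in order — simulate (or load data),
#' select, split, train (Bayesian network plus optional baselines),
#' predict (Monte-Carlo sampling), uncertainty, filter, correct,
#' evaluate — writing every artifact (cohort, gene lists, models, draw
#' tensors, uncertainty tables, reports, log) under `out_dir`, and
#' resuming from persisted state when invoked stage-by-stage.
#'
#' @param config A [default_pipeline_config()] list (or path to a JSON
#'   config).
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (default: all).
#' @return A list of class `pipeline_result` with the three
#'   [classification_report()]s (`uncorrected`, `filtered`, `corrected`),
#'   baseline accuracies, the filter threshold and retained fraction, and
#'   paths to the artifacts. Invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("pipeline_"),
                         stages = c("simulate", "select", "split", "train",
                                    "predict", "uncertainty", "filter",
                                    "correct", "evaluate")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  all_stages <- c("simulate", "select", "split", "train", "predict",
                  "uncertainty", "filter", "correct", "evaluate")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("Unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(out_dir, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  seed <- config$seed

  if ("simulate" %in% stages) {
    if (!is.null(config$data$expression)) {
      state$dataset <- read_labeled_dataset(config$data$expression,
                                            config$data$labels,
                                            config$data$orientation)
      log_line("loaded dataset from ", config$data$expression)
    } else {
      spec <- do.call(synthetic_spec, c(config$cohort, list(seed = seed)))
      state$dataset <- generate_cohort(spec)
      write_cohort(state$dataset, file.path(out_dir, "cohort"))
      log_line("simulated cohort, seed ", seed)
    }
  }

  if ("select" %in% stages && isTRUE(config$select$enabled)) {
    sel <- two_step_select(state$dataset,
                           n_components = config$select$n_components,
                           k = config$select$k,
                           tolerance = config$select$tolerance,
                           seed = seed)
    state$selection <- sel
    state$dataset <- subset_genes(state$dataset, sel$selected_genes)
    write_feature_selection(sel, file.path(out_dir, "selection"))
    log_line("selected ", length(sel$selected_genes), " genes")
  }

  if ("split" %in% stages) {
    state$split <- stratified_split(state$dataset,
                                    config$split$train_fraction,
                                    seed = seed)
    readr::write_tsv(
      dplyr::select(tidy(state$split), "sample_id", "partition"),
      file.path(out_dir, "split_manifest.tsv"), progress = FALSE)
    log_line("split ", n_samples(state$split$train), "/",
             n_samples(state$split$test))
  }

  if ("train" %in% stages) {
    tc <- config$train
    cfg <- train_config(epochs = tc$epochs,
                        learning_rate = tc$learning_rate,
                        batch_size = tc$batch_size, n_mc = tc$n_mc,
                        l2_strength = tc$l2_strength, seed = seed)
    state$bnn <- train_bnn(state$split$train,
                           hidden_sizes = tc$hidden_sizes, config = cfg)
    save_model(state$bnn, file.path(out_dir, "bnn_model.rds"))
    log_line("trained BNN, final loss ",
             format(utils::tail(state$bnn$loss_history, 1)))
    if (isTRUE(tc$baselines)) {
      state$dnn <- train_dnn_baseline(state$split$train,
                                      hidden_sizes = tc$dnn_hidden_sizes,
                                      config = cfg)
      state$logreg <- train_logreg_baseline(state$split$train, config = cfg)
      save_model(state$dnn, file.path(out_dir, "dnn_model.rds"))
      save_model(state$logreg, file.path(out_dir, "logreg_model.rds"))
      log_line("trained DNN and logistic-regression baselines")
    }
  }

  if ("predict" %in% stages) {
    T <- config$predict$T
    state$mc_train <- mc_predict(state$bnn, state$split$train, T = T,
                                 seed = seed + 1L)
    state$mc_test <- mc_predict(state$bnn, state$split$test, T = T,
                                seed = seed + 2L)
    saveRDS(state$mc_test, file.path(out_dir, "mc_test.rds"))
    log_line("Monte-Carlo prediction, T = ", T)
  }

  if ("uncertainty" %in% stages) {
    state$est_train <- epistemic_scalar(state$mc_train)
    state$est_test <- epistemic_scalar(state$mc_test)
    readr::write_tsv(tidy(state$est_test),
                     file.path(out_dir, "uncertainty_test.tsv"),
                     progress = FALSE)
    log_line("epistemic uncertainty computed")
  }

  if ("filter" %in% stages) {
    state$threshold <- training_uncertainty_threshold(
      state$est_train, state$split$train$labels)
    state$filter <- filter_predictions(state$est_test, state$threshold)
    readr::write_tsv(state$filter$samples,
                     file.path(out_dir, "filter_mask.tsv"),
                     progress = FALSE)
    log_line("filter threshold ", format(state$threshold),
             "; retained fraction ",
             format(state$filter$retained_fraction))
  }

  if ("correct" %in% stages) {
    state$correction <- fit_correction(state$est_train)
    state$corrected <- apply_correction(state$est_test, state$correction,
                                        variant = config$correct$variant)
    readr::write_tsv(tidy(state$correction),
                     file.path(out_dir, "correction_coefficients.tsv"),
                     progress = FALSE)
    log_line("uncertainty correction applied (",
             config$correct$variant, ")")
  }

  result <- NULL
  if ("evaluate" %in% stages) {
    test <- state$split$test
    y_true <- as.character(test$labels)
    cls <- test$class_names
    prov <- list(seed = seed, T = config$predict$T,
                 train_fraction = config$split$train_fraction)

    uncorrected <- classification_report(
      y_true, state$est_test$samples$predicted_class, cls,
      retained_fraction = 1, provenance = prov)
    keep <- state$filter$retained
    filtered <- if (any(keep)) {
      classification_report(
        y_true[keep], state$est_test$samples$predicted_class[keep], cls,
        retained_fraction = state$filter$retained_fraction,
        provenance = prov)
    } else NULL
    corrected <- classification_report(
      y_true, state$corrected$samples$corrected_class, cls,
      retained_fraction = 1, provenance = prov)

    write_report(uncorrected, out_dir, "uncorrected")
    if (!is.null(filtered)) write_report(filtered, out_dir, "filtered")
    write_report(corrected, out_dir, "corrected")

    baseline_accuracy <- list()
    if (!is.null(state$dnn)) {
      p <- predict(state$dnn, test)
      baseline_accuracy$dnn <- overall_accuracy(
        y_true, cls[max.col(p, ties.method = "first")])
      p <- predict(state$logreg, test)
      baseline_accuracy$logreg <- overall_accuracy(
        y_true, cls[max.col(p, ties.method = "first")])
    }

    result <- structure(
      list(uncorrected = uncorrected, filtered = filtered,
           corrected = corrected,
           baseline_accuracy = baseline_accuracy,
           threshold = state$threshold,
           retained_fraction = state$filter$retained_fraction,
           out_dir = out_dir, seed = seed),
      class = "pipeline_result")
    state$result <- result
    log_line("evaluation written: accuracy ",
             format(uncorrected$overall_accuracy), " -> corrected ",
             format(corrected$overall_accuracy))
  }

  saveRDS(state, state_path)
  invisible(state$result %||% state)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$seed, "\n", sep = "")
  cat("  uncorrected accuracy: ",
      format(x$uncorrected$overall_accuracy, digits = 4), "\n", sep = "")
  if (!is.null(x$filtered)) {
    cat("  filtered accuracy:    ",
        format(x$filtered$overall_accuracy, digits = 4),
        "  (retained ", format(x$retained_fraction, digits = 3), ")\n",
        sep = "")
  }
  cat("  corrected accuracy:   ",
      format(x$corrected$overall_accuracy, digits = 4), "\n", sep = "")
  for (nm in names(x$baseline_accuracy)) {
    cat("  ", nm, " accuracy: ",
        format(x$baseline_accuracy[[nm]], digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    seed = x$seed,
    accuracy = x$uncorrected$overall_accuracy,
    filtered_accuracy = if (!is.null(x$filtered)) {
      x$filtered$overall_accuracy
    } else NA_real_,
    retained_fraction = x$retained_fraction,
    corrected_accuracy = x$corrected$overall_accuracy,
    dnn_accuracy = x$baseline_accuracy$dnn %||% NA_real_,
    logreg_accuracy = x$baseline_accuracy$logreg %||% NA_real_
  )
}
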