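test_that("a dominant-variance gene tops the first-component ranking", {
  set.seed(5)
  n <- 60
  x <- matrix(abs(rnorm(n * 10, 6, 0.1)), n, 10,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:10)))
  x[, "g3"] <- abs(rnorm(n, 6, 10))  # 100x the variance of the rest
  ranked <- pca_top_loading_genes(x, n_components = 1,
                                  genes_per_component = 10)
  expect_identical(ranked[1], "g3")
})

test_that("PCA ranking agrees with an eigen-decomposition oracle", {
  set.seed(6)
  n <- 40; g <- 12
  x <- matrix(abs(rnorm(n * g, 6, 2)), n, g,
              dimnames = list(paste0("s", 1:n), paste0("gene", 1:g)))
  ranked <- pca_top_loading_genes(x, n_components = 3,
                                  genes_per_component = 4)

  centered <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(centered) / (n - 1), symmetric = TRUE)
  oracle <- character(0)
  for (k in 1:3) {
    load_k <- abs(eig$vectors[, k])
    names(load_k) <- colnames(x)
    top <- names(sort(load_k, decreasing = TRUE))[1:4]
    oracle <- c(oracle, setdiff(top, oracle))
  }
  expect_identical(ranked, oracle)
  expect_lte(length(ranked), 12)
  expect_false(anyDuplicated(ranked) > 0)
})

test_that("the plateau rule picks the smallest near-best count", {
  trace <- tibble::tibble(n_genes = c(5L, 10L, 20L, 40L),
                          accuracy = c(0.80, 0.95, 0.955, 0.956))
  expect_equal(choose_plateau_count(trace, tolerance = 0.01), 10L)
  # zero tolerance demands the exact maximum
  expect_equal(choose_plateau_count(trace, tolerance = 0), 40L)
  # a constant trace plateaus immediately
  flat <- tibble::tibble(n_genes = c(2L, 4L, 8L), accuracy = rep(0.9, 3))
  expect_equal(choose_plateau_count(flat, tolerance = 0.01), 2L)
  # order of rows must not matter
  shuffled <- trace[c(3, 1, 4, 2), ]
  expect_equal(choose_plateau_count(shuffled, tolerance = 0.01), 10L)
  expect_error(choose_plateau_count(trace[0, ]), "Empty")
  expect_error(choose_plateau_count(trace, tolerance = -1), ">= 0")
})

test_that("CV accuracy trace is valid and improves with informative genes", {
  ds <- generate_cohort(separated_spec(seed = 13, n_per_class = 40L))
  informative <- attr(ds, "informative_genes")
  ranking <- c(informative, setdiff(colnames(ds$x), informative))
  trace <- cv_accuracy_for_gene_counts(ds, ranking,
                                       counts_grid = c(1, 5, 10, 30),
                                       k = 5, seed = 7)
  expect_s3_class(trace, "accuracy_trace")
  expect_equal(trace$n_genes, c(1L, 5L, 10L, 30L))
  expect_true(all(trace$accuracy >= 0 & trace$accuracy <= 1))
  # all 10 informative genes should separate 3 well-separated classes
  expect_gte(trace$accuracy[trace$n_genes == 10], 0.95)
  # a single-count grid works
  one <- cv_accuracy_for_gene_counts(ds, ranking, counts_grid = 5,
                                     k = 5, seed = 7)
  expect_equal(nrow(one), 1L)
  expect_error(cv_accuracy_for_gene_counts(ds, ranking, integer(0)), "Empty")
  expect_error(cv_accuracy_for_gene_counts(ds, ranking, 10^6), "counts_grid")
})

test_that("two-step selection nests its gene sets and recovers signal", {
  spec <- synthetic_spec(n_classes = 3, samples_per_class = rep(60L, 3),
                         n_genes = 120, n_informative = 6, mean_shift = 3,
                         noise_sd = 1, seed = 23)
  ds <- generate_cohort(spec)
  res <- two_step_select(ds, n_components = 5,
                         step1_grid = c(5, 10, 20, 40, 80),
                         step2_grid = c(2, 5, 10, 20),
                         k = 5, seed = 7)
  expect_s3_class(res, "feature_selection_result")
  expect_true(all(res$selected_genes %in% res$step1_genes))
  expect_true(all(res$step1_genes %in% colnames(ds$x)))
  expect_lte(length(res$selected_genes), length(res$step1_genes))
  # the plateau rule minimizes the gene count, so with redundant signal it
  # may keep only a subset of the informative genes — but everything it
  # keeps must be informative, and accuracy must not have been sacrificed
  informative <- attr(ds, "informative_genes")
  expect_true(all(res$selected_genes %in% informative))
  expect_gte(max(res$trace_step2$accuracy), 0.95)
  m2 <- res$trace_step2$accuracy[res$trace_step2$n_genes ==
                                   length(res$selected_genes)]
  expect_gte(m2, max(res$trace_step2$accuracy) - res$plateau_tolerance)
  # tidy stacks both traces
  td <- tidy(res)
  expect_setequal(unique(td$step), c(1L, 2L))
})

test_that("two-step selection is deterministic given a seed", {
  ds <- generate_cohort(separated_spec(seed = 29, n_per_class = 30L))
  a <- two_step_select(ds, n_components = 3, step1_grid = c(5, 10, 25),
                       step2_grid = c(2, 5), k = 3, seed = 11)
  b <- two_step_select(ds, n_components = 3, step1_grid = c(5, 10, 25),
                       step2_grid = c(2, 5), k = 3, seed = 11)
  expect_identical(a$selected_genes, b$selected_genes)
  expect_equal(a$trace_step1$accuracy, b$trace_step1$accuracy)
})

test_that("single-gene screen flags disjoint-support markers only", {
  # class A lives near 0, class B near 20 on gene g1: perfect 1-gene marker;
  # g2 is pure noise shared by both classes
  set.seed(8)
  n <- 40
  x <- cbind(g1 = c(abs(rnorm(n, 1, 0.3)), abs(rnorm(n, 20, 0.3))),
             g2 = abs(rnorm(2 * n, 6, 1)))
  rownames(x) <- paste0("s", seq_len(2 * n))
  ds <- labeled_dataset(x, rep(c("A", "B"), each = n))
  screen <- single_feature_screen(ds, pr_threshold = 0.75, k = 5, seed = 3)
  expect_setequal(names(screen),
                  c("gene", "class", "precision", "recall", "f1",
                    "qualifies"))
  g1_rows <- screen[screen$gene == "g1", ]
  expect_true(all(g1_rows$qualifies))
  expect_true(all(g1_rows$precision == 1 & g1_rows$recall == 1))
  g2_rows <- screen[screen$gene == "g2", ]
  expect_false(any(g2_rows$qualifies))
})
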