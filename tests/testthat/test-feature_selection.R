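test_that("standardization centers and scales, and is reversible", {
  expect_equal(unname(standardize_features(
    matrix(c(1, 3), 2, 1, dimnames = list(NULL, "f")))$x[, 1]),
    c(-1, 1))
  withr::with_seed(71, {
    x <- matrix(rnorm(50 * 6, mean = 3, sd = 9), 50, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
  })
  std <- standardize_features(x)
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  expect_true(all(abs(colMeans(std$x)) <= 1e-10))
  expect_true(all(abs(apply(std$x, 2, sd_pop) - 1) <= 1e-10))
  # idempotent on already-standardized input
  again <- standardize_features(std$x)
  expect_equal(again$x, std$x, tolerance = 1e-10)
  x[, 2] <- 5
  expect_error(standardize_features(x), "f2")
})

test_that("stratified folds preserve class proportions and determinism", {
  labels <- rep(c(0L, 1L), each = 50)
  folds <- make_folds(labels, n_folds = 15, test_fraction = 0.2, seed = 9)
  expect_length(folds, 15L)
  for (f in folds) {
    expect_length(f$train, 80L)
    expect_length(f$test, 20L)
    expect_equal(sum(labels[f$test] == 1L), 10L)
    expect_equal(sum(labels[f$test] == 0L), 10L)
    expect_setequal(c(f$train, f$test), seq_along(labels))
  }
  again <- make_folds(labels, 15, 0.2, seed = 9)
  expect_identical(folds, again)
  different <- make_folds(labels, 15, 0.2, seed = 10)
  expect_false(identical(folds, different))

  expect_error(make_folds(rep(1L, 40), 5), "Both classes")
  expect_error(make_folds(c(rep(0L, 3), rep(1L, 50)), 5), "at least")
})

test_that("L1 regression shrinks fully at huge lambda and matches OLS at 0", {
  rows <- planted_rows(n = 40, p = 6, signal_col = 3, beta = 3, seed = 81)
  std <- standardize_features(rows$x)
  full <- fit_lasso_fold(std$x, rows$y, 1e6)
  expect_true(all(full$coefficients == 0))

  ols_fit <- fit_lasso_fold(std$x, rows$y, 0)
  ols <- coef(stats::lm(rows$y ~ std$x))
  expect_equal(unname(c(ols_fit$intercept, ols_fit$coefficients)),
               unname(ols), tolerance = 1e-6)
})

test_that("L1 regression recovers a planted signal column", {
  rows <- planted_rows(n = 120, p = 15, signal_col = 7, beta = 3, seed = 83)
  std <- standardize_features(rows$x)
  fit <- fit_lasso_fold(std$x, rows$y, 5)
  expect_true(fit$coefficients["f7"] != 0)
  expect_equal(names(which.max(abs(fit$coefficients))), "f7")
})

test_that("LASSO sparsity is monotone non-increasing in lambda", {
  rows <- planted_rows(n = 100, p = 20, signal_col = 5, beta = 2, seed = 87)
  std <- standardize_features(rows$x)
  grid <- 10^seq(-4, 2, length.out = 13)
  nnz <- vapply(grid, function(l) {
    sum(fit_lasso_fold(std$x, rows$y, l)$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("linear SVM aligns with the informative axis and shrinks with C", {
  x <- matrix(c(-2, -1.5, 1.5, 2, 0.1, -0.1, 0.05, -0.05), 4, 2,
              dimnames = list(NULL, c("sig", "noise")))
  y <- c(0L, 0L, 1L, 1L)
  fit <- fit_svm_fold(x, y, cost = 10)
  expect_gt(fit$coefficients["sig"], 0)
  expect_gt(abs(fit$coefficients["sig"]), 10 * abs(fit$coefficients["noise"]))

  rows <- planted_rows(n = 100, p = 10, signal_col = 4, beta = 3, seed = 91)
  std <- standardize_features(rows$x)
  big <- fit_svm_fold(std$x, rows$y, 1)
  expect_equal(names(which.max(abs(big$coefficients))), "f4")
  tiny <- fit_svm_fold(std$x, rows$y, 1e-4)
  expect_lt(sqrt(sum(tiny$coefficients^2)),
            0.05 * sqrt(sum(big$coefficients^2)))
  expect_error(fit_svm_fold(std$x, rep(1L, 100), 1), "single class")
})

test_that("grid search picks the accuracy maximizer with regularized ties", {
  rows <- planted_rows(n = 150, p = 10, signal_col = 2, beta = 4, seed = 93)
  std <- standardize_features(rows$x)
  folds <- make_folds(rows$y, 5, 0.2, seed = 3)

  one <- selection_config("lasso", n_folds = 5, grid = 0.5, seed = 3)
  expect_equal(grid_search(std$x, rows$y, folds, one)$value, 0.5)

  cfg <- selection_config("lasso", n_folds = 5, seed = 3)
  gs <- grid_search(std$x, rows$y, folds, cfg)
  expect_true(gs$value %in% cfg$grid)
  expect_equal(nrow(gs$table), length(cfg$grid))
  # tie rule: the most regularized value within one SE of the best wins
  se_best <- gs$table$se[which.max(gs$table$accuracy)]
  within <- gs$table$grid[gs$table$accuracy >=
                            max(gs$table$accuracy) - se_best - 1e-12]
  expect_equal(gs$value, max(within))
  expect_gte(gs$value, max(gs$table$grid[gs$table$accuracy >=
                                           max(gs$table$accuracy) - 1e-12]))
})

test_that("consensus is the intersection of per-fold supports", {
  sd_small <- small_sim_design(seed = 101)
  sel <- select_features(sd_small$design,
                         selection_config("lasso", n_folds = 5, seed = 11))
  expect_s3_class(sel, "ppi_selection")
  # every consensus feature is supported in all folds
  expect_true(all(sel$per_fold_support[sel$consensus_features] == 5))
  # and no non-consensus feature is
  non <- setdiff(sel$feature_names, sel$consensus_features)
  expect_true(all(sel$per_fold_support[non] < 5))

  td <- tidy(sel)
  expect_true(all(td$feature %in% sel$consensus_features))
  expect_equal(glance(sel)$n_consensus, length(sel$consensus_features))
})

test_that("selection is deterministic given the seed", {
  sd_small <- small_sim_design(seed = 103)
  cfg <- selection_config("lasso", n_folds = 4, seed = 17)
  s1 <- select_features(sd_small$design, cfg)
  s2 <- select_features(sd_small$design, cfg)
  expect_identical(s1$consensus_features, s2$consensus_features)
  expect_identical(s1$scores, s2$scores)
  expect_identical(s1$coefficients, s2$coefficients)
})

test_that("planted DPC features are recovered with planted-direction signs", {
  sd_small <- small_sim_design(seed = 107, n_proteins = 150,
                               n_pairs_per_class = 150)
  planted <- sd_small$sim$truth$planted
  for (method in c("lasso", "svm")) {
    sel <- select_features(sd_small$design,
                           selection_config(method, n_folds = 5, seed = 19))
    expect_gte(sum(planted %in% sel$consensus_features), 3)
    # interaction favors similar compositions: planted scores negative
    expect_true(all(sel$scores[intersect(planted,
                                         sel$consensus_features)] < 0))
  }
})

test_that("label permutation leaves no stable consensus", {
  sd_small <- small_sim_design(seed = 109)
  design <- sd_small$design
  withr::with_seed(23, design$label <- sample(design$label))
  sel <- suppressWarnings(
    select_features(design, selection_config("lasso", n_folds = 5,
                                             seed = 29)))
  expect_lte(length(sel$consensus_features), 2L)
})
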