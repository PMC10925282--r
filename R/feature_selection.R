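# Bagged feature selection: L1-penalized regression (LASSO) or linear SVM
# fits across stratified shuffled cross-validation folds; a feature is
# selected only if its coefficient is non-zero in every fold (intersection
# bagging rule).

#' Selection configuration
#'
#' @param method `"lasso"` (L1-penalized squared-error regression on the 0/1
#'   labels, the printed selection objective) or `"svm"` (linear soft-margin
#'   SVM).
#' @param n_folds Number of stratified shuffled folds (>= 2 so bagging is
#'   meaningful).
#' @param test_fraction Fraction of rows held out per fold (default 0.2, the
#'   80/20 convention).
#' @param grid Regularization grid. For LASSO, values of the penalty
#'   `lambda` on the scale of the objective `RSS + lambda * sum(|w|)`
#'   (default 13 log-spaced points in `10^-4 .. 10^2`); for SVM, values of
#'   cost `C` (default 11 log-spaced points in `10^-3 .. 10^2`). Both default
#'   grids bracket the operating points `lambda ~ 0.004` and `C = 0.1`
#'   commonly reported for this procedure.
#' @param seed Integer seed; all shuffling flows from it.
#' @param standardize Standardize features to mean 0, sd 1 before fitting
#'   (default `TRUE`).
#' @param per_fold_grid If `TRUE`, re-run the grid search inside every fold
#'   instead of once over the fold ensemble.
#' @return An object of class `ppi_selection_config`.
#' @export
selection_config <- function(method = c("lasso", "svm"),
                             n_folds = 15L,
                             test_fraction = 0.2,
                             grid = NULL,
                             seed = 1L,
                             standardize = TRUE,
                             per_fold_grid = FALSE) {
  method <- match.arg(method)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) {
    stop("n_folds must be at least 2 so that bagging can be applied",
         call. = FALSE)
  }
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (is.null(grid)) {
    grid <- if (method == "lasso") {
      10^seq(-4, 2, length.out = 13)
    } else {
      10^seq(-3, 2, length.out = 11)
    }
  }
  if (length(grid) == 0L || any(grid <= 0)) {
    stop("Regularization grid must be non-empty and strictly positive",
         call. = FALSE)
  }
  structure(list(method = method, n_folds = n_folds,
                 test_fraction = test_fraction, grid = sort(grid),
                 seed = as.integer(seed), standardize = standardize,
                 per_fold_grid = per_fold_grid),
            class = "ppi_selection_config")
}

#' Standardize feature columns to mean 0, sd 1
#'
#' Uses the population (n-denominator) standard deviation, so a two-value
#' column such as \{1, 3\} standardizes exactly to \{-1, 1\}.
#'
#' @param x Numeric matrix (rows = pairs) with no constant columns.
#' @return A list with elements `x` (standardized matrix), `center`, `scale`,
#'   so the same transform can be applied to held-out rows.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("Standardization needs at least 2 rows",
                         call. = FALSE)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center, "-")^2))
  zero <- scale == 0
  if (any(zero)) {
    stop("Zero-variance feature(s) should have been dropped upstream: ",
         paste(head(colnames(x)[zero], 5), collapse = ", "), call. = FALSE)
  }
  list(x = sweep(sweep(x, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

#' Stratified shuffled train/test folds
#'
#' Each fold is an independent random split that holds out `test_fraction`
#' of each class, so train and test label proportions match the full set
#' within one sample. Deterministic given `seed`.
#'
#' @param labels Integer vector of 0/1 labels.
#' @param n_folds Number of folds (>= 2).
#' @param test_fraction Held-out fraction per class.
#' @param seed Integer seed.
#' @return A list of length `n_folds`; each element has integer vectors
#'   `train` and `test`.
#' @export
make_folds <- function(labels, n_folds, test_fraction = 0.2, seed = 1L) {
  labels <- as.integer(labels)
  n_folds <- as.integer(n_folds)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts == 0L)) {
    stop("Both classes must be present to stratify", call. = FALSE)
  }
  if (any(counts < n_folds)) {
    stop("Each class needs at least n_folds = ", n_folds, " members",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_folds), function(k) {
      test <- unlist(lapply(c(0L, 1L), function(cl) {
        idx <- which(labels == cl)
        sample(idx, size = max(1L, round(length(idx) * test_fraction)))
      }))
      test <- sort(test)
      list(train = setdiff(seq_along(labels), test), test = test)
    })
  })
}

#' Fit one L1-penalized regression fold
#'
#' Minimizes `sum_i (y_i - w0 - sum_j w_j x_ij)^2 + lambda * sum_j |w_j|`
#' over the training rows (regression on the 0/1 labels). Solved by
#' coordinate descent via glmnet; the user-facing `lambda` is on the scale of
#' that objective and is converted internally to glmnet's per-observation
#' parameterization. `lambda = 0` gives the ordinary least-squares fit.
#'
#' @param x Standardized numeric feature matrix (training rows).
#' @param y 0/1 labels.
#' @param lambda Penalty weight (>= 0).
#' @return A list with `coefficients` (named vector), `intercept`,
#'   `regularization` and `method = "lasso"`.
#' @export
fit_lasso_fold <- function(x, y, lambda) {
  x <- as.matrix(x)
  l <- nrow(x)
  lam_g <- lambda / (2 * l)
  path <- if (lam_g > 0) {
    lam_g * c(128, 32, 8, 2, 1)
  } else {
    c(max(abs(crossprod(x, y - mean(y)))) / l, 0.1, 0.01, 0.001, 0)
  }
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = path, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12, maxit = 1e6)
  cf <- as.numeric(coef(fit, s = lam_g))
  list(coefficients = setNames(cf[-1], colnames(x)),
       intercept = cf[1], regularization = lambda, method = "lasso")
}

#' Fit one linear soft-margin SVM fold
#'
#' Minimizes `(1/2) ||w||^2 + C * sum_i xi_i` on the training rows. The
#' primal weight vector is recovered from the support vectors and oriented
#' so that a positive decision value predicts label 1.
#'
#' @param x Standardized numeric feature matrix (training rows).
#' @param y 0/1 labels (both classes must be present).
#' @param cost Regularization parameter C (> 0).
#' @return A list with `coefficients` (named vector `w`), `intercept`,
#'   `regularization`, `method = "svm"` and the fitted `model`.
#' @export
fit_svm_fold <- function(x, y, cost) {
  x <- as.matrix(x)
  yf <- factor(y, levels = c(0L, 1L))
  if (nlevels(droplevels(yf)) < 2L) {
    stop("Training split contains a single class", call. = FALSE)
  }
  m <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # e1071: positive decision values vote for the first of m$levels[m$labels];
  # flip so that positive margins predict class "1".
  pos_class <- m$levels[m$labels[1]]
  if (pos_class != "1") {
    w <- -w
    b <- -b
  }
  list(coefficients = setNames(w, colnames(x)), intercept = b,
       regularization = cost, method = "svm", model = m)
}

.fold_fit <- function(x, y, method, reg) {
  if (method == "lasso") fit_lasso_fold(x, y, reg)
  else fit_svm_fold(x, y, reg)
}

.fold_predict <- function(fit, x) {
  score <- drop(as.matrix(x) %*% fit$coefficients) + fit$intercept
  if (fit$method == "lasso") as.integer(score > 0.5) else
    as.integer(score > 0)
}

# Support set of a fit. LASSO: exactly-zero coefficients are dropped by the
# penalty itself. The SVM's dense weight vector is never exactly zero in
# floating point, so "non-zero" needs a data-driven cut: a weight counts as
# selected when it exceeds the bulk of the weight distribution by two
# standard deviations (scale-free, and under a label-permutation null no
# weight survives the cut in every fold).
.fit_support <- function(fit) {
  w <- abs(fit$coefficients)
  if (fit$method == "lasso") return(w != 0)
  if (length(w) < 3L) return(w > 0)
  w > mean(w) + 2 * sd(w)
}

#' Grid search for the regularization parameter
#'
#' For each grid value, fits the configured model on every fold's training
#' side and measures accuracy on its held-out side. Among all grid values
#' whose mean validation accuracy is statistically indistinguishable from
#' the best — within one per-fold standard deviation of the accuracy at the
#' maximizer, a one-SE-style rule with a dependence-honest scale (shuffled
#' folds share most of their training data) — the most regularized value
#' wins: largest lambda for LASSO, smallest C for the SVM. Exact ties are
#' the degenerate case. This keeps selected models as sparse as the
#' validation signal allows; under a no-signal null, where the whole grid
#' is statistically tied, it drives selection to the fully shrunk end.
#'
#' @param x Standardized feature matrix.
#' @param y 0/1 labels.
#' @param folds Folds from [make_folds()].
#' @param config A [selection_config()].
#' @return A list with `value` (chosen grid point) and `table` (tibble of
#'   grid values and mean validation accuracies).
#' @export
grid_search <- function(x, y, folds, config) {
  grid <- config$grid
  if (config$method == "lasso") {
    # one coordinate-descent path per fold covers the whole grid
    acc_mat <- matrix(vapply(folds, function(f) {
      l <- length(f$train)
      fit <- glmnet::glmnet(x[f$train, , drop = FALSE], y[f$train],
                            family = "gaussian", alpha = 1,
                            lambda = sort(grid / (2 * l), decreasing = TRUE),
                            standardize = FALSE, intercept = TRUE,
                            thresh = 1e-9, maxit = 1e6)
      pred <- predict(fit, x[f$test, , drop = FALSE], s = grid / (2 * l))
      colMeans((pred > 0.5) == y[f$test])
    }, numeric(length(grid))), nrow = length(grid))
  } else {
    acc_mat <- matrix(vapply(grid, function(g) {
      vapply(folds, function(f) {
        fit <- .fold_fit(x[f$train, , drop = FALSE], y[f$train],
                         config$method, g)
        mean(.fold_predict(fit, x[f$test, , drop = FALSE]) == y[f$test])
      }, numeric(1))
    }, numeric(length(folds))), ncol = length(grid))
    acc_mat <- t(acc_mat)
  }
  acc <- rowMeans(acc_mat)
  i_best <- which.max(acc)
  # Tie radius: the single-fold SD at the best point. Shuffled folds share
  # most of their training data, so dividing by sqrt(n_folds) would
  # overstate the precision of the CV mean; the per-fold SD is an honest
  # scale for "statistically indistinguishable" accuracies.
  radius <- sd(acc_mat[i_best, ])
  if (!is.finite(radius)) radius <- 0
  within <- acc >= max(acc) - radius - 1e-12
  value <- if (config$method == "lasso") max(grid[within]) else
    min(grid[within])
  list(value = value,
       table = tibble::tibble(grid = grid, accuracy = acc,
                              se = apply(acc_mat, 1, sd)))
}

#' Bagged feature selection across cross-validation folds
#'
#' Implements the full selection procedure: standardize the design matrix,
#' draw stratified shuffled folds, grid-search the regularization parameter
#' over the fold ensemble, fit the configured model (L1 regression or linear
#' SVM) on every fold's training side at the chosen value, and retain the
#' consensus set — features whose coefficient is non-zero (LASSO) or above
#' the relative threshold (SVM) in *all* folds. The importance score of a
#' consensus feature is its mean signed coefficient across folds: negative
#' scores mean larger differences in that property make interaction less
#' likely.
#'
#' @param design Design matrix tibble from [build_design_matrix()].
#' @param config A [selection_config()].
#' @return An object of class `ppi_selection`; see [tidy.ppi_selection()]
#'   and [autoplot.ppi_selection()].
#' @export
select_features <- function(design, config = selection_config()) {
  xy <- .design_xy(design)
  x <- xy$x
  if (config$standardize) {
    std <- standardize_features(x)
    x <- std$x
  }
  y <- xy$y
  folds <- make_folds(y, config$n_folds, config$test_fraction, config$seed)
  gs <- NULL
  if (length(config$grid) == 1L) {
    gs <- list(value = config$grid,
               table = tibble::tibble(grid = config$grid, accuracy = NA_real_))
  } else if (!config$per_fold_grid) {
    gs <- grid_search(x, y, folds, config)
  }
  coefs <- matrix(NA_real_, nrow = length(xy$features),
                  ncol = config$n_folds,
                  dimnames = list(xy$features, NULL))
  support <- matrix(FALSE, nrow = length(xy$features),
                    ncol = config$n_folds,
                    dimnames = list(xy$features, NULL))
  reg_used <- numeric(config$n_folds)
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    if (config$per_fold_grid && length(config$grid) > 1L) {
      sub <- make_folds(y[f$train], max(2L, min(5L, config$n_folds)),
                        config$test_fraction, config$seed + k)
      gs <- grid_search(x[f$train, , drop = FALSE], y[f$train], sub, config)
    }
    fit <- .fold_fit(x[f$train, , drop = FALSE], y[f$train],
                     config$method, gs$value)
    coefs[, k] <- fit$coefficients
    support[, k] <- .fit_support(fit)
    reg_used[k] <- gs$value
  }
  per_fold_support <- rowSums(support)
  consensus <- xy$features[per_fold_support == config$n_folds]
  scores <- rowMeans(coefs)[consensus]
  if (length(consensus) == 0L) {
    warning("Empty consensus: no feature had a non-zero coefficient in ",
            "every fold", call. = FALSE)
  }
  structure(list(
    consensus_features = consensus[order(-abs(scores))],
    scores = scores[order(-abs(scores))],
    per_fold_support = per_fold_support,
    coefficients = coefs,
    regularization = reg_used[1],
    grid_table = gs$table,
    config = config,
    feature_names = xy$features),
    class = "ppi_selection")
}

#' @export
print.ppi_selection <- function(x, ...) {
  cat("Bagged ", toupper(x$config$method), " feature selection\n", sep = "")
  cat("  folds:          ", x$config$n_folds, " (stratified shuffled, ",
      round(100 * (1 - x$config$test_fraction)), "/",
      round(100 * x$config$test_fraction), " split)\n", sep = "")
  cat("  regularization: ", signif(x$regularization, 4), "\n", sep = "")
  cat("  consensus:      ", length(x$consensus_features), " of ",
      length(x$feature_names), " features\n", sep = "")
  if (length(x$consensus_features) > 0) {
    top <- head(x$consensus_features, 10)
    cat("  top features:   ", paste0(top, " (",
        signif(x$scores[top], 3), ")", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
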