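# Baseline classifier and balanced-classification metrics: Accuracy, Recall,
# F1 and the Matthews correlation coefficient, averaged over stratified
# cross-validation folds.

#' Confusion matrix counts
#'
#' Either supply the four counts directly, or `truth`/`pred` 0/1 vectors.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @param truth,pred Optional 0/1 vectors from which counts are tallied
#'   (ignored when counts are given).
#' @return An object of class `ppi_confusion` (a named list of counts).
#' @export
confusion_matrix <- function(tp = NULL, tn = NULL, fp = NULL, fn = NULL,
                             truth = NULL, pred = NULL) {
  if (is.null(tp)) {
    stopifnot(!is.null(truth), !is.null(pred), length(truth) == length(pred))
    truth <- as.integer(truth)
    pred <- as.integer(pred)
    tp <- sum(truth == 1L & pred == 1L)
    tn <- sum(truth == 0L & pred == 0L)
    fp <- sum(truth == 0L & pred == 1L)
    fn <- sum(truth == 1L & pred == 0L)
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("Confusion counts must be non-negative",
                            call. = FALSE)
  structure(as.list(counts), class = "ppi_confusion")
}

#' @export
print.ppi_confusion <- function(x, ...) {
  cat("Confusion matrix: TP =", x$tp, " TN =", x$tn,
      " FP =", x$fp, " FN =", x$fn, "\n")
  invisible(x)
}

#' Accuracy: (TP + TN) / (TP + TN + FP + FN)
#' @param cm A [confusion_matrix()].
#' @return Numeric in \[0, 1\].
#' @export
accuracy <- function(cm) {
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop("Accuracy undefined on an empty confusion matrix",
                       call. = FALSE)
  (cm$tp + cm$tn) / total
}

#' Recall (sensitivity on the positive class): TP / (TP + FN)
#' @inheritParams accuracy
#' @return Numeric in \[0, 1\].
#' @export
recall <- function(cm) {
  if (cm$tp + cm$fn == 0) stop("Recall undefined without positive instances",
                               call. = FALSE)
  cm$tp / (cm$tp + cm$fn)
}

#' F1 score: 2 TP / (2 TP + FP + FN)
#'
#' Algebraically the harmonic mean of precision and recall.
#' @inheritParams accuracy
#' @return Numeric in \[0, 1\].
#' @export
f1_score <- function(cm) {
  denom <- 2 * cm$tp + cm$fp + cm$fn
  if (denom == 0) stop("F1 undefined: no positive predictions or instances",
                       call. = FALSE)
  2 * cm$tp / denom
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, ranging from -1
#' (total disagreement) through 0 (chance level) to +1 (perfect prediction).
#' When any marginal factor is zero (e.g. a constant classifier) the value is
#' 0 by the standard convention.
#' @inheritParams accuracy
#' @return Numeric in \[-1, 1\].
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

.metric_row <- function(cm) {
  tibble::tibble(accuracy = accuracy(cm), recall = recall(cm),
                 f1 = f1_score(cm), mcc = mcc(cm),
                 tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn)
}

#' Train the baseline linear SVM on selected features
#'
#' @param x Numeric feature matrix restricted to the selected features.
#' @param y 0/1 labels (both classes present).
#' @param cost SVM cost parameter C.
#' @return An `e1071::svm` fit.
#' @export
train_baseline <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) {
    stop("No features to train on; run select_features() first",
         call. = FALSE)
  }
  yf <- factor(as.integer(y), levels = c(0L, 1L))
  if (nlevels(droplevels(yf)) < 2L) {
    stop("Training rows contain a single class", call. = FALSE)
  }
  e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
}

#' Evaluate the baseline classifier over cross-validation folds
#'
#' For each of `n_folds` stratified 80/20 splits (fresh splits drawn from
#' `seed`, independent of the splits used during selection): restrict the
#' design matrix to the consensus features, standardize with training-side
#' statistics, train the linear SVM on the training side, predict the
#' held-out side, and compute Accuracy, Recall, F1 and MCC. Headline values
#' are the unweighted means of the per-fold values.
#'
#' @param design Design matrix tibble from [build_design_matrix()].
#' @param selection A `ppi_selection` object, or a character vector of
#'   feature names to use directly.
#' @param n_folds Number of evaluation folds.
#' @param seed Integer seed for the evaluation splits.
#' @param test_fraction Held-out fraction per fold.
#' @param cost SVM cost; defaults to the cost chosen during SVM selection,
#'   or 1 when the selection came from LASSO.
#' @return An object of class `ppi_eval` with per-fold and mean metrics; see
#'   [tidy.ppi_eval()] and [glance.ppi_eval()].
#' @export
evaluate_baseline <- function(design, selection, n_folds = 15L, seed = 1L,
                              test_fraction = 0.2, cost = NULL) {
  if (inherits(selection, "ppi_selection")) {
    features <- selection$consensus_features
    if (is.null(cost)) {
      cost <- if (selection$config$method == "svm")
        selection$regularization else 1
    }
  } else {
    features <- as.character(selection)
    if (is.null(cost)) cost <- 1
  }
  if (length(features) == 0L) {
    stop("Empty consensus feature set; run select_features() first",
         call. = FALSE)
  }
  missing <- setdiff(features, names(design))
  if (length(missing) > 0L) {
    stop("Feature(s) absent from the design matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(design[, features, drop = FALSE])
  y <- as.integer(design$label)
  folds <- make_folds(y, n_folds, test_fraction, seed)
  per_fold <- purrr::map_dfr(seq_along(folds), function(k) {
    f <- folds[[k]]
    xtr <- x[f$train, , drop = FALSE]
    center <- colMeans(xtr)
    scl <- apply(xtr, 2, sd)
    scl[scl == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, center, "-"), 2, scl, "/")
    xte <- sweep(sweep(x[f$test, , drop = FALSE], 2, center, "-"), 2,
                 scl, "/")
    m <- train_baseline(xtr, y[f$train], cost = cost)
    pred <- as.integer(as.character(predict(m, xte)))
    cm <- confusion_matrix(truth = y[f$test], pred = pred)
    dplyr::bind_cols(tibble::tibble(fold = k), .metric_row(cm))
  })
  means <- colMeans(per_fold[, c("accuracy", "recall", "f1", "mcc")])
  structure(list(per_fold = per_fold, means = means,
                 n_folds = as.integer(n_folds), features = features,
                 cost = cost, seed = as.integer(seed)),
            class = "ppi_eval")
}

#' @export
print.ppi_eval <- function(x, ...) {
  cat("Baseline linear SVM on", length(x$features), "selected feature(s),",
      x$n_folds, "folds\n")
  cat(sprintf("  Accuracy %.3f  Recall %.3f  F1 %.3f  MCC %.3f\n",
              x$means["accuracy"], x$means["recall"],
              x$means["f1"], x$means["mcc"]))
  invisible(x)
}

#' One-line results row in the layout of a results table
#'
#' @param eval A `ppi_eval` object.
#' @param features_label Label for the feature-selection method column.
#' @return A one-row tibble: Features, Accuracy, Recall, MCC, F1.
#' @export
metrics_row <- function(eval, features_label = "") {
  tibble::tibble(Features = features_label,
                 Accuracy = unname(eval$means["accuracy"]),
                 Recall = unname(eval$means["recall"]),
                 MCC = unname(eval$means["mcc"]),
                 F1 = unname(eval$means["f1"]))
}
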