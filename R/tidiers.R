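# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a feature-selection result
#'
#' @param x A `ppi_selection` object.
#' @param all_features If `TRUE`, return one row per input feature with its
#'   fold support; by default only consensus features are returned.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `score` (mean signed coefficient
#'   across folds), `per_fold_support` and `consensus`.
#' @export
#' @exportS3Method generics::tidy
tidy.ppi_selection <- function(x, all_features = FALSE, ...) {
  if (all_features) {
    tibble::tibble(
      feature = x$feature_names,
      score = rowMeans(x$coefficients)[x$feature_names],
      per_fold_support = unname(x$per_fold_support[x$feature_names]),
      consensus = x$feature_names %in% x$consensus_features) |>
      dplyr::arrange(dplyr::desc(.data$consensus),
                     dplyr::desc(abs(.data$score)))
  } else {
    tibble::tibble(
      feature = x$consensus_features,
      score = unname(x$scores),
      per_fold_support = unname(x$per_fold_support[x$consensus_features]),
      consensus = TRUE)
  }
}

#' One-row summary of a feature-selection result
#'
#' @param x A `ppi_selection` object.
#' @param ... Unused.
#' @return A one-row tibble: method, regularization, folds, feature counts
#'   and seed.
#' @export
#' @exportS3Method generics::glance
glance.ppi_selection <- function(x, ...) {
  tibble::tibble(method = x$config$method,
                 regularization = x$regularization,
                 n_folds = x$config$n_folds,
                 n_features = length(x$feature_names),
                 n_consensus = length(x$consensus_features),
                 seed = x$config$seed)
}

#' Ranked signed-importance plot of selected features
#'
#' Horizontal bars of the consensus features' mean signed coefficients;
#' negative scores mean larger between-protein differences in that property
#' disfavor interaction.
#'
#' @param object A `ppi_selection` object.
#' @param top_n Show at most this many features (by absolute score).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ppi_selection <- function(object, top_n = 30L, ...) {
  df <- tidy(object)
  if (nrow(df) == 0L) stop("Nothing to plot: empty consensus", call. = FALSE)
  df <- head(df[order(-abs(df$score)), ], top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$feature, abs(.data$score)),
    fill = .data$score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = "Importance score (mean signed coefficient across folds)",
      y = NULL,
      title = paste("Bagged", toupper(object$config$method),
                    "consensus features")) +
    ggplot2::theme_minimal()
}

#' Tidy per-fold evaluation metrics
#'
#' @param x A `ppi_eval` object.
#' @param ... Unused.
#' @return A long tibble with columns `fold`, `metric`, `value`.
#' @export
#' @exportS3Method generics::tidy
tidy.ppi_eval <- function(x, ...) {
  tidyr::pivot_longer(
    x$per_fold[, c("fold", "accuracy", "recall", "f1", "mcc")],
    cols = -"fold", names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation
#'
#' @param x A `ppi_eval` object.
#' @param ... Unused.
#' @return A one-row tibble of fold-averaged Accuracy, Recall, F1 and MCC.
#' @export
#' @exportS3Method generics::glance
glance.ppi_eval <- function(x, ...) {
  tibble::tibble(accuracy = unname(x$means["accuracy"]),
                 recall = unname(x$means["recall"]),
                 f1 = unname(x$means["f1"]),
                 mcc = unname(x$means["mcc"]),
                 n_folds = x$n_folds,
                 n_features = length(x$features))
}

#' Per-fold metric distribution plot
#'
#' @param object A `ppi_eval` object.
#' @param ... Unused.
#' @return A ggplot object showing per-fold metric values with their means.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ppi_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, linewidth = 0.3, color = "red") +
    ggplot2::labs(x = NULL, y = "Per-fold value",
                  title = "Cross-validated baseline metrics") +
    ggplot2::theme_minimal()
}

#' Grouped bar plot of dipeptide compositions across proteins
#'
#' Companion plot for [compare_dipeptides()].
#'
#' @param comparison Tibble from [compare_dipeptides()].
#' @return A ggplot object.
#' @export
plot_dipeptide_comparison <- function(comparison) {
  df <- tidyr::pivot_longer(comparison, cols = -"id",
                            names_to = "dipeptide", values_to = "dpc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dipeptide, y = .data$dpc,
                                   fill = .data$id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Dipeptide", y = "Composition (fraction of N - 1)",
                  fill = "Protein") +
    ggplot2::theme_minimal()
}
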