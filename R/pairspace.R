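# Pair space: min-max feature normalization and per-pair difference vectors
# that form the classification design matrix.

#' Fit min-max normalization parameters over a protein set
#'
#' Records, per feature, the minimum and maximum value over the reference
#' protein set, so that `z_hat = (z - z_min) / (z_max - z_min)` maps the set
#' onto \[0, 1\] and every property enters the analysis with similar weight.
#' Features with `z_max == z_min` are flagged degenerate: they carry no
#' information on this set.
#'
#' @param features Feature matrix tibble (`id` + numeric columns).
#' @param reference_set_id Optional identifier of the protein set; defaults
#'   to a hash of the sorted ids.
#' @return A tibble of class `ppi_norm` with columns `feature`, `z_min`,
#'   `z_max`, `degenerate`.
#' @export
fit_normalization <- function(features, reference_set_id = NULL) {
  stopifnot(names(features)[1] == "id")
  if (nrow(features) == 0L) {
    stop("Cannot fit normalization on an empty protein set", call. = FALSE)
  }
  mat <- as.matrix(features[, -1, drop = FALSE])
  if (!all(is.finite(mat))) {
    stop("Feature matrix contains non-finite values", call. = FALSE)
  }
  params <- tibble::tibble(
    feature = colnames(mat),
    z_min = unname(apply(mat, 2, min)),
    z_max = unname(apply(mat, 2, max)))
  params$degenerate <- params$z_max == params$z_min
  attr(params, "reference_set_id") <-
    reference_set_id %||% rlang::hash(sort(features$id))
  class(params) <- c("ppi_norm", class(params))
  params
}

#' Apply min-max normalization to a feature matrix
#'
#' Maps each feature through `(z - z_min) / (z_max - z_min)` using parameters
#' from [fit_normalization()]. Values outside the fitted range (possible when
#' the parameters were fit on a training subset) are clipped to \[0, 1\];
#' degenerate features map to 0.
#'
#' @param features Feature matrix tibble (`id` + numeric columns).
#' @param params A `ppi_norm` object with matching feature schema.
#' @return A tibble of the same shape with values in \[0, 1\].
#' @export
apply_normalization <- function(features, params) {
  feats <- setdiff(names(features), "id")
  if (!setequal(feats, params$feature)) {
    stop("Feature schema does not match the normalization parameters",
         call. = FALSE)
  }
  p <- params[match(feats, params$feature), ]
  mat <- as.matrix(features[, feats, drop = FALSE])
  range <- ifelse(p$degenerate, 1, p$z_max - p$z_min)
  scaled <- sweep(sweep(mat, 2, p$z_min, "-"), 2, range, "/")
  scaled[, p$degenerate] <- 0
  scaled <- pmin(pmax(scaled, 0), 1)
  out <- tibble::as_tibble(scaled)
  dplyr::bind_cols(features["id"], out)
}

#' Per-feature difference vector of two proteins
#'
#' The pair representation: `A - B = (A_1 - B_1, ..., A_N - B_N)`. In
#' `"absolute"` mode (the default) each entry is `|A_j - B_j|`, which is
#' symmetric under swapping the two proteins — interaction is a symmetric
#' relation and the ordering of pairs in an input table is arbitrary.
#' `"signed"` mode keeps the raw subtraction.
#'
#' @param vec_a,vec_b Named numeric vectors with identical feature schemas.
#' @param mode `"absolute"` or `"signed"`.
#' @return A named numeric vector of per-feature differences.
#' @export
pair_difference <- function(vec_a, vec_b, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (!identical(names(vec_a), names(vec_b))) {
    stop("Feature schemas of the two proteins differ", call. = FALSE)
  }
  d <- vec_a - vec_b
  if (mode == "absolute") abs(d) else d
}

#' Build the pair-difference design matrix
#'
#' One row per labeled pair: identifiers, label, then the per-feature
#' difference of the two proteins' (normalized) descriptor vectors.
#' Degenerate (constant) features are dropped with their names logged, since
#' constant columns carry no information and destabilize downstream
#' standardization; pairs whose proteins lack feature vectors are dropped
#' with a logged count.
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `label`.
#' @param features Normalized feature matrix tibble (`id` + numeric columns).
#' @param mode `"absolute"` (default) or `"signed"`; see [pair_difference()].
#' @return A tibble with columns `id_a`, `id_b`, `label`, then one column per
#'   retained feature. The difference mode is attached as attribute `"mode"`.
#' @export
build_design_matrix <- function(pairs, features,
                                mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  known <- pairs$id_a %in% features$id & pairs$id_b %in% features$id
  if (any(!known)) {
    message("Dropped ", sum(!known), " pair(s) with missing proteins")
  }
  pairs <- pairs[known, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("No pairs left to build", call. = FALSE)

  mat <- as.matrix(features[, -1, drop = FALSE])
  rownames(mat) <- features$id
  degenerate <- apply(mat, 2, function(v) max(v) == min(v))
  if (any(degenerate)) {
    message("Dropped ", sum(degenerate), " degenerate feature(s): ",
            paste(head(colnames(mat)[degenerate], 10), collapse = ", "))
    mat <- mat[, !degenerate, drop = FALSE]
  }
  diff <- mat[pairs$id_a, , drop = FALSE] - mat[pairs$id_b, , drop = FALSE]
  if (mode == "absolute") diff <- abs(diff)
  out <- dplyr::bind_cols(
    tibble::tibble(id_a = pairs$id_a, id_b = pairs$id_b,
                   label = as.integer(pairs$label)),
    tibble::as_tibble(diff))
  attr(out, "mode") <- mode
  out
}

# Split a design matrix into its numeric feature matrix and label vector.
.design_xy <- function(design) {
  feats <- setdiff(names(design), c("id_a", "id_b", "label"))
  list(x = as.matrix(design[, feats, drop = FALSE]),
       y = as.integer(design$label),
       features = feats)
}
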