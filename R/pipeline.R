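# Pipeline stages shared by the package interface and the command-line
# wrapper (exec/ppiselect): featurize -> pairs -> select -> evaluate, plus
# simulate and the dipeptide comparison table.

#' Compare named dipeptide components across proteins
#'
#' Builds a small table of dipeptide-composition components for a set of
#' proteins — the kind of comparison used to contrast an interacting pair
#' (e.g. a histidine kinase and its cognate response regulator) with a
#' non-interacting control protein.
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param ids Protein identifiers to compare (default: all).
#' @param dipeptides Dipeptide names, e.g. `c("VV", "KK", "IK", "EE")`.
#' @return A tibble with one row per protein and one column per dipeptide.
#' @export
compare_dipeptides <- function(records, ids = records$id,
                               dipeptides = c("VV", "KK", "IK", "EE")) {
  bad <- setdiff(dipeptides, DIPEPTIDES)
  if (length(bad) > 0L) {
    stop("Unknown dipeptide name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(ids, records$id)
  if (length(missing) > 0L) {
    stop("Protein(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- records[match(ids, records$id), ]
  cols <- paste0("DPC_", dipeptides)
  vals <- t(vapply(rows$sequence,
                   function(s) dipeptide_composition(s)[cols],
                   numeric(length(cols))))
  out <- tibble::as_tibble(vals, .name_repair = "minimal")
  names(out) <- dipeptides
  dplyr::bind_cols(tibble::tibble(id = rows$id), out)
}

#' Run the full analysis pipeline on sequence and pair inputs
#'
#' Chains the stages: read and validate sequences, drop proteins with
#' non-natural residues, compute descriptors, fit and apply min-max
#' normalization, build the pair-difference design matrix, select features
#' by bagging, and evaluate the baseline classifier on fresh folds.
#'
#' @param records Protein records tibble (`id`, `sequence`).
#' @param pairs Labeled pairs tibble (`id_a`, `id_b`, `label`).
#' @param descriptor_cfg A [descriptor_config()].
#' @param selection_cfg A [selection_config()].
#' @param mode Pair difference mode, `"absolute"` or `"signed"`.
#' @param eval_folds Folds for the final evaluation.
#' @param eval_seed Seed for the evaluation splits (independent of the
#'   selection folds).
#' @return A list with elements `features`, `normalization`, `design`,
#'   `selection` (`ppi_selection`) and `evaluation` (`ppi_eval`).
#' @export
run_ppi_pipeline <- function(records, pairs,
                             descriptor_cfg = descriptor_config(),
                             selection_cfg = selection_config(),
                             mode = c("absolute", "signed"),
                             eval_folds = 15L,
                             eval_seed = selection_cfg$seed + 101L) {
  mode <- match.arg(mode)
  nat <- filter_natural(records)
  features <- compute_descriptors(nat$kept, descriptor_cfg)
  params <- fit_normalization(features)
  normalized <- apply_normalization(features, params)
  design <- build_design_matrix(pairs, normalized, mode = mode)
  selection <- select_features(design, selection_cfg)
  evaluation <- evaluate_baseline(design, selection, n_folds = eval_folds,
                                  seed = eval_seed)
  list(features = features, normalization = params, design = design,
       selection = selection, evaluation = evaluation)
}

#' Serialize a selection result to JSON
#'
#' @param selection A `ppi_selection` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  cfg <- selection$config
  jsonlite::write_json(list(
    method = cfg$method,
    consensus_features = selection$consensus_features,
    scores = as.list(selection$scores),
    per_fold_support = as.list(
      selection$per_fold_support[selection$per_fold_support > 0]),
    regularization = selection$regularization,
    config = list(method = cfg$method, n_folds = cfg$n_folds,
                  test_fraction = cfg$test_fraction, grid = cfg$grid,
                  seed = cfg$seed, standardize = cfg$standardize)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#'
#' @param eval A `ppi_eval` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(eval, path) {
  jsonlite::write_json(list(
    means = as.list(eval$means),
    per_fold = eval$per_fold,
    n_folds = eval$n_folds,
    features = eval$features,
    cost = eval$cost,
    seed = eval$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
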