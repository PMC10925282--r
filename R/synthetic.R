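# Synthetic proteomes and balanced labeled pair sets with a planted
# dipeptide-composition signal, providing ground truth for selection
# recovery and evaluation calibration.

# Approximate natural amino-acid background frequencies (UniProt/Swiss-Prot
# composition), in the package's fixed residue order.
.natural_background <- function() {
  f <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  f / sum(f)
}

#' Synthetic dataset configuration
#'
#' Describes a synthetic study: a proteome drawn from natural background
#' residue frequencies in which a random half of the proteins ("signal"
#' proteins) are enriched for a small set of planted dipeptides, and a
#' balanced set of labeled pairs in which only the planted
#' dipeptide-composition differences carry the interaction signal.
#'
#' The interaction model is logistic: for a candidate pair with summed
#' planted-dipeptide composition difference s, the interaction probability is
#' `plogis(alpha - beta * z)` where z is s standardized over the candidate
#' pairs and alpha is calibrated so the marginal positive rate is 0.5. The
#' negative sign encodes physicochemical similarity: pairs that *differ* less
#' in the planted compositions are more likely to interact. `beta = 0` is an
#' exact null; `beta` around 50 makes labels nearly deterministic in s.
#'
#' @param n_proteins Number of proteins in the proteome.
#' @param length_range Integer range (min, max) of sequence lengths.
#' @param planted_dipeptides Dipeptides carrying the signal.
#' @param effect_size Logistic coefficient beta (>= 0) on the standardized
#'   planted difference score.
#' @param n_pairs_per_class Pairs per class in the balanced output.
#' @param background Named 20-vector of residue frequencies (sums to 1);
#'   defaults to natural Swiss-Prot-like frequencies.
#' @param enrichment_factor Multiple (> 1) by which each planted dipeptide's
#'   composition in a signal protein must exceed its background expectation.
#' @param seed Integer seed; proteome and pair generation are deterministic
#'   given it.
#' @return An object of class `ppi_synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 300L,
                             length_range = c(100L, 300L),
                             planted_dipeptides = c("VV", "KK", "IK", "EE"),
                             effect_size = 6,
                             n_pairs_per_class = 300L,
                             background = NULL,
                             enrichment_factor = 3,
                             seed = 1L) {
  background <- background %||% .natural_background()
  stopifnot(length(background) == 20L, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  if (is.null(names(background))) names(background) <- AMINO_ACIDS
  background <- background[AMINO_ACIDS]
  if (!all(planted_dipeptides %in% DIPEPTIDES)) {
    stop("Invalid planted dipeptide name(s): ",
         paste(setdiff(planted_dipeptides, DIPEPTIDES), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(effect_size >= 0, enrichment_factor > 1,
            n_pairs_per_class >= 1L, length(length_range) == 2L,
            length_range[1] >= 10L, length_range[2] >= length_range[1])
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 planted_dipeptides = planted_dipeptides,
                 effect_size = effect_size,
                 n_pairs_per_class = as.integer(n_pairs_per_class),
                 background = background,
                 enrichment_factor = enrichment_factor,
                 seed = as.integer(seed)),
            class = "ppi_synthetic_config")
}

# Per-letter next-residue sampling weights for signal proteins: background
# weights with planted transitions boosted, renormalized per row. The boost
# (2x the enrichment factor) over-targets so that the rejection check below
# passes within a few attempts.
.signal_transitions <- function(config) {
  rows <- matrix(rep(config$background, each = 20L), nrow = 20L,
                 dimnames = list(AMINO_ACIDS, AMINO_ACIDS))
  boost <- 2 * config$enrichment_factor
  for (dp in config$planted_dipeptides) {
    a <- substr(dp, 1, 1)
    b <- substr(dp, 2, 2)
    rows[a, b] <- rows[a, b] * boost
  }
  rows / rowSums(rows)
}

.sample_background_seq <- function(len, background) {
  paste(sample(AMINO_ACIDS, len, replace = TRUE, prob = background),
        collapse = "")
}

.sample_signal_seq <- function(len, trans, background) {
  idx <- integer(len)
  idx[1] <- sample.int(20L, 1L, prob = background)
  for (i in 2:len) {
    idx[i] <- sample.int(20L, 1L, prob = trans[idx[i - 1L], ])
  }
  paste(AMINO_ACIDS[idx], collapse = "")
}

#' Generate a synthetic proteome with a planted subpopulation
#'
#' Residues are drawn i.i.d. from the background frequencies; a random half
#' of the proteins are "signal" proteins generated from a first-order chain
#' whose planted transitions are boosted, then rejection-checked (up to 1000
#' resamples) until every planted dipeptide's composition exceeds
#' `enrichment_factor` times its background expectation. Rejection keeps the
#' sequences statistically natural aside from the planted marginal shift.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `id`, `sequence` and logical `signal` (the
#'   hidden subpopulation tag, not part of any downstream interface).
#' @export
generate_proteome <- function(config = synthetic_config()) {
  trans <- .signal_transitions(config)
  bg <- config$background
  planted <- config$planted_dipeptides
  targets <- vapply(planted, function(dp) {
    config$enrichment_factor * bg[substr(dp, 1, 1)] * bg[substr(dp, 2, 2)]
  }, numeric(1))
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    lens <- sample(seq.int(config$length_range[1], config$length_range[2]),
                   n, replace = TRUE)
    is_signal <- rep(FALSE, n)
    is_signal[sample.int(n, n %/% 2L)] <- TRUE
    seqs <- character(n)
    for (i in seq_len(n)) {
      if (!is_signal[i]) {
        seqs[i] <- .sample_background_seq(lens[i], bg)
      } else {
        ok <- FALSE
        for (attempt in seq_len(1000L)) {
          s <- .sample_signal_seq(lens[i], trans, bg)
          dpc <- dipeptide_composition(s)[paste0("DPC_", planted)]
          if (all(dpc >= targets)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("Could not reach the requested enrichment after 1000 ",
               "attempts; lower enrichment_factor or lengthen sequences",
               call. = FALSE)
        }
        seqs[i] <- s
      }
    }
    tibble::tibble(id = sprintf("syn%04d", seq_len(n)),
                   sequence = seqs, signal = is_signal)
  })
}

#' Generate balanced labeled pairs over a synthetic proteome
#'
#' Candidate pairs are sampled uniformly from the unordered pairs of distinct
#' proteins; each pair's planted score s is the sum over planted dipeptides
#' of the absolute dipeptide-composition difference. Interaction labels are
#' drawn from `plogis(alpha - beta * z)` (z the standardized s, alpha
#' calibrated so the marginal positive rate is 0.5), then both classes are
#' down-sampled to exactly `n_pairs_per_class`.
#'
#' @param proteome Tibble from [generate_proteome()].
#' @param config The same [synthetic_config()].
#' @return A list of class `ppi_sim` with elements `proteins` (tibble
#'   `id`/`sequence`), `pairs` (balanced `id_a`/`id_b`/`label`), `truth`
#'   (planted feature names and per-pair linear predictors) and `config`.
#' @export
generate_pairs <- function(proteome, config = synthetic_config()) {
  planted_cols <- paste0("DPC_", config$planted_dipeptides)
  dpc <- t(vapply(proteome$sequence,
                  function(s) dipeptide_composition(s)[planted_cols],
                  numeric(length(planted_cols))))
  rownames(dpc) <- proteome$id
  withr::with_seed(config$seed + 1L, {
    all_pairs <- utils::combn(proteome$id, 2L)
    n_cand <- min(ncol(all_pairs),
                  max(10L * config$n_pairs_per_class, 1000L))
    cand <- all_pairs[, sample.int(ncol(all_pairs), n_cand), drop = FALSE]
    s <- rowSums(abs(dpc[cand[1, ], , drop = FALSE] -
                       dpc[cand[2, ], , drop = FALSE]))
    z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else s * 0
    beta <- config$effect_size
    alpha <- uniroot(function(a) mean(plogis(a - beta * z)) - 0.5,
                     interval = c(-10 * beta - 10, 10 * beta + 10))$root
    eta <- alpha - beta * z
    label <- rbinom(length(eta), 1L, plogis(eta))
    pos <- which(label == 1L)
    neg <- which(label == 0L)
    if (length(pos) < config$n_pairs_per_class ||
        length(neg) < config$n_pairs_per_class) {
      stop("Cannot reach ", config$n_pairs_per_class, " pairs per class; ",
           "increase n_proteins or lower n_pairs_per_class", call. = FALSE)
    }
    keep <- c(sample(pos, config$n_pairs_per_class),
              sample(neg, config$n_pairs_per_class))
    keep <- sample(keep)
    pairs <- tibble::tibble(id_a = cand[1, keep], id_b = cand[2, keep],
                            label = as.integer(label[keep]))
    truth <- list(planted = planted_cols,
                  pair_truth = tibble::tibble(
                    id_a = pairs$id_a, id_b = pairs$id_b,
                    label = pairs$label, eta = eta[keep]))
    structure(list(proteins = proteome[, c("id", "sequence")],
                   pairs = pairs, truth = truth, config = config),
              class = "ppi_sim")
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_proteome()] then [generate_pairs()].
#'
#' @param config A [synthetic_config()].
#' @return A `ppi_sim` object; see [generate_pairs()].
#' @export
simulate_ppi_dataset <- function(config = synthetic_config()) {
  generate_pairs(generate_proteome(config), config)
}

#' @export
print.ppi_sim <- function(x, ...) {
  cat("Synthetic PPI dataset:", nrow(x$proteins), "proteins,",
      nrow(x$pairs), "pairs (balanced)\n")
  cat("  planted features:", paste(x$truth$planted, collapse = ", "), "\n")
  cat("  effect size beta:", x$config$effect_size, "\n")
  invisible(x)
}

#' Bayes accuracy of the generator's oracle classifier
#'
#' Accuracy, on the balanced output pairs, of the oracle that predicts
#' interaction exactly when the true linear predictor is positive. This
#' upper-bounds the expected accuracy of any classifier trained on features
#' of this generator.
#'
#' @param sim A `ppi_sim` object (or its `truth` element).
#' @return A single numeric accuracy.
#' @export
bayes_accuracy <- function(sim) {
  truth <- if (inherits(sim, "ppi_sim")) sim$truth else sim
  pt <- truth$pair_truth
  mean(as.integer(pt$eta > 0) == pt$label)
}
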