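# Physicochemical descriptor families computed from a primary sequence.
#
# Families and naming (fixed concatenation order in descriptor_vector()):
#   AAC        AAC_<X>                    20 values, fractions of each residue
#   DPC        DPC_<XY>                   400 values, overlapping dipeptide
#                                         counts / (N - 1)
#   MoranAuto  MoranAuto_<Scale><d>       lag-d autocorrelation of a property
#   PAAC       PAAC<k>                    20 + lambda pseudo composition
#   APAAC      APAAC<k>                   20 + 2*lambda amphiphilic variant
#   CTD        CTD_<Prop>_<C|T|D>_...     3-class composition / transition /
#                                         distribution encodings

.seq_chars <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- !chars %in% AMINO_ACIDS
  if (any(bad)) {
    stop("Sequence contains non-natural residue '", chars[which(bad)[1]],
         "' at position ", which(bad)[1],
         "; run filter_natural() first", call. = FALSE)
  }
  chars
}

#' Descriptor configuration
#'
#' Bundles which descriptor families to compute and their tuning parameters.
#' Defaults follow the conventions of the propy descriptor toolkit: Moran
#' autocorrelation up to lag 30, pseudo-composition with `paac_lambda = 10`
#' sequence-order terms weighted by `paac_weight = 0.05`.
#'
#' @param families Subset of `"AAC"`, `"DPC"`, `"MoranAuto"`, `"PAAC"`,
#'   `"APAAC"`, `"CTD"`.
#' @param moran_scales Property scales for Moran autocorrelation (see
#'   [list_property_scales()]).
#' @param moran_max_lag Largest sequence separation d (in residues).
#' @param paac_lambda Number of sequence-order correlation tiers.
#' @param paac_weight Weight of the sequence-order terms relative to
#'   composition.
#' @return An object of class `ppi_descriptor_config`.
#' @export
descriptor_config <- function(families = c("AAC", "DPC", "MoranAuto",
                                           "PAAC", "APAAC", "CTD"),
                              moran_scales = c("Mutability", "Steric"),
                              moran_max_lag = 30L,
                              paac_lambda = 10L,
                              paac_weight = 0.05) {
  families <- match.arg(families, several.ok = TRUE)
  moran_max_lag <- as.integer(moran_max_lag)
  paac_lambda <- as.integer(paac_lambda)
  stopifnot(moran_max_lag >= 1L, paac_lambda >= 0L, paac_weight > 0)
  known <- list_property_scales()
  if (!all(moran_scales %in% known)) {
    stop("Unknown Moran scale(s): ",
         paste(setdiff(moran_scales, known), collapse = ", "), call. = FALSE)
  }
  structure(list(families = families, moran_scales = moran_scales,
                 moran_max_lag = moran_max_lag, paac_lambda = paac_lambda,
                 paac_weight = paac_weight),
            class = "ppi_descriptor_config")
}

#' @export
print.ppi_descriptor_config <- function(x, ...) {
  cat("Descriptor configuration\n")
  cat("  families:    ", paste(x$families, collapse = ", "), "\n")
  cat("  Moran scales:", paste(x$moran_scales, collapse = ", "),
      " (max lag ", x$moran_max_lag, ")\n", sep = "")
  cat("  PAAC/APAAC:  lambda =", x$paac_lambda, ", weight =",
      x$paac_weight, "\n")
  invisible(x)
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 standard residues; the 20 components sum to 1.
#'
#' @param sequence Protein sequence over the standard alphabet (N >= 1).
#' @return Named numeric vector `AAC_A` ... `AAC_Y`.
#' @export
aa_composition <- function(sequence) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 1L) stop("Empty sequence has no composition", call. = FALSE)
  counts <- tabulate(match(chars, AMINO_ACIDS), nbins = 20L)
  setNames(counts / n, paste0("AAC_", AMINO_ACIDS))
}

#' Dipeptide composition
#'
#' For a sequence of N residues there are N - 1 overlapping adjacent pairs;
#' each of the 400 possible dipeptides is scored as its count divided by
#' N - 1, so every component lies in \[0, 1\] and the 400 components sum to 1.
#'
#' @param sequence Protein sequence over the standard alphabet (N >= 2).
#' @return Named numeric vector `DPC_AA` ... `DPC_YY` of length 400.
#' @export
dipeptide_composition <- function(sequence) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 2L) stop("Sequence of length ", n, " has no dipeptides",
                   call. = FALSE)
  first <- match(chars[-n], AMINO_ACIDS)
  second <- match(chars[-1], AMINO_ACIDS)
  idx <- (first - 1L) * 20L + second
  counts <- tabulate(idx, nbins = 400L)
  setNames(counts / (n - 1L), paste0("DPC_", DIPEPTIDES))
}

#' Moran autocorrelation of a property at one lag
#'
#' With per-residue property values M_1..M_N and mean M-bar,
#' `Moran(d) = [ (1/(N-d)) sum_(i=1..N-d) (M_i - Mbar)(M_(i+d) - Mbar) ] /
#' [ (1/N) sum_(i=1..N) (M_i - Mbar)^2 ]`. Positive values mean residues d
#' positions apart tend to share similar property values. A sequence with
#' zero property variance returns 0 (the no-autocorrelation neutral value).
#' The statistic is invariant under affine rescaling of the property scale.
#'
#' @param sequence Protein sequence over the standard alphabet.
#' @param scale_values Named numeric vector over the 20 residues (e.g. from
#'   [property_scale()]).
#' @param d Lag in residues, `1 <= d <= N - 1`.
#' @return A single numeric value.
#' @export
moran_autocorrelation <- function(sequence, scale_values, d) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  d <- as.integer(d)
  if (d < 1L || d > n - 1L) {
    stop("Lag d = ", d, " outside 1..N-1 for sequence of length ", n,
         call. = FALSE)
  }
  m <- unname(scale_values[chars])
  if (anyNA(m)) stop("Property scale missing residues", call. = FALSE)
  mbar <- mean(m)
  dev <- m - mbar
  denom <- sum(dev^2) / n
  if (denom == 0) return(0)
  num <- sum(dev[seq_len(n - d)] * dev[seq.int(d + 1L, n)]) / (n - d)
  num / denom
}

#' Moran autocorrelation profile over scales and lags
#'
#' One feature per (scale, lag) combination, named as e.g.
#' `MoranAuto_Mutability27` for the mutability scale at lag 27. Scales are
#' standardized over the 20 letters before use.
#'
#' @param sequence Protein sequence with N greater than `moran_max_lag`.
#' @param config A [descriptor_config()].
#' @return Named numeric vector of length
#'   `length(moran_scales) * moran_max_lag`.
#' @export
moran_profile <- function(sequence, config = descriptor_config()) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n <= config$moran_max_lag) {
    stop("Sequence length ", n, " must exceed the maximum lag ",
         config$moran_max_lag, call. = FALSE)
  }
  out <- lapply(config$moran_scales, function(sc) {
    vals <- property_scale(sc, standardize = TRUE)
    v <- vapply(seq_len(config$moran_max_lag), function(d) {
      moran_autocorrelation(sequence, vals, d)
    }, numeric(1))
    setNames(v, paste0("MoranAuto_", sc, seq_len(config$moran_max_lag)))
  })
  unlist(out)
}

# Shared machinery for PAAC/APAAC composition fractions.
.aa_fractions <- function(chars) {
  tabulate(match(chars, AMINO_ACIDS), nbins = 20L) / length(chars)
}

#' Pseudo amino-acid composition
#'
#' Chou's pseudo composition: the 20 residue fractions augmented with
#' `paac_lambda` sequence-order correlation factors. Tier k averages, over all
#' residue pairs k positions apart, the mean squared difference of three
#' normalized property values (hydrophobicity, hydrophilicity, side-chain
#' mass). All components are non-negative and sum to 1; with
#' `paac_lambda = 0` the result equals [aa_composition()] (up to names).
#'
#' @param sequence Protein sequence with N greater than `paac_lambda`.
#' @param config A [descriptor_config()].
#' @return Named numeric vector `PAAC1` ... `PAAC<20 + paac_lambda>`.
#' @export
paac <- function(sequence, config = descriptor_config()) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  lam <- config$paac_lambda
  w <- config$paac_weight
  if (n <= lam) {
    stop("PAAC needs sequence length > lambda (", lam, "); got N = ", n,
         call. = FALSE)
  }
  h1 <- .paac_normalize(property_scale("PAACHydrophobicity"))[chars]
  h2 <- .paac_normalize(property_scale("PAACHydrophilicity"))[chars]
  ms <- .paac_normalize(property_scale("SideChainMass"))[chars]
  theta <- vapply(seq_len(lam), function(k) {
    i <- seq_len(n - k)
    mean(((h1[i] - h1[i + k])^2 + (h2[i] - h2[i + k])^2 +
            (ms[i] - ms[i + k])^2) / 3)
  }, numeric(1))
  f <- .aa_fractions(chars)
  denom <- 1 + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  setNames(out, paste0("PAAC", seq_along(out)))
}

#' Amphiphilic pseudo amino-acid composition
#'
#' As [paac()], but each lag contributes two raw product-correlation terms,
#' one per hydrophobicity and hydrophilicity track, so the output has
#' `20 + 2 * paac_lambda` components. Components sum to 1; unlike PAAC, the
#' correlation terms are raw products and may be negative. With
#' `paac_lambda = 0` the result equals [aa_composition()] (up to names).
#'
#' @inheritParams paac
#' @return Named numeric vector `APAAC1` ... `APAAC<20 + 2*paac_lambda>`.
#' @export
apaac <- function(sequence, config = descriptor_config()) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  lam <- config$paac_lambda
  w <- config$paac_weight
  if (n <= lam) {
    stop("APAAC needs sequence length > lambda (", lam, "); got N = ", n,
         call. = FALSE)
  }
  h1 <- .paac_normalize(property_scale("PAACHydrophobicity"))[chars]
  h2 <- .paac_normalize(property_scale("PAACHydrophilicity"))[chars]
  tau <- numeric(2L * lam)
  for (k in seq_len(lam)) {
    i <- seq_len(n - k)
    tau[2L * k - 1L] <- mean(h1[i] * h1[i + k])
    tau[2L * k] <- mean(h2[i] * h2[i + k])
  }
  f <- .aa_fractions(chars)
  denom <- 1 + w * sum(tau)
  out <- c(f / denom, w * tau / denom)
  setNames(out, paste0("APAAC", seq_along(out)))
}

# Three-class property alphabets for the CTD encodings. Each property
# partitions the 20 residues into classes 1..3.
CTD_PROPERTIES <- list(
  Hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  NormalizedVDWV = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  Polarity = c("LIFWCMVY", "PATGS", "HQRKNED"),
  Polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  Charge = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  SecondaryStructure = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  # buried / exposed / intermediate
  SolventAccessibility = c("ALFCGIVW", "PKQEND", "MRSTHY")
)

.ctd_classes <- function(chars, groups) {
  cls <- integer(length(chars))
  for (k in 1:3) {
    cls[chars %in% strsplit(groups[k], "")[[1]]] <- k
  }
  cls
}

#' Composition-transition-distribution descriptors
#'
#' For each of seven physicochemical properties (hydrophobicity, normalized
#' van der Waals volume, polarity, polarizability, charge, secondary
#' structure, solvent accessibility) residues are mapped to 3 classes.
#' Composition (`_C_<k>`) is the class fraction, transition (`_T_<jk>`) the
#' fraction of adjacent residue pairs crossing between classes j and k, and
#' distribution (`_D_<k>_<q>`) the relative sequence position (percent of N)
#' at which the first, 25%, 50%, 75% and 100% occurrences of class k are
#' found (0 when the class is absent). 21 features per property, 147 total.
#'
#' @param sequence Protein sequence over the standard alphabet (N >= 2).
#' @return Named numeric vector of length 147.
#' @export
ctd <- function(sequence) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 2L) stop("CTD transitions need N >= 2", call. = FALSE)
  out <- lapply(names(CTD_PROPERTIES), function(prop) {
    cls <- .ctd_classes(chars, CTD_PROPERTIES[[prop]])
    comp <- tabulate(cls, nbins = 3L) / n
    a <- cls[-n]
    b <- cls[-1]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    trans <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
               sum(lo == 2 & hi == 3)) / (n - 1L)
    dist <- unlist(lapply(1:3, function(k) {
      pos <- which(cls == k)
      cnt <- length(pos)
      qs <- c(0, 0.25, 0.5, 0.75, 1)
      v <- if (cnt == 0L) rep(0, 5) else {
        vapply(qs, function(q) {
          idx <- if (q == 0) 1L else max(1L, floor(q * cnt))
          100 * pos[idx] / n
        }, numeric(1))
      }
      setNames(v, paste0("CTD_", prop, "_D_", k, "_", c(0, 25, 50, 75, 100)))
    }))
    c(setNames(comp, paste0("CTD_", prop, "_C_", 1:3)),
      setNames(trans, paste0("CTD_", prop, "_T_", c("12", "13", "23"))),
      dist)
  })
  unlist(out)
}

#' Full descriptor vector for one sequence
#'
#' Concatenates the enabled families in the fixed order AAC, DPC, MoranAuto,
#' PAAC, APAAC, CTD so that every protein computed under the same
#' configuration shares an identical feature-name schema.
#'
#' @param sequence Protein sequence over the standard alphabet.
#' @param config A [descriptor_config()].
#' @return Named numeric vector.
#' @export
descriptor_vector <- function(sequence, config = descriptor_config()) {
  parts <- list()
  fams <- config$families
  if ("AAC" %in% fams) parts$aac <- aa_composition(sequence)
  if ("DPC" %in% fams) parts$dpc <- dipeptide_composition(sequence)
  if ("MoranAuto" %in% fams) parts$moran <- moran_profile(sequence, config)
  if ("PAAC" %in% fams) parts$paac <- paac(sequence, config)
  if ("APAAC" %in% fams) parts$apaac <- apaac(sequence, config)
  if ("CTD" %in% fams) parts$ctd <- ctd(sequence)
  unlist(unname(parts))
}

#' Compute a descriptor matrix for a protein collection
#'
#' Applies [descriptor_vector()] to every record. Proteins that do not meet a
#' family's length requirement (e.g. shorter than the maximum Moran lag, or
#' not longer than `paac_lambda`) are excluded with a logged reason rather
#' than zero-padded, since padding would fabricate signal.
#'
#' @param records Tibble with columns `id` and `sequence` (natural alphabet).
#' @param config A [descriptor_config()].
#' @return A tibble with column `id` and one numeric column per feature.
#'   Excluded ids and reasons are attached as attribute `"excluded"`.
#' @export
compute_descriptors <- function(records, config = descriptor_config()) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  vecs <- vector("list", nrow(records))
  reasons <- character(0)
  for (i in seq_len(nrow(records))) {
    vecs[[i]] <- tryCatch(descriptor_vector(records$sequence[i], config),
                          error = function(e) conditionMessage(e))
  }
  ok <- vapply(vecs, is.numeric, logical(1))
  if (any(!ok)) {
    reasons <- setNames(unlist(vecs[!ok]), records$id[!ok])
    message("Excluded ", sum(!ok), " protein(s) from the feature matrix: ",
            paste(head(records$id[!ok], 10), collapse = ", "))
  }
  if (!any(ok)) {
    stop("No protein satisfied the length requirements of the enabled ",
         "descriptor families", call. = FALSE)
  }
  mat <- do.call(rbind, vecs[ok])
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(id = records$id[ok]), out)
  attr(out, "excluded") <- reasons
  attr(out, "schema_id") <- rlang::hash(list(config, colnames(mat)))
  out
}

#' Descriptor schema metadata
#'
#' @param features A feature matrix from [compute_descriptors()].
#' @return A list with the feature names and schema hash, suitable for
#'   serializing alongside the matrix.
#' @export
descriptor_schema <- function(features) {
  list(schema_id = attr(features, "schema_id"),
       n_features = ncol(features) - 1L,
       features = setdiff(names(features), "id"))
}
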