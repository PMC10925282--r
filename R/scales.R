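# Property-scale resources: one TSV per scale under inst/extdata/scales,
# columns letter<TAB>value, provenance documented in '#' header lines.

.scale_dir <- function() {
  system.file("extdata", "scales", package = "ppiselect", mustWork = TRUE)
}

#' List the property scales shipped with the package
#'
#' @return Character vector of scale names usable in
#'   [property_scale()] and [descriptor_config()].
#' @export
list_property_scales <- function() {
  sub("\\.tsv$", "", list.files(.scale_dir(), pattern = "\\.tsv$"))
}

#' Load a per-residue physicochemical property scale
#'
#' Scales map each of the 20 standard amino acids to a real number (e.g.
#' relative mutability, steric parameter). When `standardize = TRUE` the scale
#' is centred to zero mean and unit standard deviation over the 20 letters,
#' the convention used before computing autocorrelation descriptors. Moran
#' autocorrelation is invariant to this affine rescaling, so it only fixes a
#' common reporting convention.
#'
#' @param name Scale name, one of [list_property_scales()].
#' @param standardize Centre and scale the 20 values.
#' @return A named numeric vector of length 20 (names are residue letters).
#' @export
property_scale <- function(name, standardize = FALSE) {
  path <- file.path(.scale_dir(), paste0(name, ".tsv"))
  if (!file.exists(path)) {
    stop("Unknown property scale '", name, "'; available: ",
         paste(list_property_scales(), collapse = ", "), call. = FALSE)
  }
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("character", "numeric"))
  vals <- setNames(df$value, df$letter)
  if (!setequal(names(vals), AMINO_ACIDS) || length(vals) != 20L) {
    stop("Scale file ", path, " must define exactly the 20 standard letters",
         call. = FALSE)
  }
  vals <- vals[AMINO_ACIDS]
  if (!all(is.finite(vals))) {
    stop("Scale '", name, "' contains non-finite values", call. = FALSE)
  }
  if (standardize) {
    vals <- (vals - mean(vals)) / sd(vals)
  }
  vals
}

# Chou-style normalization used by PAAC/APAAC: centre over the 20 letters and
# divide by the population (n = 20) standard deviation.
.paac_normalize <- function(vals) {
  (vals - mean(vals)) / sqrt(sum((vals - mean(vals))^2) / 20)
}
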