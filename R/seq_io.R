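#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a tibble of
#' protein records. Sequences are uppercased, terminal `*` stop characters are
#' stripped, and the record identifier is the first whitespace-delimited token
#' of the header line. Duplicate identifiers are rejected because descriptors
#' and pair tables address proteins by id.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`. An empty file yields a
#'   zero-row tibble.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV", ">p2", "ACDE"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("Malformed FASTA: line ", nonblank[1],
         " contains sequence data before any '>' header: ",
         substr(lines[nonblank[1]], 1, 40), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("Malformed FASTA: record ", which(!nzchar(ids))[1],
         " has an empty identifier", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("Duplicate sequence ID(s) in FASTA: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("Empty sequence for ID(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Keep only proteins over the 20-letter standard alphabet
#'
#' Proteins containing any non-natural letter (including the ambiguity and
#' rare-residue codes B, J, O, U, X, Z and internal `*`) are excluded, since
#' every descriptor family is defined only on the 20 standard amino acids.
#'
#' @param records A tibble with columns `id` and `sequence`.
#' @param strict If `TRUE`, any non-natural letter raises an error naming the
#'   protein and position instead of filtering it out.
#' @return A list with elements `kept` (tibble of valid records) and
#'   `excluded` (character vector of removed ids).
#' @export
filter_natural <- function(records, strict = FALSE) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  bad_at <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", records$sequence)
  ok <- bad_at < 0L & nzchar(records$sequence)
  if (strict && any(!ok)) {
    i <- which(!ok)[1]
    if (!nzchar(records$sequence[i])) {
      stop("Protein '", records$id[i], "' has an empty sequence",
           call. = FALSE)
    }
    pos <- as.integer(bad_at[i])
    stop("Non-natural residue '", substr(records$sequence[i], pos, pos),
         "' in protein '", records$id[i], "' at position ", pos,
         call. = FALSE)
  }
  excluded <- records$id[!ok]
  if (length(excluded) > 0L) {
    message("Excluded ", length(excluded),
            " protein(s) with non-natural residues: ",
            paste(head(excluded, 10), collapse = ", "))
  }
  list(kept = records[ok, , drop = FALSE], excluded = excluded)
}

#' Read a labeled protein-pair table
#'
#' Reads a tab-separated table with header columns `id_a`, `id_b`, `label`
#' (`#` comment lines ignored). Pairs referencing proteins absent from
#' `records` (for example proteins excluded for non-natural residues) are
#' dropped with a logged count; labels outside \{0, 1\} are an error.
#'
#' @param path Path to the TSV file.
#' @param records Tibble of protein records the pairs must resolve against.
#' @return A tibble with columns `id_a`, `id_b` and integer `label`.
#' @export
read_pairs <- function(path, records) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          id_a = readr::col_character(),
                          id_b = readr::col_character(),
                          label = readr::col_double()))
  if (!all(c("id_a", "id_b", "label") %in% names(df))) {
    stop("Pair table must have columns id_a, id_b, label", call. = FALSE)
  }
  bad <- !df$label %in% c(0, 1)
  if (any(bad)) {
    stop("Pair labels must be 0 or 1; offending row(s): ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  known <- df$id_a %in% records$id & df$id_b %in% records$id
  if (any(!known)) {
    message("Dropped ", sum(!known),
            " pair(s) referencing unknown or excluded proteins")
  }
  tibble::tibble(id_a = df$id_a[known], id_b = df$id_b[known],
                 label = as.integer(df$label[known]))
}

#' Write a labeled protein-pair table
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `label`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("id_a", "id_b", "label")], path)
  invisible(path)
}

#' Count pairs per interaction label
#'
#' Balanced designs (equal numbers of interacting and non-interacting pairs)
#' keep the classifier and its accuracy-type metrics unbiased; this helper
#' reports the counts so balance can be checked.
#'
#' @param pairs Tibble with a `label` column.
#' @return A tibble with columns `label` and `n`.
#' @export
pair_balance <- function(pairs) {
  dplyr::count(
    tibble::tibble(label = as.integer(pairs$label)), .data$label)
}

#' Write a protein feature matrix as TSV
#'
#' @param features Tibble whose first column is `id` followed by numeric
#'   feature columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(names(features)[1] == "id")
  readr::write_tsv(features, path)
  invisible(path)
}

#' Read a protein feature matrix from TSV
#'
#' @param path Path written by [write_feature_matrix()].
#' @return A tibble with column `id` and numeric feature columns.
#' @export
read_feature_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    .default = readr::col_double()))
}
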