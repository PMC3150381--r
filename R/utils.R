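# Internal helpers shared across modules.

DNA_OK <- c("A", "C", "G", "T", "N", "-")
AMBIG <- c("N", "-")

#' Normalise a species label for joining across input files
#'
#' Species names are the join key between the FASTA, catch, taxonomy and
#' trophic tables. Joins use exact string match after replacing underscores
#' with spaces, squishing whitespace and case-folding; the original spelling
#' is kept for display.
#'
#' @param x character vector of species names.
#' @return character vector of canonical keys.
#' @keywords internal
species_key <- function(x) {
  tolower(stringr::str_squish(gsub("_", " ", x, fixed = TRUE)))
}

# Character matrix (one row per sequence) from equal-length strings.
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(character(), nrow = 0L, ncol = 0L))
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    abort("All sequences must have equal length (an aligned set).")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

# Validate a DNA string vector over {A,C,G,T,N,-}; report offender position.
check_dna_alphabet <- function(seqs, ids = NULL) {
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    who <- if (is.null(ids)) paste0("sequence ", i) else paste0("record '", ids[i], "'")
    abort(sprintf(
      "Illegal character '%s' at position %d in %s (alphabet is A,C,G,T,N,-).",
      substr(seqs[i], bad[i], bad[i]), bad[i], who
    ))
  }
  invisible(seqs)
}

# Extract a sequence column from the tibble/vector polymorphic inputs used
# by the diversity functions.
as_sequence_tbl <- function(x, arg = "x") {
  if (is.character(x)) {
    return(tibble::tibble(
      sample_id = if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x),
      species = NA_character_,
      sequence = toupper(x)
    ))
  }
  if (is.data.frame(x)) {
    if (!"sequence" %in% names(x)) {
      abort(sprintf("`%s` must have a `sequence` column.", arg))
    }
    out <- tibble::as_tibble(x)
    if (!"sample_id" %in% names(out)) out$sample_id <- paste0("seq", seq_len(nrow(out)))
    if (!"species" %in% names(out)) out$species <- NA_character_
    out$sequence <- toupper(out$sequence)
    return(out)
  }
  abort(sprintf("`%s` must be a data frame with a `sequence` column or a character vector.", arg))
}

# Stable order: descending by `by`, ties kept in input order.
order_desc_stable <- function(by) order(-by, seq_along(by))
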