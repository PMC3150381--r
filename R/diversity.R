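#' Collapse aligned sequences into unique haplotypes
#'
#' Haplotypes are defined by exact string identity over `A,C,G,T`.
#' Sequences containing ambiguity (`N` or `-`) are merged into an existing
#' unambiguous haplotype only when they are identical to exactly ONE of them
#' at all their unambiguous sites; otherwise they are kept as distinct
#' haplotypes. This conservative rule avoids inventing identity that the
#' data cannot support.
#'
#' @param seqs a data frame with columns `sequence` and (optionally)
#'   `species`, `sample_id` — e.g. from [read_fasta()] — or a character
#'   vector of equal-length sequences.
#' @return a tibble of class `haplotype_table` with columns `hap_id`,
#'   `haplotype` (the sequence), `count` and `species` (list column of
#'   contributing species), sorted by descending count then sequence.
#'   Attributes: `n` (sample size) and `L` (alignment length).
#' @examples
#' collapse_haplotypes(c("ACGT", "ACGT", "ACGA"))
#' @export
collapse_haplotypes <- function(seqs) {
  seqs <- as_sequence_tbl(seqs, "seqs")
  check_dna_alphabet(seqs$sequence, seqs$sample_id)
  m <- seq_char_matrix(seqs$sequence)  # errors on unequal lengths
  n <- nrow(seqs)
  if (n == 0L) {
    out <- tibble::tibble(hap_id = character(), haplotype = character(),
                          count = integer(), species = list())
    return(structure(out, class = c("haplotype_table", class(out)), n = 0L, L = 0L))
  }
  L <- ncol(m)
  has_ambig <- grepl("[N-]", seqs$sequence)

  groups <- split(seq_len(n), seqs$sequence)          # exact identity first
  states <- names(groups)
  first_seen <- vapply(groups, min, 0L)
  ord <- order(first_seen)
  states <- states[ord]; groups <- groups[ord]
  is_amb <- grepl("[N-]", states)

  clean_states <- states[!is_amb]
  assigned <- setNames(vector("list", length(states)), states)
  for (s in states) assigned[[s]] <- groups[[s]]
  kept_amb <- character()
  for (s in states[is_amb]) {
    sv <- strsplit(s, "", fixed = TRUE)[[1L]]
    unamb <- !(sv %in% AMBIG)
    compatible <- clean_states[vapply(clean_states, function(cs) {
      all(strsplit(cs, "", fixed = TRUE)[[1L]][unamb] == sv[unamb])
    }, TRUE)]
    if (length(compatible) == 1L) {
      assigned[[compatible]] <- c(assigned[[compatible]], assigned[[s]])
      assigned[[s]] <- NULL
    } else {
      kept_amb <- c(kept_amb, s)
    }
  }
  kept <- c(clean_states, kept_amb)
  counts <- vapply(assigned[kept], length, 0L)
  spp <- lapply(assigned[kept], function(i) sort(unique(seqs$species[i])))
  out <- tibble::tibble(haplotype = kept, count = unname(counts),
                        species = unname(spp))
  out <- out[order(-out$count, out$haplotype), ]
  out <- tibble::add_column(out, hap_id = paste0("H", seq_len(nrow(out))),
                            .before = 1L)
  structure(out, class = c("haplotype_table", class(out)), n = n, L = L)
}

#' Haplotypic (gene) diversity with standard deviation
#'
#' Nei's unbiased haplotype diversity
#' \eqn{Hd = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)} with its sampling
#' standard deviation (Nei 1987, eq. 8.12). `Hd` is the small-sample
#' corrected probability that two sequences drawn from the pooled sample
#' are different haplotypes.
#'
#' @param ht a `haplotype_table` from [collapse_haplotypes()], or a numeric
#'   vector of haplotype counts.
#' @return a one-row tibble with columns `Hd`, `sd`, `k` (haplotypes) and
#'   `n` (sample size).
#' @export
haplotype_diversity <- function(ht) {
  counts <- if (is.data.frame(ht)) ht$count else ht
  if (!is.numeric(counts) || any(counts < 1)) abort("Haplotype counts must be positive.")
  n <- sum(counts)
  if (n < 2) abort("Haplotype diversity needs a sample of at least 2 sequences.")
  p <- counts / n
  s2 <- sum(p^2)
  Hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  tibble::tibble(Hd = Hd, sd = sqrt(max(v, 0)), k = length(counts), n = n)
}

#' Pooled nucleotide diversity with standard deviation
#'
#' \eqn{\pi} is the mean proportion of differing sites over all
#' \eqn{\binom{n}{2}} sequence pairs of the pooled sample, with pairwise
#' deletion of sites where either sequence carries `N` or `-`. All
#' sequences are considered together without separating species. The
#' standard deviation uses Nei's (1987, eq. 10.7) total variance formula.
#'
#' @param seqs a data frame with a `sequence` column, a character vector of
#'   equal-length sequences, or a `haplotype_table` (its counts are used).
#' @return a one-row tibble with columns `pi` (per site), `sd`,
#'   `n` (sequences) and `L` (alignment length).
#' @examples
#' nucleotide_diversity(c("AAAA", "AAAT", "AATT", "TTTT"))  # pi = 0.5417
#' @export
nucleotide_diversity <- function(seqs) {
  if (inherits(seqs, "haplotype_table")) {
    states <- seqs$haplotype
    counts <- seqs$count
    n <- attr(seqs, "n")
  } else {
    tbl <- as_sequence_tbl(seqs, "seqs")
    check_dna_alphabet(tbl$sequence)
    grp <- table(tbl$sequence)
    states <- names(grp)
    counts <- as.integer(grp)
    n <- nrow(tbl)
  }
  if (n < 2) abort("Nucleotide diversity needs at least 2 sequences.")
  m <- seq_char_matrix(states)
  L <- ncol(m)
  if (L == 0L) abort("Zero-length alignment.")
  ok <- !(m == "N" | m == "-")
  k <- length(states)
  total <- 0
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        comp <- ok[i, ] & ok[j, ]
        n_comp <- sum(comp)
        if (n_comp == 0L) {
          abort(sprintf("Sequence pair (%d, %d) has no comparable sites.", i, j))
        }
        diff <- sum(m[i, comp] != m[j, comp])
        total <- total + counts[i] * counts[j] * diff / n_comp
      }
    }
  }
  n_pairs <- n * (n - 1) / 2
  pi <- total / n_pairs
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  tibble::tibble(pi = pi, sd = sqrt(max(v, 0)), n = n, L = L)
}

#' Translate a COI barcode under the vertebrate mitochondrial code
#'
#' Translation uses the vertebrate mitochondrial genetic code (NCBI
#' translation table 2: `TGA` = Trp, `AGA`/`AGG` = Ter, `ATA` = Met).
#' Trailing partial codons are dropped; any codon containing ambiguity
#' (`N`, or `-` which is treated as `N`) translates to `X`, even when every
#' resolution would agree — a deliberately conservative policy, since codon
#' resolution differs between genetic codes. Barcode amplicons do not start
#' in frame
#' universally, so `frame = "auto"` picks the single reading frame with no
#' internal stop codon and errors when none or several qualify.
#'
#' @param seq character vector of DNA sequences over `A,C,G,T,N,-`.
#' @param frame `"auto"` (default) or a fixed frame offset 1, 2 or 3. A
#'   forced frame whose translation contains a stop is an error.
#' @return character vector of amino-acid sequences.
#' @examples
#' translate_coi("ATGGCC", frame = 1)  # "MA"
#' translate_coi("TGA", frame = 1)     # "W"
#' @export
translate_coi <- function(seq, frame = "auto") {
  stopifnot(is.character(seq))
  if (length(seq) == 0L) return(character())
  seq <- toupper(seq)
  check_dna_alphabet(seq)
  if (!identical(frame, "auto") &&
      !(is.numeric(frame) && length(frame) == 1L && frame %in% 1:3)) {
    abort("`frame` must be \"auto\" or one of 1, 2, 3.")
  }
  frames <- if (identical(frame, "auto")) 1:3 else as.integer(frame)
  aa_by_frame <- lapply(frames, function(off) translate_frame(seq, off))
  if (!identical(frame, "auto")) {
    aa <- aa_by_frame[[1L]]
    bad <- grepl("*", aa, fixed = TRUE)
    if (any(bad)) {
      abort(sprintf("Internal stop codon in forced frame %d (sequence %d).",
                    frames, which(bad)[1L]))
    }
    return(aa)
  }
  vapply(seq_along(seq), function(i) {
    aa_i <- vapply(aa_by_frame, `[[`, "", i)
    open <- !grepl("*", aa_i, fixed = TRUE) & nchar(aa_i) > 0L
    if (sum(open) == 0L) {
      abort(sprintf("No stop-free reading frame for sequence %d.", i))
    }
    if (sum(open) > 1L) {
      abort(sprintf("Ambiguous reading frame for sequence %d (frames %s are stop-free).",
                    i, paste(which(open), collapse = ", ")))
    }
    aa_i[which(open)]
  }, "")
}

# Translate all sequences at a given frame offset; returns "" when too short.
translate_frame <- function(seq, off) {
  sub <- substring(seq, off)
  len <- nchar(sub) - nchar(sub) %% 3L
  out <- rep("", length(seq))
  idx <- which(len >= 3L)
  if (length(idx) == 0L) return(out)
  dna <- gsub("-", "N", substring(sub[idx], 1L, len[idx]), fixed = TRUE)
  aa <- Biostrings::translate(Biostrings::DNAStringSet(dna),
                              genetic.code = Biostrings::getGeneticCode("2"),
                              if.fuzzy.codon = "X")
  out[idx] <- as.character(aa)
  out
}

#' Collapse haplotypes into unique polypeptide variants
#'
#' Translates every haplotype with [translate_coi()] and groups identical
#' amino-acid sequences, summing counts and pooling contributing species.
#' Because COI is highly conserved, most intraspecific haplotypes are
#' synonymous and collapse onto one protein per species (or per genus).
#'
#' @param ht a `haplotype_table` from [collapse_haplotypes()].
#' @param frame passed to [translate_coi()].
#' @return a tibble of class `protein_table` with columns `protein_id`,
#'   `protein`, `count`, `n_haplotypes` and `species` (list column), sorted
#'   by descending count then sequence. Attributes: `n` (sample size) and
#'   `P` (number of variants).
#' @export
collapse_proteins <- function(ht, frame = "auto") {
  stopifnot(inherits(ht, "haplotype_table"))
  aa <- vapply(seq_len(nrow(ht)), function(i) {
    tryCatch(translate_coi(ht$haplotype[i], frame = frame),
             error = function(e) {
               abort(sprintf("Translation failed for haplotype %s: %s",
                             ht$hap_id[i], conditionMessage(e)))
             })
  }, "")
  groups <- split(seq_len(nrow(ht)), aa)
  out <- tibble::tibble(
    protein = names(groups),
    count = unname(vapply(groups, function(i) sum(ht$count[i]), 0)),
    n_haplotypes = unname(vapply(groups, length, 0L)),
    species = lapply(groups, function(i) sort(unique(unlist(ht$species[i]))))
  )
  out <- out[order(-out$count, out$protein), ]
  out$species <- unname(out$species)
  out <- tibble::add_column(out, protein_id = paste0("P", seq_len(nrow(out))),
                            .before = 1L)
  structure(out, class = c("protein_table", class(out)),
            n = attr(ht, "n"), P = nrow(out))
}

#' Haplotypes-per-polypeptide ratio
#'
#' The number of distinct DNA haplotypes divided by the number of distinct
#' translated protein variants: a proxy for the synonymous ("hidden")
#' genetic diversity of the pooled sample. Always at least 1.
#'
#' @param ht a `haplotype_table` (or the haplotype count `k`).
#' @param pt a `protein_table` (or the protein count `P`).
#' @return a single number `k / P`.
#' @examples
#' haplotypes_per_protein(17, 4)  # 4.25
#' @export
haplotypes_per_protein <- function(ht, pt) {
  k <- if (is.data.frame(ht)) nrow(ht) else ht
  P <- if (is.data.frame(pt)) nrow(pt) else pt
  if (P < 1) abort("At least one protein variant is required.")
  as.numeric(k) / as.numeric(P)
}
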