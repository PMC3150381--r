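#' Read species-labelled barcode sequences from FASTA
#'
#' Headers must follow the dialect `>sample_id|Genus_species[|region]`;
#' underscores in the species field are converted to spaces. Sequences are
#' upper-cased and validated over the alphabet `A,C,G,T,N,-`.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `sample_id`, `species`, `region` (NA when
#'   absent) and `sequence`, one row per FASTA record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">A1|Salmo_trutta|Asturias", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file '%s' does not exist.", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    return(tibble::tibble(sample_id = character(), species = character(),
                          region = character(), sequence = character()))
  }
  headers <- names(ss)
  parts <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 2L)) {
    abort(sprintf("Malformed FASTA header (no species field): '>%s'.",
                  headers[which(n_fields < 2L)[1L]]))
  }
  species <- stringr::str_squish(gsub("_", " ", vapply(parts, `[[`, "", 2L)))
  if (any(species == "")) {
    abort(sprintf("Malformed FASTA header (empty species field): '>%s'.",
                  headers[which(species == "")[1L]]))
  }
  seqs <- toupper(as.character(ss))
  check_dna_alphabet(seqs, ids = vapply(parts, `[[`, "", 1L))
  tibble::tibble(
    sample_id = vapply(parts, `[[`, "", 1L),
    species = species,
    region = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, ""),
    sequence = unname(seqs)
  )
}

#' Write species-labelled sequences to FASTA
#'
#' Inverse of [read_fasta()]: headers are `sample_id|Genus_species[|region]`
#' with spaces in species converted to underscores.
#'
#' @param seqs a data frame with columns `sample_id`, `species`, `sequence`
#'   and optionally `region`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequence_tbl(seqs, "seqs")
  sp <- gsub(" ", "_", seqs$species)
  hdr <- paste0(seqs$sample_id, "|", sp)
  if ("region" %in% names(seqs)) {
    has_region <- !is.na(seqs$region)
    hdr[has_region] <- paste0(hdr[has_region], "|", seqs$region[has_region])
  }
  writeLines(paste0(">", hdr, "\n", seqs$sequence), path)
  invisible(path)
}

# Shared TSV/CSV reader; delim chosen by flag, headers required.
read_delim_table <- function(path, delim, required, what) {
  if (!file.exists(path)) abort(sprintf("%s file '%s' does not exist.", what, path))
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE, col_types = readr::cols(.default = "c"))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    abort(sprintf("%s table is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  tab
}

#' Read a catch-composition table
#'
#' One row per species with its annual catch in tons. Tonnage may contain
#' thousands separators (`"16,086"` parses to 16086).
#'
#' @param path path to a delimited file with columns `species` and `tonnage`.
#' @param delim field delimiter, tab by default.
#' @return a tibble with columns `species` (character) and `tonnage` (double).
#' @export
read_catch_table <- function(path, delim = "\t") {
  tab <- read_delim_table(path, delim, c("species", "tonnage"), "Catch")
  tonnage <- readr::parse_number(tab$tonnage,
                                 locale = readr::locale(grouping_mark = ","))
  if (any(is.na(tonnage))) {
    abort(sprintf("Unparseable tonnage value '%s' for species '%s'.",
                  tab$tonnage[which(is.na(tonnage))[1L]],
                  tab$species[which(is.na(tonnage))[1L]]))
  }
  if (any(tonnage < 0)) {
    abort(sprintf("Negative tonnage (%s) for species '%s'.",
                  tonnage[which(tonnage < 0)[1L]], tab$species[which(tonnage < 0)[1L]]))
  }
  key <- species_key(tab$species)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate species in catch table: '%s'.", tab$species[duplicated(key)][1L]))
  }
  tibble::tibble(species = tab$species, tonnage = tonnage)
}

TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Read a six-rank taxonomy table
#'
#' One row per species with its full Linnean lineage. The hierarchy must be
#' internally consistent: each genus maps to exactly one family, each family
#' to one order, and so on up to phylum.
#'
#' @param path path to a delimited file with columns `species`, `genus`,
#'   `family`, `order`, `class`, `phylum`.
#' @param delim field delimiter, tab by default.
#' @return a tibble with the six rank columns, species first.
#' @export
read_taxonomy_table <- function(path, delim = "\t") {
  tab <- read_delim_table(path, delim, rev(TAXONOMY_RANKS), "Taxonomy")
  out <- tibble::as_tibble(tab[rev(TAXONOMY_RANKS)])
  validate_taxonomy(out)
}

#' @rdname read_taxonomy_table
#' @param taxonomy a data frame with the six rank columns, checked for
#'   non-empty names and hierarchy consistency.
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- tibble::as_tibble(taxonomy)
  missing <- setdiff(rev(TAXONOMY_RANKS), names(taxonomy))
  if (length(missing) > 0L) {
    abort(sprintf("Taxonomy is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(taxonomy) == 0L) return(taxonomy)
  for (r in TAXONOMY_RANKS) {
    v <- taxonomy[[r]]
    if (any(is.na(v) | stringr::str_squish(v) == "")) {
      abort(sprintf("Empty %s name in taxonomy table.", r))
    }
  }
  key <- species_key(taxonomy$species)
  if (anyDuplicated(key)) {
    dup <- taxonomy$species[duplicated(key)][1L]
    abort(sprintf("Duplicate species in taxonomy table: '%s'.", dup))
  }
  # child rank -> parent rank must be a function
  pairs <- list(c("genus", "family"), c("family", "order"),
                c("order", "class"), c("class", "phylum"))
  for (p in pairs) {
    child <- taxonomy[[p[1L]]]
    parent <- taxonomy[[p[2L]]]
    tab <- unique(data.frame(child, parent))
    if (anyDuplicated(tab$child)) {
      bad <- tab$child[duplicated(tab$child)][1L]
      abort(sprintf(
        "Inconsistent taxonomy: %s '%s' is assigned to more than one %s (%s).",
        p[1L], bad, p[2L], paste(unique(tab$parent[tab$child == bad]), collapse = ", ")))
    }
  }
  taxonomy
}

#' Read a species trophic-level table
#'
#' @param path path to a delimited file with columns `species` and
#'   `trophic_level` (positive reals, e.g. from FishBase).
#' @param delim field delimiter, tab by default.
#' @return a tibble with columns `species` and `trophic_level`.
#' @export
read_trophic_table <- function(path, delim = "\t") {
  tab <- read_delim_table(path, delim, c("species", "trophic_level"), "Trophic")
  tl <- readr::parse_double(tab$trophic_level)
  if (any(is.na(tl)) || any(tl <= 0)) {
    i <- which(is.na(tl) | tl <= 0)[1L]
    abort(sprintf("Trophic level must be a positive number; got '%s' for species '%s'.",
                  tab$trophic_level[i], tab$species[i]))
  }
  tibble::tibble(species = tab$species, trophic_level = tl)
}

#' Write a phylogenetic tree in newick format
#'
#' @param tree an `ape::phylo` tree, e.g. from [neighbor_joining()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a haplotype network to disk
#'
#' `edge_tsv` writes one row per edge with columns `state_a`, `state_b` and
#' `mutations`; `gml` writes the full annotated graph (node type
#' observed/median, observed counts, species) in GML.
#'
#' @param graph an `igraph` network from [median_joining_network()].
#' @param path output path.
#' @param format `"edge_tsv"` or `"gml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("edge_tsv", "gml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "igraph"))
  if (format == "gml") {
    igraph::write_graph(graph, path, format = "gml")
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    states <- setNames(igraph::V(graph)$state, igraph::V(graph)$name)
    edges <- tibble::tibble(
      state_a = unname(states[el[, 1L]]),
      state_b = unname(states[el[, 2L]]),
      mutations = if (igraph::ecount(graph) > 0L) igraph::E(graph)$mutations else integer()
    )
    readr::write_tsv(edges, path)
  }
  invisible(path)
}

#' Read a haplotype-network edge list written by [write_network()]
#'
#' @param path path to an `edge_tsv` file.
#' @return a tibble with columns `state_a`, `state_b`, `mutations`.
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(state_a = "c", state_b = "c",
                                          mutations = "i"))
}
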