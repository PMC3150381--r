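#' Build a six-rank taxonomy tree
#'
#' Constructs the rooted Linnean tree (root, phylum, class, order, family,
#' genus, species) underlying the taxonomic distinctness indices. Every
#' edge carries the same step weight, normalised so the longest possible
#' path between two species (different phyla: six steps up) equals 100,
#' i.e. 100/6 per step. A single synthetic root sits above all phyla, so
#' each distinct phylum contributes one root edge.
#'
#' @param taxonomy a data frame with columns `species`, `genus`, `family`,
#'   `order`, `class`, `phylum`, e.g. from [read_taxonomy_table()].
#' @return an object of class `taxonomy_tree`: a list with `lineages`
#'   (tibble keyed by species), `edges` (tibble of parent/child node paths
#'   with rank), `step_weight` (100/6) and `ranks`.
#' @export
build_taxonomy_tree <- function(taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  ranks <- TAXONOMY_RANKS  # phylum .. species
  lineages <- tibble::as_tibble(taxonomy[rev(ranks)])
  lineages$key <- species_key(lineages$species)
  # node path ids disambiguate homonyms at different positions
  paths <- lapply(seq_along(ranks), function(d) {
    apply(as.data.frame(taxonomy[ranks[seq_len(d)]]), 1L, paste, collapse = "/")
  })
  edges <- purrr::map_dfr(seq_along(ranks), function(d) {
    parent <- if (d == 1L) rep("root", nrow(taxonomy)) else paths[[d - 1L]]
    tibble::tibble(parent = parent, child = paths[[d]], rank = ranks[d])
  })
  edges <- dplyr::distinct(edges)
  structure(list(lineages = lineages, edges = edges,
                 step_weight = 100 / 6, ranks = ranks),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("Six-rank taxonomy tree: %d species, %d edges, step weight %.4g\n",
              nrow(x$lineages), nrow(x$edges), x$step_weight))
  invisible(x)
}

tree_lineage <- function(tree, species) {
  key <- species_key(species)
  idx <- match(key, tree$lineages$key)
  if (anyNA(idx)) {
    abort(sprintf("Species not in taxonomy tree: %s.",
                  paste(species[is.na(idx)], collapse = ", ")))
  }
  tree$lineages[idx, , drop = FALSE]
}

#' Taxonomic path weight between two species
#'
#' The Clarke–Warwick style distinctness weight: the number of ranks
#' ascended from a species to the lowest taxon shared with the other
#' species, times the step weight 100/6. Congeners score 100/6 (~16.7),
#' confamilial species 200/6 (~33.3), and species in different phyla 100.
#'
#' @param tree a `taxonomy_tree` from [build_taxonomy_tree()].
#' @param sp_i,sp_j species names present in the tree.
#' @return a single non-negative number; 0 when `sp_i` and `sp_j` are the
#'   same species.
#' @export
path_weight <- function(tree, sp_i, sp_j) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  li <- tree_lineage(tree, sp_i)
  lj <- tree_lineage(tree, sp_j)
  # ranks from species upward: species, genus, family, order, class, phylum
  up <- rev(tree$ranks)
  steps <- 6L
  for (m in seq_along(up)) {
    if (identical(li[[up[m]]], lj[[up[m]]])) { steps <- m - 1L; break }
  }
  steps * tree$step_weight
}

#' Pairwise taxonomic path-weight matrix
#'
#' @inheritParams path_weight
#' @param species character vector of species in the tree.
#' @return a symmetric matrix of path weights with zero diagonal, with
#'   `species` as dimnames.
#' @export
path_weight_matrix <- function(tree, species) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  lin <- tree_lineage(tree, species)
  S <- length(species)
  up <- rev(tree$ranks)
  omega <- matrix(0, S, S, dimnames = list(species, species))
  if (S > 1L) {
    for (i in seq_len(S - 1L)) {
      for (j in (i + 1L):S) {
        steps <- 6L
        for (m in seq_along(up)) {
          if (identical(lin[[up[m]]][i], lin[[up[m]]][j])) { steps <- m - 1L; break }
        }
        omega[i, j] <- omega[j, i] <- steps * tree$step_weight
      }
    }
  }
  omega
}

#' Total taxonomic distinctness (TTD)
#'
#' \eqn{TTD = \sum_i \bigl[\sum_{j \ne i} \omega_{ij} / (S - 1)\bigr]}: the
#' sum over species of the average taxonomic path weight to all other
#' species in the set. Grows with the number of species and with how
#' taxonomically spread they are; suited to comparing spatially independent
#' communities that may differ in composition.
#'
#' @inheritParams path_weight_matrix
#' @return a single number.
#' @examples
#' tax <- tibble::tibble(
#'   species = c("Salmo trutta", "Salmo salar"), genus = "Salmo",
#'   family = "Salmonidae", order = "Salmoniformes",
#'   class = "Actinopterygii", phylum = "Chordata"
#' )
#' tree <- build_taxonomy_tree(tax)
#' total_taxonomic_distinctness(tree, tax$species)  # 33.3
#' @export
total_taxonomic_distinctness <- function(tree, species) {
  S <- length(species)
  if (S < 2L) abort("TTD needs at least 2 species.")
  omega <- path_weight_matrix(tree, species)
  sum(rowSums(omega) / (S - 1))
}

#' Total taxonomic path length (s-Phi+)
#'
#' The summed edge weights of the taxonomy tree spanning the species set
#' and the root — Faith-style phylogenetic diversity on Linnean ranks. With
#' equal step weights this equals 100/6 times the number of distinct taxa
#' across the six ranks (each taxon contributes the edge to its parent;
#' the root edge above each distinct phylum is included). A single species
#' scores exactly 100; adding a congener adds exactly 100/6.
#'
#' @inheritParams path_weight_matrix
#' @return a single number.
#' @export
total_taxonomic_path_length <- function(tree, species) {
  if (length(species) < 1L) abort("s-Phi+ needs at least 1 species.")
  lin <- tree_lineage(tree, species)
  n_taxa <- 0L
  path <- rep("", nrow(lin))
  for (r in tree$ranks) {
    path <- paste(path, lin[[r]], sep = "/")
    n_taxa <- n_taxa + length(unique(path))
  }
  n_taxa * tree$step_weight
}
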