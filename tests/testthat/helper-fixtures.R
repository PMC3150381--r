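# Shared fixtures: printed regional catch tables shipped as extdata, small
# taxonomies, and synthetic community specs built in code.

extdata <- function(name) {
  system.file("extdata", name, package = "metacatch", mustWork = TRUE)
}

amazon_catch <- function() read_catch_table(extdata("catch_amazon.tsv"))
mediterranean_catch <- function() read_catch_table(extdata("catch_mediterranean.tsv"))
cantabric_catch <- function() read_catch_table(extdata("catch_cantabric.tsv"))
rivers_catch <- function() read_catch_table(extdata("catch_spanish_rivers.tsv"))

atlantic_taxonomy <- function() read_taxonomy_table(extdata("taxonomy_atlantic.tsv"))

salmo_taxonomy <- function() {
  tibble::tibble(
    species = c("Salmo trutta", "Salmo salar"), genus = "Salmo",
    family = "Salmonidae", order = "Salmoniformes",
    class = "Actinopterygii", phylum = "Chordata"
  )
}

cantabric_taxonomy <- function() {
  dplyr::filter(atlantic_taxonomy(), species %in% c(
    "Scomber scombrus", "Thunnus alalunga", "Sardina pilchardus",
    "Micromesistius poutassou"
  ))
}

# Random six-rank taxonomy with hierarchy consistency, for property tests.
random_taxonomy <- function(n_species, seed) {
  withr::with_seed(seed, {
    pick <- function(parent, k) paste0(parent, "_", sample.int(k, 1L))
    rows <- purrr::map_dfr(seq_len(n_species), function(i) {
      ph <- paste0("Ph", sample.int(2L, 1L))
      cl <- pick(ph, 2L); or <- pick(cl, 2L)
      fa <- pick(or, 2L); ge <- pick(fa, 2L)
      tibble::tibble(species = paste0("sp", i), genus = ge, family = fa,
                     order = or, class = cl, phylum = ph)
    })
    rows
  })
}

# Two-congener community mirroring a river sport fishery: brown trout with
# 3 synonymous haplotypes dominating the catch, plus Atlantic salmon with a
# single haplotype; explicit 38/2 sample split; congeners share one protein.
asturias_like_spec <- function(seed = 11L) {
  sp <- salmo_taxonomy()
  sp$tonnage <- c(348.6, 9.2)
  sp$k_haplotypes <- c(3L, 1L)
  sp$trophic_level <- c(4.4, 4.5)
  sp$n_samples <- c(38L, 2L)
  community_spec(sp, seed = seed, synonymous_divergence = TRUE,
                 region = "rivers")
}

# Marine-style community: four species, three orders, mixed haplotype
# richness, catch-proportional allocation of 40 sequences.
marine_like_spec <- function(seed = 7L, n = 40L) {
  sp <- cantabric_taxonomy()
  sp <- sp[match(c("Scomber scombrus", "Sardina pilchardus",
                   "Micromesistius poutassou", "Thunnus alalunga"),
                 sp$species), ]
  sp$tonnage <- c(5405.35, 2725.52, 2042.49, 1727.15)
  sp$k_haplotypes <- c(5L, 5L, 4L, 3L)
  sp$trophic_level <- c(3.65, 3.1, 4.01, 4.31)
  community_spec(sp, n = n, seed = seed)
}

# Brute-force pi: double loop over pairs and sites with pairwise deletion.
brute_force_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !(m[i, ] %in% c("N", "-")) & !(m[j, ] %in% c("N", "-"))
      vals <- c(vals, sum(m[i, comp] != m[j, comp]) / sum(comp))
    }
  }
  mean(vals)
}

# Independent TTD oracle: shortest-path distances on an explicitly built
# igraph of the six-rank tree, never using path_weight_matrix().
graph_ttd <- function(taxonomy, species) {
  tree <- build_taxonomy_tree(taxonomy)
  g <- igraph::graph_from_data_frame(tree$edges[, c("parent", "child")],
                                     directed = FALSE)
  lin <- taxonomy[match(tolower(species), tolower(taxonomy$species)), ]
  leaf <- apply(as.data.frame(lin[c("phylum", "class", "order", "family",
                                    "genus", "species")]), 1L,
                paste, collapse = "/")
  d <- igraph::distances(g, v = leaf, to = leaf)
  half <- d * tree$step_weight / 2  # ranks ascended = half the path edges
  S <- length(species)
  sum(rowSums(half) / (S - 1))
}
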