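#' Compute the full community diversity profile of a catch
#'
#' The pipeline behind a one-column community summary: select the dominant
#' species of the catch, restrict the pooled barcode sample to them
#' (unless `include_all = TRUE`), collapse haplotypes and polypeptides,
#' estimate pooled haplotypic and nucleotide diversity, the Shannon index
#' on the observed per-species sequence counts, the taxonomic indices (TTD
#' and total taxonomic path length) on the dominant species, the mean
#' trophic level, and the median-joining haplotype network node counts.
#' Fields whose inputs are missing or insufficient (e.g. TTD with a single
#' species, trophic level without a trophic table) are reported as `NA`
#' and listed, with the reason, in the profile's `unavailable` element.
#'
#' @param fasta sequences: a path to a FASTA file (see [read_fasta()]) or a
#'   data frame with columns `sample_id`, `species`, `sequence`.
#' @param catch catch composition: a path (see [read_catch_table()]) or a
#'   data frame with `species` and `tonnage`.
#' @param taxonomy six-rank taxonomy: a path (see [read_taxonomy_table()])
#'   or a data frame.
#' @param trophic optional trophic levels: a path (see
#'   [read_trophic_table()]) or a data frame; `NULL` marks the trophic
#'   fields unavailable.
#' @param region label for the profile.
#' @param threshold cumulative catch fraction defining the dominant set.
#' @param include_all keep sequences from non-dominant species (default
#'   drops them, matching a survey design that only samples the dominant
#'   catch).
#' @param frame reading-frame policy for translation (see
#'   [translate_coi()]).
#' @param epsilon relaxation for the median-joining network.
#' @param inventory_size optional number of species inventoried in the
#'   ecosystem (reported alongside the dominant species count; it is
#'   user-supplied metadata, never computed).
#' @return an object of class `community_profile`; see [tidy()] and
#'   [glance()] methods, and [write_profile()].
#' @export
compute_profile <- function(fasta, catch, taxonomy, trophic = NULL,
                            region = NA_character_, threshold = 0.65,
                            include_all = FALSE, frame = "auto",
                            epsilon = 0, inventory_size = NA_integer_) {
  seqs <- if (is.character(fasta)) read_fasta(fasta) else as_sequence_tbl(fasta, "fasta")
  catch_tbl <- if (is.character(catch)) read_catch_table(catch) else tibble::as_tibble(catch)
  tax_tbl <- if (is.character(taxonomy)) read_taxonomy_table(taxonomy) else
    validate_taxonomy(taxonomy)
  trophic_tbl <- if (is.character(trophic)) read_trophic_table(trophic) else trophic

  dominant <- select_dominant_species(catch_tbl, threshold)
  dom_keys <- species_key(dominant$species)

  # join checks: every dominant species must be resolvable in the taxonomy
  missing_tax <- dominant$species[!dom_keys %in% species_key(tax_tbl$species)]
  if (length(missing_tax) > 0L) {
    abort(sprintf("Dominant species missing from taxonomy table: %s.",
                  paste(missing_tax, collapse = ", ")))
  }

  if (!include_all) seqs <- seqs[species_key(seqs$species) %in% dom_keys, ]
  if (nrow(seqs) == 0L) abort("No sequences left after restricting to the dominant species.")

  unavailable <- character()
  ht <- collapse_haplotypes(seqs)
  hd <- haplotype_diversity(ht)
  pi <- nucleotide_diversity(ht)
  pt <- collapse_proteins(ht, frame = frame)
  ratio <- haplotypes_per_protein(ht, pt)

  sp_counts <- dplyr::count(seqs, .data$species, name = "n_samples")
  shannon <- shannon_index(sp_counts)

  tree <- build_taxonomy_tree(tax_tbl)
  sphi <- total_taxonomic_path_length(tree, dominant$species)
  if (nrow(dominant) >= 2L) {
    ttd <- total_taxonomic_distinctness(tree, dominant$species)
  } else {
    ttd <- NA_real_
    unavailable <- c(unavailable,
                     ttd = "TTD needs at least 2 dominant species")
  }

  if (!is.null(trophic_tbl)) {
    troph <- mean_trophic_level(dominant$species, trophic_tbl)
    trophic_mean <- troph$mean_trophic_level
    trophic_var <- troph$variance
  } else {
    trophic_mean <- trophic_var <- NA_real_
    unavailable <- c(unavailable,
                     trophic_mean = "no trophic table supplied")
  }

  net <- suppressMessages(median_joining_network(ht, epsilon = epsilon))
  nodes <- count_nodes(net)

  provenance <- list(
    threshold = threshold, include_all = include_all, frame = frame,
    epsilon = epsilon, n_input_sequences = nrow(seqs),
    input_digest = rlang::hash(list(seqs$sequence, seqs$species,
                                    catch_tbl, tax_tbl, trophic_tbl)),
    package_version = as.character(utils::packageVersion("metacatch"))
  )

  structure(list(
    region = region,
    n_sequences = attr(ht, "n"),
    k_haplotypes = nrow(ht),
    p_polypeptides = nrow(pt),
    haplotypes_per_polypeptide = ratio,
    haplotype_diversity = hd$Hd, haplotype_diversity_sd = hd$sd,
    nucleotide_diversity = pi$pi, nucleotide_diversity_sd = pi$sd,
    n_dominant_species = nrow(dominant),
    inventory_size = as.integer(inventory_size),
    shannon_H = shannon$H,
    ttd = ttd,
    s_phi_plus = sphi,
    mean_trophic_level = trophic_mean, trophic_variance = trophic_var,
    network_observed_nodes = nodes$observed,
    network_median_nodes = nodes$median,
    unavailable = unavailable,
    dominant = tibble::as_tibble(dominant),
    sample_counts = sp_counts,
    haplotypes = ht, proteins = pt, network = net,
    provenance = provenance
  ), class = "community_profile")
}

profile_metric_names <- c(
  "n_sequences", "k_haplotypes", "p_polypeptides",
  "haplotypes_per_polypeptide", "haplotype_diversity",
  "haplotype_diversity_sd", "nucleotide_diversity",
  "nucleotide_diversity_sd", "n_dominant_species", "inventory_size",
  "shannon_H", "ttd", "s_phi_plus", "mean_trophic_level",
  "trophic_variance", "network_observed_nodes", "network_median_nodes"
)

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("Community diversity profile%s\n",
              if (is.na(x$region)) "" else paste0(" - ", x$region)))
  cat(sprintf("  sequences: %d pooled over %d dominant species\n",
              x$n_sequences, x$n_dominant_species))
  cat(sprintf("  haplotypes: %d, polypeptides: %d, ratio: %.4g\n",
              x$k_haplotypes, x$p_polypeptides, x$haplotypes_per_polypeptide))
  cat(sprintf("  Hd: %.3f (%.3f), pi: %.3f (%.3f)\n",
              x$haplotype_diversity, x$haplotype_diversity_sd,
              x$nucleotide_diversity, x$nucleotide_diversity_sd))
  cat(sprintf("  Shannon H: %.4f, TTD: %.1f, s-Phi+: %.1f\n",
              x$shannon_H, x$ttd, x$s_phi_plus))
  cat(sprintf("  trophic level: %.3f (%.3f)\n",
              x$mean_trophic_level, x$trophic_variance))
  cat(sprintf("  network: %d observed + %d median nodes\n",
              x$network_observed_nodes, x$network_median_nodes))
  if (length(x$unavailable) > 0L) {
    cat("  unavailable:", paste(sprintf("%s (%s)", names(x$unavailable),
                                        x$unavailable), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy a community profile into a metric table
#'
#' @param x a `community_profile` from [compute_profile()].
#' @param ... ignored.
#' @return a tibble with columns `metric` and `value`, one row per scalar
#'   metric of the profile.
#' @exportS3Method generics::tidy
tidy.community_profile <- function(x, ...) {
  tibble::tibble(
    metric = profile_metric_names,
    value = unname(vapply(profile_metric_names, function(m) as.numeric(x[[m]]), 0))
  )
}

#' One-row summary of a community profile
#'
#' @inheritParams tidy.community_profile
#' @return a one-row tibble: region plus every scalar metric as a column.
#' @exportS3Method generics::glance
glance.community_profile <- function(x, ...) {
  vals <- lapply(profile_metric_names, function(m) x[[m]])
  names(vals) <- profile_metric_names
  tibble::as_tibble(c(list(region = x$region), vals))
}

#' Plot the indices of one or more community profiles
#'
#' Faceted dot plot of the profile's diversity indices, for side-by-side
#' comparison of regional catches.
#'
#' @param object a `community_profile`.
#' @param ... further `community_profile` objects to compare.
#' @return a `ggplot` object.
#' @exportS3Method ggplot2::autoplot
autoplot.community_profile <- function(object, ...) {
  profiles <- c(list(object), Filter(function(p) inherits(p, "community_profile"),
                                     list(...)))
  dat <- purrr::map_dfr(profiles, function(p) {
    d <- tidy(p)
    d$region <- if (is.na(p$region)) "unnamed" else p$region
    d
  })
  show <- c("k_haplotypes", "p_polypeptides", "haplotypes_per_polypeptide",
            "haplotype_diversity", "nucleotide_diversity", "shannon_H",
            "ttd", "s_phi_plus", "mean_trophic_level")
  dat <- dat[dat$metric %in% show, ]
  dat$metric <- factor(dat$metric, levels = show)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$region, y = .data$value)) +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Community diversity profile") +
    ggplot2::theme_minimal()
}

#' Serialize a community profile
#'
#' `json` writes the scalar metrics, region, unavailability notes and
#' provenance (plus the dominant-set and sample-count tables) and is
#' round-trip safe via [read_profile()]; `tsv` writes the tidy
#' metric/value table.
#'
#' @param profile a `community_profile`.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(profile, "community_profile"))
  if (format == "tsv") {
    out <- tidy(profile)
    readr::write_tsv(out, path)
    return(invisible(path))
  }
  payload <- list(
    region = profile$region,
    metrics = as.list(tidy(profile) |> tibble::deframe()),
    unavailable = as.list(profile$unavailable),
    dominant = profile$dominant,
    sample_counts = profile$sample_counts,
    provenance = profile$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a JSON community profile
#'
#' Restores the scalar structure written by [write_profile()] (metrics,
#' region, unavailability notes, dominant set, sample counts, provenance).
#' The sequence-level tables (haplotypes, proteins, network) are not
#' serialized and are absent from the restored object.
#'
#' @param path path to a profile JSON file.
#' @return a `community_profile` (partial: scalar fields and small tables).
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.list(x$metrics)
  out <- lapply(out, function(v) if (is.null(v)) NA_real_ else v)
  names(out) <- names(x$metrics)
  for (m in setdiff(profile_metric_names, names(out))) out[[m]] <- NA_real_
  ints <- c("n_sequences", "k_haplotypes", "p_polypeptides",
            "n_dominant_species", "inventory_size",
            "network_observed_nodes", "network_median_nodes")
  for (m in ints) if (!is.na(out[[m]])) out[[m]] <- as.integer(out[[m]])
  out$region <- x$region %||% NA_character_
  out$unavailable <- unlist(x$unavailable) %||% character()
  out$dominant <- tibble::as_tibble(x$dominant)
  out$sample_counts <- tibble::as_tibble(x$sample_counts)
  out$provenance <- x$provenance
  structure(out[c("region", profile_metric_names, "unavailable", "dominant",
                  "sample_counts", "provenance")],
            class = "community_profile")
}
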