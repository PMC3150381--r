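# Synthetic multi-species barcode communities with controlled structure:
# known per-species haplotype counts, controlled synonymous vs
# nonsynonymous variation, and catch-proportional sample sizes. Used to
# validate every pipeline stage without real sequence downloads.

MITO_STOP_CODONS <- c("TAA", "TAG", "AGA", "AGG")
DNA_BASES <- c("A", "C", "G", "T")

#' Specify a synthetic barcode community
#'
#' Collects the design of a synthetic multi-species COI community: the
#' species list with taxonomy, tonnage, designed haplotype counts and
#' nonsynonymous variants, plus global parameters. Defaults emulate a
#' regional fishery catch survey: 40 pooled sequences over a full-length
#' barcode (648 bp, a codon multiple), a geometric haplotype-frequency
#' profile (one common haplotype dominating each species, as is typical of
#' barcode datasets) and an inter-species divergence floor of 24
#' substitutions.
#'
#' @param species a data frame with columns `species`, `genus`, `family`,
#'   `order`, `class`, `phylum`, `tonnage`, `k_haplotypes` and optionally
#'   `n_nonsynonymous` (default 0), `trophic_level` (default NA) and
#'   `n_samples` (explicit per-species sample counts overriding
#'   proportional allocation).
#' @param L barcode length in bp; must be a codon multiple.
#' @param divergence minimum number of substitutions between the ancestral
#'   sequences of any two species. Congeners sit exactly at this floor and
#'   distances grow with taxonomic rank of the split.
#' @param n total sample size (sequences) allocated over species in
#'   proportion to tonnage via [allocate_samples()]; ignored for species
#'   with explicit `n_samples`.
#' @param seed integer seed; one PRNG stream drives the whole dataset.
#' @param synonymous_divergence when `TRUE`, the substitutions separating
#'   species ancestors are themselves constrained to be synonymous, so all
#'   species share one ancestral protein — emulating congeneric species
#'   with identical COI polypeptides. Default `FALSE`: ancestral divergence
#'   is unconstrained and species typically carry distinct proteins.
#' @param frequency_profile `"geometric"` (default) or `"uniform"`
#'   haplotype frequencies within each species.
#' @param geometric_ratio ratio of the geometric profile (default 0.5).
#' @param region label written into FASTA headers.
#' @return an object of class `community_spec`.
#' @export
community_spec <- function(species, L = 648L, divergence = 24L, n = 40L,
                           seed = 1L, frequency_profile = c("geometric", "uniform"),
                           geometric_ratio = 0.5, region = "synthetic",
                           synonymous_divergence = FALSE) {
  frequency_profile <- match.arg(frequency_profile)
  stopifnot(is.data.frame(species))
  required <- c(rev(TAXONOMY_RANKS), "tonnage", "k_haplotypes")
  missing <- setdiff(required, names(species))
  if (length(missing) > 0L) {
    abort(sprintf("`species` is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  species <- tibble::as_tibble(species)
  if (!"n_nonsynonymous" %in% names(species)) species$n_nonsynonymous <- 0L
  if (!"trophic_level" %in% names(species)) species$trophic_level <- NA_real_
  if (!"n_samples" %in% names(species)) species$n_samples <- NA_integer_
  if (L %% 3L != 0L || L < 30L) abort("`L` must be a codon multiple of at least 30 bp.")
  if (any(species$k_haplotypes < 1L)) abort("`k_haplotypes` must be >= 1.")
  if (any(species$n_nonsynonymous < 0L |
          species$n_nonsynonymous >= species$k_haplotypes & species$k_haplotypes > 1L |
          (species$k_haplotypes == 1L & species$n_nonsynonymous > 0L))) {
    abort("`n_nonsynonymous` must be between 0 and k_haplotypes - 1.")
  }
  if (divergence < 1L) abort("`divergence` must be >= 1 substitution.")
  validate_taxonomy(species[rev(TAXONOMY_RANKS)])
  structure(list(species = species, L = as.integer(L),
                 divergence = as.integer(divergence), n = as.integer(n),
                 seed = as.integer(seed), frequency_profile = frequency_profile,
                 geometric_ratio = geometric_ratio, region = region,
                 synonymous_divergence = isTRUE(synonymous_divergence)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("Synthetic community spec: %d species, L = %d bp, n = %d, seed = %d\n",
              nrow(x$species), x$L, x$n, x$seed))
  invisible(x)
}

# Single random substitution at `pos` keeping the frame-1 codon stop-free
# (and, optionally, synonymous under the vertebrate mitochondrial code).
# Returns the new sequence or NULL when no base works at that position.
mutate_site_stopfree <- function(chars, pos, synonymous = FALSE) {
  code <- Biostrings::getGeneticCode("2")
  codon_i <- (pos - 1L) %/% 3L
  cpos <- codon_i * 3L + 1:3
  aa_old <- code[[paste(chars[cpos], collapse = "")]]
  for (b in sample(setdiff(DNA_BASES, chars[pos]))) {
    cand <- chars
    cand[pos] <- b
    codon <- paste(cand[cpos], collapse = "")
    if (codon %in% MITO_STOP_CODONS) next
    if (synonymous && code[[codon]] != aa_old) next
    return(cand)
  }
  NULL
}

# Apply `steps` substitutions drawing sites from a shared pool so that all
# branch mutations hit distinct sites and distances stay exactly additive.
apply_branch_mutations <- function(chars, steps, pool_env, synonymous = FALSE) {
  done <- 0L
  while (done < steps) {
    if (length(pool_env$pool) == 0L) {
      abort("Sequence too short for the requested divergence structure; increase `L` or lower `divergence`.")
    }
    pos <- pool_env$pool[1L]
    pool_env$pool <- pool_env$pool[-1L]
    cand <- mutate_site_stopfree(chars, pos, synonymous)
    if (!is.null(cand)) {
      chars <- cand
      done <- done + 1L
    }
  }
  chars
}

#' Generate ancestral barcode sequences for a synthetic community
#'
#' Draws one stop-free (vertebrate mitochondrial code, frame 1) coding
#' sequence per species by evolving a random root sequence down the
#' community's taxonomy: every distinct taxon above species level adds
#' `divergence` substitutions and every species edge adds
#' `ceiling(divergence/2)`, all at globally distinct sites. Pairwise
#' distances are therefore exactly additive and rank-consistent: congeners
#' are separated by exactly `divergence` substitutions and pairs splitting
#' at higher ranks by proportionally more.
#'
#' @param spec a `community_spec`.
#' @param seed optional seed; when `NULL` the current PRNG stream is used
#'   (as [simulate_community()] does).
#' @return a named character vector of ancestral sequences, one per species.
#' @export
generate_ancestors <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (!is.null(seed)) return(withr::with_seed(seed, generate_ancestors(spec)))
  sp <- spec$species
  n_codons <- spec$L / 3L
  ok_codons <- setdiff(
    apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste, collapse = ""),
    MITO_STOP_CODONS
  )
  root <- unlist(strsplit(paste(sample(ok_codons, n_codons, replace = TRUE),
                                collapse = ""), "", fixed = TRUE))
  pool_env <- new.env(parent = emptyenv())
  pool_env$pool <- sample.int(spec$L)
  d <- spec$divergence
  s_steps <- max(1L, as.integer(ceiling(d / 2)))
  node_seq <- list(root = root)
  for (r in TAXONOMY_RANKS) {
    depth <- match(r, TAXONOMY_RANKS)
    paths <- apply(as.data.frame(sp[TAXONOMY_RANKS[seq_len(depth)]]), 1L,
                   paste, collapse = "/")
    parents <- if (depth == 1L) rep("root", nrow(sp)) else
      apply(as.data.frame(sp[TAXONOMY_RANKS[seq_len(depth - 1L)]]), 1L,
            paste, collapse = "/")
    steps <- if (r == "species") s_steps else d
    for (i in which(!duplicated(paths))) {
      node_seq[[paths[i]]] <-
        apply_branch_mutations(node_seq[[parents[i]]], steps, pool_env,
                               spec$synonymous_divergence)
    }
  }
  leaf_paths <- apply(as.data.frame(sp[TAXONOMY_RANKS]), 1L, paste, collapse = "/")
  setNames(vapply(node_seq[leaf_paths], paste, "", collapse = ""), sp$species)
}

# Enumerate single-site substitutions of `chars` classed as synonymous or
# nonsynonymous under the vertebrate mitochondrial code (stops excluded).
single_substitutions <- function(chars) {
  code <- Biostrings::getGeneticCode("2")
  L <- length(chars)
  out <- vector("list", 3L * L)
  n <- 0L
  for (pos in seq_len(L)) {
    codon_i <- (pos - 1L) %/% 3L
    cpos <- codon_i * 3L + 1:3
    codon <- paste(chars[cpos], collapse = "")
    aa_old <- code[[codon]]
    off <- (pos - 1L) %% 3L + 1L
    for (b in setdiff(DNA_BASES, chars[pos])) {
      cand <- codon
      substr(cand, off, off) <- b
      if (cand %in% MITO_STOP_CODONS) next
      n <- n + 1L
      out[[n]] <- list(pos = pos, base = b, synonymous = code[[cand]] == aa_old)
    }
  }
  out[seq_len(n)]
}

#' Generate intra-species haplotypes around an ancestor
#'
#' Produces `k` distinct haplotypes: the ancestor itself plus `k - 1`
#' single-substitution derivatives, each at its own site. By default every
#' substitution is synonymous under the vertebrate mitochondrial code, so
#' all haplotypes translate to one protein (the dominant pattern in COI
#' barcode data); `n_nonsynonymous` of the derived haplotypes instead carry
#' a nonsynonymous change at a distinct site each, yielding exactly
#' `1 + n_nonsynonymous` distinct proteins.
#'
#' @param ancestor a stop-free (frame 1) DNA string.
#' @param k number of distinct haplotypes (>= 1).
#' @param n_nonsynonymous how many derived haplotypes carry a
#'   nonsynonymous change (0 means synonymous-only).
#' @param seed optional seed; `NULL` uses the current PRNG stream.
#' @return a character vector of `k` distinct DNA strings, ancestor first.
#' @export
generate_haplotypes <- function(ancestor, k, n_nonsynonymous = 0L, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_haplotypes(ancestor, k, n_nonsynonymous)))
  }
  stopifnot(is.character(ancestor), length(ancestor) == 1L, k >= 1L,
            n_nonsynonymous >= 0L, n_nonsynonymous <= max(k - 1L, 0L))
  if (k == 1L) return(ancestor)
  chars <- strsplit(toupper(ancestor), "", fixed = TRUE)[[1L]]
  subs <- single_substitutions(chars)
  syn <- subs[vapply(subs, `[[`, TRUE, "synonymous")]
  nonsyn <- subs[!vapply(subs, `[[`, TRUE, "synonymous")]
  pick_distinct_sites <- function(cands, m, used, what) {
    sites <- unique(vapply(cands, `[[`, 0L, "pos"))
    sites <- setdiff(sites, used)
    if (length(sites) < m) {
      abort(sprintf("Only %d %s sites available but %d haplotypes requested.",
                    length(sites), what, m))
    }
    chosen_sites <- if (length(sites) == 1L) sites else sample(sites, m)
    lapply(chosen_sites[seq_len(m)], function(s) {
      at <- cands[vapply(cands, function(x) x$pos == s, TRUE)]
      at[[if (length(at) == 1L) 1L else sample.int(length(at), 1L)]]
    })
  }
  n_syn <- k - 1L - n_nonsynonymous
  muts <- pick_distinct_sites(syn, n_syn, integer(), "synonymous")
  used <- vapply(muts, `[[`, 0L, "pos")
  if (n_nonsynonymous > 0L) {
    muts <- c(muts, pick_distinct_sites(nonsyn, n_nonsynonymous, used, "nonsynonymous"))
  }
  haps <- vapply(muts, function(mu) {
    v <- chars
    v[mu$pos] <- mu$base
    paste(v, collapse = "")
  }, "")
  c(paste(chars, collapse = ""), haps)
}

# Designed within-species haplotype frequencies.
haplotype_frequencies <- function(k, profile, ratio) {
  f <- switch(profile,
              geometric = ratio^(seq_len(k) - 1L),
              uniform = rep(1, k))
  f / sum(f)
}

#' Simulate a synthetic barcode community in memory
#'
#' Runs the full generator: ancestral sequences per species
#' ([generate_ancestors()]), designed haplotypes per species
#' ([generate_haplotypes()]), catch-proportional sample allocation
#' ([allocate_samples()], unless explicit `n_samples` are given) and
#' haplotype sampling under the designed frequency profile. When a species'
#' sample count is at least its haplotype count, every designed haplotype
#' is observed at least once (mirroring surveys that deposit each unique
#' haplotype); the remaining draws are multinomial. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a `community_spec`.
#' @return a list with tibbles `sequences` (`sample_id`, `species`,
#'   `region`, `sequence`), `catch`, `taxonomy`, `trophic`, `haplotypes`
#'   (designed haplotypes with frequencies) and `allocation`.
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  sp <- spec$species
  ancestors <- generate_ancestors(spec)
  counts <- if (all(!is.na(sp$n_samples))) {
    as.integer(sp$n_samples)
  } else if (spec$n == 0L) {
    rep(0L, nrow(sp))
  } else {
    allocate_samples(tibble::tibble(species = sp$species, tonnage = sp$tonnage),
                     spec$n)$n_samples
  }
  designed <- purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    haps <- generate_haplotypes(ancestors[[i]], sp$k_haplotypes[i],
                                sp$n_nonsynonymous[i])
    tibble::tibble(
      species = sp$species[i], hap_index = seq_along(haps), sequence = haps,
      frequency = haplotype_frequencies(length(haps), spec$frequency_profile,
                                        spec$geometric_ratio)
    )
  })
  sequences <- purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    hp <- designed[designed$species == sp$species[i], ]
    n_i <- counts[i]
    k <- nrow(hp)
    if (n_i == 0L) {
      return(tibble::tibble(sample_id = character(), species = character(),
                            region = character(), sequence = character()))
    }
    draws <- if (n_i >= k) {
      extra <- stats::rmultinom(1L, n_i - k, hp$frequency)[, 1L]
      rep(seq_len(k), 1L + extra)
    } else {
      seq_len(n_i)  # top designed frequencies, one copy each
    }
    tibble::tibble(
      sample_id = sprintf("s%02d_%03d", i, seq_len(n_i)),
      species = sp$species[i], region = spec$region,
      sequence = hp$sequence[draws]
    )
  })
  list(
    sequences = sequences,
    catch = tibble::tibble(species = sp$species, tonnage = sp$tonnage),
    taxonomy = sp[rev(TAXONOMY_RANKS)],
    trophic = tibble::tibble(species = sp$species,
                             trophic_level = sp$trophic_level)[!is.na(sp$trophic_level), ],
    haplotypes = designed,
    allocation = tibble::tibble(species = sp$species, n_samples = counts)
  )
}

#' Write a simulated community dataset to disk
#'
#' Materialises [simulate_community()] into the pipeline's file dialects:
#' a FASTA of sampled sequences plus catch, taxonomy and trophic TSV
#' tables. Identical specs (including seed) produce byte-identical files.
#'
#' @param spec a `community_spec`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths (`fasta`, `catch`,
#'   `taxonomy`, `trophic`), invisibly.
#' @export
generate_dataset <- function(spec, dir) {
  sim <- simulate_community(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             catch = file.path(dir, "catch.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             trophic = file.path(dir, "trophic.tsv"))
  write_fasta(sim$sequences, paths[["fasta"]])
  readr::write_tsv(sim$catch, paths[["catch"]])
  readr::write_tsv(sim$taxonomy, paths[["taxonomy"]])
  readr::write_tsv(sim$trophic, paths[["trophic"]])
  invisible(paths)
}
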