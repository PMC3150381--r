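#' Hamming distance matrix between haplotypes
#'
#' Integer substitution counts between all pairs of haplotype states.
#' Alignment columns containing ambiguity (`N` or `-`) in any haplotype are
#' excluded globally, so the distances form a proper metric on the shared
#' unambiguous columns (the same convention the network construction uses).
#'
#' @param ht a `haplotype_table` from [collapse_haplotypes()] or a character
#'   vector of equal-length sequences.
#' @return a symmetric integer matrix; the number of excluded columns is
#'   attached as attribute `"n_excluded_sites"`.
#' @export
hamming_matrix <- function(ht) {
  states <- if (is.data.frame(ht)) ht$haplotype else ht
  m <- seq_char_matrix(states)
  keep <- if (nrow(m) > 0L) {
    colSums(m == "N" | m == "-") == 0L
  } else {
    logical(0)
  }
  mm <- m[, keep, drop = FALSE]
  k <- length(states)
  d <- matrix(0L, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d[i, j] <- d[j, i] <- sum(mm[i, ] != mm[j, ])
      }
    }
  }
  dimnames(d) <- if (is.data.frame(ht)) list(ht$hap_id, ht$hap_id) else
    list(states, states)
  attr(d, "n_excluded_sites") <- sum(!keep)
  d
}

# Level at which each pair of states becomes connected when all pairs are
# linked in order of increasing Hamming distance (components merge per
# distance level). lambda[i, j] is the minimum spanning network level.
msn_connection_levels <- function(d) {
  k <- nrow(d)
  lambda <- matrix(0, k, k)
  if (k < 2L) return(lambda)
  comp <- seq_len(k)
  for (delta in sort(unique(d[upper.tri(d)]))) {
    pre <- comp
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (d[i, j] == delta && pre[i] != pre[j]) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
    newly <- outer(pre, pre, "!=") & outer(comp, comp, "==")
    lambda[newly & lambda == 0] <- delta
  }
  lambda
}

# Edge matrix of the epsilon-relaxed minimum spanning network: a pair is an
# edge iff its distance is within epsilon of the level at which its
# components first connect.
msn_edges <- function(d, epsilon = 0) {
  lambda <- msn_connection_levels(d)
  adj <- d <= lambda + epsilon & d > 0
  adj | t(adj)
}

# Majority-consensus state of three sequences, site by site. A site where
# all three states differ has no majority: no median is generated from the
# triple (conservative tie rule).
triple_median <- function(a, b, c) {
  sv <- rbind(strsplit(a, "", fixed = TRUE)[[1L]],
              strsplit(b, "", fixed = TRUE)[[1L]],
              strsplit(c, "", fixed = TRUE)[[1L]])
  med <- character(ncol(sv))
  for (s in seq_len(ncol(sv))) {
    tab <- table(sv[, s])
    if (max(tab) == 1L) return(NA_character_)
    med[s] <- names(tab)[which.max(tab)]
  }
  paste(med, collapse = "")
}

#' Median-joining haplotype network
#'
#' Builds the median-joining network of Bandelt, Forster and Roehl (1999)
#' over the haplotype states: iteratively construct the
#' epsilon-relaxed minimum spanning network, add the majority-consensus
#' (median) state of every triple of mutually linked nodes when it is a new
#' state, and repeat until no median is added; finally prune obsolete
#' median vectors (degree at most 2 and on no shortest connection between
#' observed haplotypes). Observed haplotypes are the "real" nodes of the
#' network; retained medians represent hypothetical unsampled
#' intermediates. Alignment columns with ambiguity in any haplotype are
#' excluded (a message reports how many); ties are broken lexicographically
#' by state so the result is independent of input order.
#'
#' @param ht a `haplotype_table` from [collapse_haplotypes()] or a character
#'   vector of equal-length unambiguous sequences.
#' @param epsilon non-negative integer relaxation of the minimum spanning
#'   network (0 reproduces the program defaults used in barcoding studies).
#' @param max_iter safety cap on median-addition sweeps.
#' @return an `igraph` graph with vertex attributes `name` (`H*` for
#'   observed, `M*` for median nodes), `state`, `type`
#'   (`"observed"`/`"median"`), `count` (0 for medians) and `species`
#'   (collapsed with `;`), and edge attribute `mutations` (Hamming distance
#'   between endpoint states).
#' @examples
#' net <- median_joining_network(c("ATT", "TAT", "TTA"))
#' count_nodes(net)  # 3 observed, 1 median
#' @export
median_joining_network <- function(ht, epsilon = 0, max_iter = 25L) {
  if (!(is.numeric(epsilon) && length(epsilon) == 1L && epsilon >= 0)) {
    abort("`epsilon` must be a single non-negative number.")
  }
  if (is.data.frame(ht)) {
    obs_states_full <- ht$haplotype
    counts <- ht$count
    species <- vapply(ht$species, function(s) paste(s, collapse = ";"), "")
  } else {
    obs_states_full <- as.character(ht)
    counts <- rep(1L, length(ht))
    species <- rep("", length(ht))
  }
  k_obs <- length(obs_states_full)
  if (k_obs == 0L) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  m <- seq_char_matrix(obs_states_full)
  keep <- colSums(m == "N" | m == "-") == 0L
  if (any(!keep)) {
    inform(sprintf("Excluding %d alignment column(s) with ambiguity from network construction.",
                   sum(!keep)))
  }
  states <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (ncol(m[, keep, drop = FALSE]) == 0L) states <- rep("", k_obs)
  # observed states may collide after column exclusion; collapse them
  first <- !duplicated(states)
  obs_states <- states[first]
  grp <- factor(match(states, obs_states), levels = seq_along(obs_states))
  obs_counts <- vapply(split(counts, grp), sum, 0)
  obs_species <- vapply(split(species, grp),
                        function(s) paste(unique(s[s != ""]), collapse = ";"), "")
  obs_full <- obs_states_full[first]

  all_states <- obs_states
  for (iter in seq_len(max_iter)) {
    d <- hamming_from_states(all_states)
    adj <- msn_edges(d, epsilon)
    new_medians <- character()
    nn <- length(all_states)
    if (nn >= 3L) {
      for (i in seq_len(nn - 2L)) {
        for (j in (i + 1L):(nn - 1L)) {
          for (l in (j + 1L):nn) {
            n_links <- adj[i, j] + adj[i, l] + adj[j, l]
            if (n_links >= 2L) {
              med <- triple_median(all_states[i], all_states[j], all_states[l])
              if (!is.na(med) && !(med %in% all_states) && !(med %in% new_medians)) {
                new_medians <- c(new_medians, med)
              }
            }
          }
        }
      }
    }
    if (length(new_medians) == 0L) break
    all_states <- c(all_states, sort(new_medians))
  }

  graph <- build_network_graph(all_states, obs_states, obs_counts,
                               obs_species, obs_full, epsilon)
  prune_obsolete_medians(graph, epsilon)
}

hamming_from_states <- function(states) {
  m <- seq_char_matrix(states)
  k <- length(states)
  d <- matrix(0L, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

build_network_graph <- function(all_states, obs_states, obs_counts,
                                obs_species, obs_full, epsilon) {
  is_obs <- all_states %in% obs_states
  ord <- order(!is_obs, match(all_states, obs_states), all_states)
  all_states <- all_states[ord]
  is_obs <- is_obs[ord]
  d <- hamming_from_states(all_states)
  adj <- msn_edges(d, epsilon)
  idx_obs <- match(obs_states, all_states)
  name <- character(length(all_states))
  name[idx_obs] <- paste0("H", seq_along(obs_states))
  name[!is_obs] <- paste0("M", seq_len(sum(!is_obs)))
  count <- rep(0, length(all_states)); count[idx_obs] <- obs_counts
  spp <- rep("", length(all_states)); spp[idx_obs] <- obs_species
  full <- all_states; full[idx_obs] <- obs_full
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- name
  igraph::V(g)$state <- full
  igraph::V(g)$net_state <- all_states
  igraph::V(g)$type <- ifelse(is_obs, "observed", "median")
  igraph::V(g)$count <- count
  igraph::V(g)$species <- spp
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$mutations <- d[el]
  g
}

# Remove median nodes of degree <= 2 that lie on no shortest connection
# between observed haplotypes, rebuilding the MSN over the surviving
# states until stable.
prune_obsolete_medians <- function(graph, epsilon) {
  repeat {
    med <- which(igraph::V(graph)$type == "median")
    if (length(med) == 0L) return(graph)
    deg <- igraph::degree(graph)
    obs <- which(igraph::V(graph)$type == "observed")
    removable <- NA_integer_
    base_d <- igraph::distances(graph, v = obs, to = obs,
                                weights = igraph::E(graph)$mutations)
    for (v in med[deg[med] <= 2L]) {
      g2 <- igraph::delete_vertices(graph, v)
      obs2 <- which(igraph::V(g2)$type == "observed")
      d2 <- igraph::distances(g2, v = obs2, to = obs2,
                              weights = igraph::E(g2)$mutations)
      if (all(is.finite(d2)) && isTRUE(all.equal(unname(base_d), unname(d2)))) {
        removable <- v
        break
      }
    }
    if (is.na(removable)) return(graph)
    keep <- setdiff(seq_len(igraph::vcount(graph)), removable)
    graph <- rebuild_from_vertices(graph, keep, epsilon)
  }
}

rebuild_from_vertices <- function(graph, keep, epsilon) {
  states <- igraph::V(graph)$net_state[keep]
  is_obs <- igraph::V(graph)$type[keep] == "observed"
  build_network_graph(states, states[is_obs],
                      igraph::V(graph)$count[keep][is_obs],
                      igraph::V(graph)$species[keep][is_obs],
                      igraph::V(graph)$state[keep][is_obs], epsilon)
}

#' Count observed and median nodes of a haplotype network
#'
#' @param graph an `igraph` network from [median_joining_network()].
#' @return a one-row tibble with columns `observed` and `median`.
#' @export
count_nodes <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  type <- if (igraph::vcount(graph) > 0L) igraph::V(graph)$type else character()
  tibble::tibble(observed = sum(type == "observed"),
                 median = sum(type == "median"))
}

#' Plot a haplotype network
#'
#' Observed haplotypes are drawn as filled dots scaled by sample count,
#' inferred median nodes as smaller dark dots; edge labels give the number
#' of mutations.
#'
#' @param object an `igraph` network from [median_joining_network()].
#' @param seed layout seed (Fruchterman–Reingold), for reproducible plots.
#' @param ... ignored.
#' @return a `ggplot` object.
#' @exportS3Method ggplot2::autoplot
autoplot.igraph <- function(object, seed = 42L, ...) {
  stopifnot(inherits(object, "igraph"))
  xy <- withr::with_seed(seed, igraph::layout_with_fr(object))
  nodes <- tibble::tibble(
    x = xy[, 1L], y = xy[, 2L],
    type = igraph::V(object)$type %||% "observed",
    count = igraph::V(object)$count %||% 1,
    label = igraph::V(object)$name %||% as.character(seq_len(igraph::vcount(object)))
  )
  el <- igraph::as_edgelist(object, names = FALSE)
  edges <- tibble::tibble(
    x = xy[el[, 1L], 1L], y = xy[el[, 1L], 2L],
    xend = xy[el[, 2L], 1L], yend = xy[el[, 2L], 2L],
    mutations = igraph::E(object)$mutations %||% rep(1L, nrow(el))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_label(data = edges,
                        ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                     y = (.data$y + .data$yend) / 2,
                                     label = .data$mutations),
                        size = 2.5, label.size = 0) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = pmax(.data$count, 1),
                                     colour = .data$type)) +
    ggplot2::scale_colour_manual(values = c(observed = "gold", median = "firebrick")) +
    ggplot2::scale_size_area(max_size = 10, guide = "none") +
    ggplot2::labs(colour = NULL, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
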