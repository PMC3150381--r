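#' Pairwise distances between protein variants
#'
#' `model = "p"` is the proportion of differing sites with pairwise
#' deletion of ambiguous residues (`X`, `-`, `*`). `model = "jtt"` is the
#' maximum-likelihood pairwise distance under the Jones–Taylor–Thornton
#' substitution matrix (via \pkg{phangorn}), optionally with discrete-gamma
#' rate heterogeneity at a user-supplied shape (model selection itself,
#' e.g. ProtTest, is up to the user).
#'
#' @param proteins a `protein_table` from [collapse_proteins()] or a
#'   (optionally named) character vector of equal-length amino-acid
#'   sequences.
#' @param model `"p"` (default) or `"jtt"`.
#' @param gamma_shape optional positive gamma shape; only used for `"jtt"`.
#' @param gamma_categories number of discrete gamma categories (default 4).
#' @return a `dist` object labelled by protein id (or input names).
#' @export
protein_distance <- function(proteins, model = c("p", "jtt"),
                             gamma_shape = NULL, gamma_categories = 4L) {
  model <- match.arg(model)
  if (is.data.frame(proteins)) {
    aa <- setNames(proteins$protein, proteins$protein_id)
  } else {
    aa <- proteins
    if (is.null(names(aa))) names(aa) <- paste0("P", seq_along(aa))
  }
  if (length(aa) < 2L) abort("At least 2 protein variants are required.")
  m <- seq_char_matrix(aa)
  ok <- !(m %in% c("X", "-", "*", "?"))
  dim(ok) <- dim(m)
  k <- length(aa)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!any(ok[i, ] & ok[j, ])) {
        abort(sprintf("Protein pair (%s, %s) has no comparable sites.",
                      names(aa)[i], names(aa)[j]))
      }
    }
  }
  if (model == "p") {
    d <- matrix(0, k, k, dimnames = list(names(aa), names(aa)))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        comp <- ok[i, ] & ok[j, ]
        d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
      }
    }
    return(as.dist(d))
  }
  if (!is.null(gamma_shape) &&
      !(is.numeric(gamma_shape) && length(gamma_shape) == 1L && gamma_shape > 0)) {
    abort("`gamma_shape` must be a single positive number.")
  }
  mm <- m
  mm[!ok] <- "X"
  rownames(mm) <- names(aa)
  ph <- phangorn::phyDat(mm, type = "AA")
  d <- if (is.null(gamma_shape)) {
    phangorn::dist.ml(ph, model = "JTT")
  } else {
    phangorn::dist.ml(ph, model = "JTT", k = gamma_categories,
                      shape = gamma_shape)
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou–Nei neighbour joining (via \pkg{ape}), the standard tree
#' inference for barcoding surveys. Negative branch-length estimates are
#' clamped to zero with a warning. The tree is left unrooted.
#'
#' @param d a `dist` object or symmetric matrix with at least 3 labels.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (is.matrix(d)) d <- as.dist(d)
  if (!inherits(d, "dist")) abort("`d` must be a dist object or symmetric matrix.")
  if (attr(d, "Size") < 3L) abort("Neighbour joining needs at least 3 labels.")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warn(sprintf("Clamping %d negative branch length(s) to zero.",
                 sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbour-joining tree with bootstrap support
#'
#' Computes the point-estimate NJ tree from the full protein alignment,
#' then resamples alignment columns with replacement `replicates` times,
#' recomputing distances and the NJ tree each time; the support of each
#' internal split of the point tree is the percentage of replicate trees
#' containing it. Replicates whose resampled alignment leaves a pair with
#' no comparable sites are skipped and counted (a warning is raised when
#' more than 1% are skipped).
#'
#' @inheritParams protein_distance
#' @param replicates number of bootstrap replicates (0 returns the point
#'   tree without supports).
#' @param seed optional integer seed making the resampling reproducible.
#' @return an `ape::phylo` tree; with `replicates > 0` the internal node
#'   labels carry supports in \[0, 100\] and the attribute
#'   `"n_skipped_replicates"` reports skipped replicates.
#' @export
bootstrap_support <- function(proteins, model = c("p", "jtt"),
                              gamma_shape = NULL, replicates = 2000L,
                              seed = NULL) {
  model <- match.arg(model)
  if (is.data.frame(proteins)) {
    aa <- setNames(proteins$protein, proteins$protein_id)
  } else {
    aa <- proteins
    if (is.null(names(aa))) names(aa) <- paste0("P", seq_along(aa))
  }
  point <- neighbor_joining(protein_distance(aa, model, gamma_shape))
  if (replicates == 0L) return(point)
  m <- seq_char_matrix(aa)
  L <- ncol(m)
  run <- function() {
    trees <- vector("list", replicates)
    skipped <- 0L
    for (r in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      boot_aa <- setNames(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""),
                          names(aa))
      tr <- tryCatch(
        suppressWarnings(neighbor_joining(protein_distance(boot_aa, model, gamma_shape))),
        error = function(e) NULL
      )
      if (is.null(tr)) skipped <- skipped + 1L else trees[[r]] <- tr
    }
    list(trees = Filter(Negate(is.null), trees), skipped = skipped)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (res$skipped > 0.01 * replicates) {
    warn(sprintf("%d of %d bootstrap replicates skipped (no comparable sites).",
                 res$skipped, replicates))
  }
  n_eff <- length(res$trees)
  counts <- ape::prop.clades(point, res$trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / max(n_eff, 1L), 1)
  attr(point, "n_skipped_replicates") <- res$skipped
  point
}
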