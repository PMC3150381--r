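#' Select the dominant species of a catch
#'
#' Orders species by descending annual tonnage (ties keep input order) and
#' takes the minimal prefix whose cumulative share of the TOTAL catch —
#' including any residual "Others" row — reaches `threshold`. This is the
#' rule behind "species representing 65% of the catch" in fishery profiling
#' (river sport fisheries typically need a higher threshold, e.g. 0.9, to
#' cover the registered catch).
#'
#' @param catch a data frame with columns `species` and `tonnage`
#'   (tons/year), e.g. from [read_catch_table()].
#' @param threshold cumulative catch fraction in (0, 1] to cover; default 0.65.
#' @param residual labels (case-insensitive) of aggregate rows such as
#'   "Others": their tonnage counts toward the total catch but they are
#'   never selected as dominant species.
#' @return a tibble of class `dominant_set`, ordered by descending tonnage,
#'   with columns `species`, `tonnage`, `fraction` (share of total catch) and
#'   `cumulative_percent`. Attributes: `threshold`, `total_tonnage`.
#' @examples
#' catch <- tibble::tibble(
#'   species = c("Sardine", "Anchovy", "Mackerel", "Hake", "Others"),
#'   tonnage = c(13188, 4184, 1659, 1331, 10097)
#' )
#' select_dominant_species(catch, 0.65)
#' @export
select_dominant_species <- function(catch, threshold = 0.65,
                                    residual = c("others", "miscellaneous", "total")) {
  stopifnot(is.data.frame(catch), all(c("species", "tonnage") %in% names(catch)))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single fraction in (0, 1].")
  }
  if (any(catch$tonnage < 0, na.rm = TRUE)) abort("Tonnage must be non-negative.")
  total <- sum(catch$tonnage, na.rm = TRUE)
  if (!isTRUE(total > 0)) abort("All tonnages are zero: no catch to profile.")
  keep <- !species_key(catch$species) %in% species_key(residual)
  species_tbl <- tibble::as_tibble(catch)[keep, c("species", "tonnage")]
  if (nrow(species_tbl) == 0L) abort("Catch table contains no selectable species.")
  ord <- order_desc_stable(dplyr::coalesce(species_tbl$tonnage, 0))
  sorted <- species_tbl[ord, ]
  sorted$fraction <- sorted$tonnage / total
  cum <- cumsum(sorted$fraction)
  n_keep <- which(cum >= threshold)[1L]
  if (is.na(n_keep)) {
    n_keep <- nrow(sorted)
    warn(sprintf(
      "Named species cover only %.2f%% of the total catch; threshold %.0f%% is unreachable, returning all of them.",
      100 * cum[n_keep], 100 * threshold))
  }
  out <- sorted[seq_len(n_keep), ]
  out$cumulative_percent <- 100 * cum[seq_len(n_keep)]
  structure(out, class = c("dominant_set", class(out)),
            threshold = threshold, total_tonnage = total)
}

#' Allocate a sample size proportionally over a dominant set
#'
#' Largest-remainder (Hamilton) apportionment of `n` sequences over the
#' catch fractions renormalised within the dominant set, mirroring a design
#' where the number of specimens sequenced per species is proportional to
#' its weight in the catch. Every species receives at least one sample;
#' any deficit this creates is taken from the species with the largest
#' allocation. Remainder ties are broken by larger fraction, then input order.
#'
#' @param dominant a `dominant_set` from [select_dominant_species()], or any
#'   data frame with `species` and either `fraction` or `tonnage`.
#' @param n total number of samples (sequences) to allocate; must be at
#'   least the number of species.
#' @return a tibble with columns `species`, `fraction` (renormalised) and
#'   `n_samples`, summing exactly to `n`.
#' @export
allocate_samples <- function(dominant, n = 40) {
  stopifnot(is.data.frame(dominant), "species" %in% names(dominant))
  w <- if ("fraction" %in% names(dominant)) dominant$fraction else dominant$tonnage
  if (is.null(w)) abort("`dominant` needs a `fraction` or `tonnage` column.")
  S <- nrow(dominant)
  if (S == 0L) abort("Empty dominant set.")
  if (!is.numeric(n) || n != round(n) || n < S) {
    abort(sprintf("`n` must be an integer >= the number of species (%d).", S))
  }
  fr <- w / sum(w)
  quota <- fr * n
  counts <- floor(quota)
  remainder <- quota - counts
  deficit <- n - sum(counts)
  if (deficit > 0L) {
    give <- order(-remainder, -fr, seq_len(S))[seq_len(deficit)]
    counts[give] <- counts[give] + 1L
  }
  # guarantee >= 1 per species, deficit taken from the largest counts
  while (any(counts == 0L)) {
    zero <- which(counts == 0L)[1L]
    donor <- which.max(counts)
    counts[zero] <- 1L
    counts[donor] <- counts[donor] - 1L
  }
  tibble::tibble(species = dominant$species, fraction = fr,
                 n_samples = as.integer(counts))
}

#' Shannon diversity index on sample composition
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with natural logarithm, where the
#' proportions come from per-species sample counts (the observed composition
#' of the pooled sequence sample), not raw tonnage. Zero counts are dropped.
#'
#' @param counts a numeric vector of per-species counts or positive weights
#'   (optionally named), or a data frame with columns `species` and one of
#'   `n_samples`, `count` or `n`.
#' @return a one-row tibble with columns `H` (nats), `richness` (number of
#'   species with positive count) and `n` (total count). The proportions
#'   used are attached as attribute `"proportions"`.
#' @examples
#' shannon_index(c(38, 2))    # H = 0.1985
#' shannon_index(c(26, 8, 3, 3))
#' @export
shannon_index <- function(counts) {
  if (is.data.frame(counts)) {
    col <- intersect(c("n_samples", "count", "n"), names(counts))[1L]
    if (is.na(col)) abort("`counts` data frame needs a `n_samples`, `count` or `n` column.")
    x <- setNames(counts[[col]], counts$species)
  } else {
    x <- counts
  }
  if (!is.numeric(x) || length(x) == 0L) abort("`counts` must be numeric and non-empty.")
  if (any(x < 0)) abort("Counts must be non-negative.")
  x <- x[x > 0]
  if (length(x) == 0L) abort("All counts are zero.")
  p <- x / sum(x)
  H <- unname(vegan::diversity(p, index = "shannon", base = exp(1)))
  out <- tibble::tibble(H = H, richness = length(p), n = sum(x))
  attr(out, "proportions") <- p
  out
}

#' Mean trophic level of a species set
#'
#' Unweighted mean and unbiased (n-1) sample variance of the trophic levels
#' of the given species; a single species yields variance 0. With `weights`
#' (e.g. catch fractions) the mean is weighted instead, while the variance
#' stays the unweighted sample variance.
#'
#' @param species character vector of species names.
#' @param trophic a data frame with columns `species` and `trophic_level`,
#'   e.g. from [read_trophic_table()].
#' @param weights optional non-negative weights aligned with `species`.
#' @return a one-row tibble with columns `mean_trophic_level`, `variance`
#'   and `n_species`.
#' @export
mean_trophic_level <- function(species, trophic, weights = NULL) {
  stopifnot(is.data.frame(trophic),
            all(c("species", "trophic_level") %in% names(trophic)))
  key <- species_key(species)
  lookup <- setNames(trophic$trophic_level, species_key(trophic$species))
  missing <- species[!key %in% names(lookup)]
  if (length(missing) > 0L) {
    abort(sprintf("Species missing from trophic table: %s.",
                  paste(missing, collapse = ", ")))
  }
  tl <- unname(lookup[key])
  m <- if (is.null(weights)) mean(tl) else {
    stopifnot(length(weights) == length(tl), all(weights >= 0))
    sum(weights * tl) / sum(weights)
  }
  v <- if (length(tl) < 2L) 0 else var(tl)
  tibble::tibble(mean_trophic_level = m, variance = v, n_species = length(tl))
}

#' @export
print.dominant_set <- function(x, ...) {
  cat(sprintf("Dominant species set: %d species covering %.2f%% of the catch (threshold %.0f%%)\n",
              nrow(x), max(x$cumulative_percent), 100 * attr(x, "threshold")))
  NextMethod()
}
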