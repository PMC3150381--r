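# the river catch also lists a minor species and a residual row, so the
# 0.9 threshold genuinely needs both congeners
asturias_catch <- function(sim) {
  dplyr::bind_rows(
    sim$catch,
    tibble::tibble(species = c("European eel", "Others"), tonnage = c(8, 28.4)))
}

asturias_profile <- function() {
  sim <- simulate_community(asturias_like_spec(seed = 11L))
  compute_profile(sim$sequences, asturias_catch(sim), sim$taxonomy, sim$trophic,
                  region = "rivers", threshold = 0.9, inventory_size = 17L)
}

test_that("the river-fishery fixture reproduces its designed profile column", {
  prof <- asturias_profile()
  expect_equal(prof$k_haplotypes, 4L)
  expect_equal(prof$p_polypeptides, 1L)
  expect_equal(prof$haplotypes_per_polypeptide, 4)
  expect_equal(round(prof$shannon_H, 4), 0.1985)   # counts 38/2
  expect_equal(round(prof$ttd, 1), 33.3)
  expect_equal(round(prof$s_phi_plus, 1), 116.7)
  expect_equal(prof$n_dominant_species, 2L)
  expect_equal(prof$mean_trophic_level, 4.45)
  expect_true(prof$haplotype_diversity > 0 && prof$haplotype_diversity < 1)
  expect_equal(prof$network_observed_nodes, 4L)
})

test_that("a single-species profile degrades gracefully", {
  sp <- salmo_taxonomy()[1, ]
  sp$tonnage <- 100
  sp$k_haplotypes <- 3L
  sp$trophic_level <- 3.5
  sim <- simulate_community(community_spec(sp, n = 10L, seed = 4L))
  prof <- compute_profile(sim$sequences, sim$catch, sim$taxonomy, sim$trophic)
  expect_equal(prof$shannon_H, 0)
  expect_true(is.na(prof$ttd))
  expect_match(prof$unavailable[["ttd"]], "at least 2")
  expect_equal(prof$s_phi_plus, 100)
})

test_that("a missing trophic table only disables the trophic fields", {
  sim <- simulate_community(asturias_like_spec(seed = 11L))
  prof <- compute_profile(sim$sequences, asturias_catch(sim), sim$taxonomy,
                          trophic = NULL, threshold = 0.9)
  expect_true(is.na(prof$mean_trophic_level))
  expect_match(prof$unavailable[["trophic_mean"]], "trophic")
  expect_equal(prof$k_haplotypes, 4L)
})

test_that("non-dominant sequences are excluded unless include_all is set", {
  sim <- simulate_community(asturias_like_spec(seed = 11L))
  extra <- tibble::tibble(sample_id = "x1", species = "Micromesistius poutassou",
                          region = "rivers",
                          sequence = sim$sequences$sequence[1])
  seqs <- dplyr::bind_rows(sim$sequences, extra)
  tax <- dplyr::bind_rows(
    sim$taxonomy,
    atlantic_taxonomy()[atlantic_taxonomy()$species == "Micromesistius poutassou", ])
  catch <- dplyr::bind_rows(
    asturias_catch(sim),
    tibble::tibble(species = "Micromesistius poutassou", tonnage = 1))
  p_dom <- compute_profile(seqs, catch, tax, threshold = 0.9)
  expect_equal(p_dom$n_sequences, 40L)
  p_all <- compute_profile(seqs, catch, tax, threshold = 0.9, include_all = TRUE)
  expect_equal(p_all$n_sequences, 41L)
})

test_that("join failures across inputs are reported by species name", {
  sim <- simulate_community(asturias_like_spec(seed = 11L))
  tax_missing <- sim$taxonomy[1, ]
  expect_error(
    compute_profile(sim$sequences, asturias_catch(sim), tax_missing,
                    threshold = 0.9),
    "Salmo salar")
  troph_missing <- sim$trophic[1, ]
  expect_error(
    compute_profile(sim$sequences, asturias_catch(sim), sim$taxonomy,
                    troph_missing, threshold = 0.9),
    "Salmo salar")
})

test_that("profiles are deterministic and JSON round-trip safe", {
  p1 <- asturias_profile()
  p2 <- asturias_profile()
  expect_equal(tidy(p1), tidy(p2))
  expect_identical(p1$provenance$input_digest, p2$provenance$input_digest)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile(p1, f, "json")
  back <- read_profile(f)
  expect_equal(tidy(back), tidy(p1))
  expect_equal(back$region, p1$region)
  expect_equal(back$dominant$species, p1$dominant$species)
  # writing the reloaded profile reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".json")
  write_profile(p1, f2, "json")
  expect_identical(readLines(f), readLines(f2))
})

test_that("tidy and glance expose the profile as tables", {
  prof <- asturias_profile()
  td <- tidy(prof)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_equal(td$value[td$metric == "k_haplotypes"], 4)
  gl <- glance(prof)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$region, "rivers")
  expect_equal(gl$inventory_size, 17L)
})

test_that("profile and network plots build without error", {
  prof <- asturias_profile()
  expect_s3_class(autoplot(prof), "ggplot")
  expect_s3_class(autoplot(prof$network), "ggplot")
})

test_that("TSV profile output carries the tidy metric table", {
  prof <- asturias_profile()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, f, "tsv")
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$value[back$metric == "shannon_H"], prof$shannon_H,
               tolerance = 1e-12)
})
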