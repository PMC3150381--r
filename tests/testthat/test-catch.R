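test_that("dominant-species selection reproduces the regional catch tables", {
  am <- select_dominant_species(amazon_catch(), 0.65)
  expect_equal(nrow(am), 7L)
  expect_equal(am$species[1], "Jaraqui")
  expect_equal(max(am$cumulative_percent), 67.56, tolerance = 0.05 / 67.56)

  med <- select_dominant_species(mediterranean_catch(), 0.65)
  expect_equal(med$species, c("Sardine", "Anchovy", "Mackerel", "Hake"))
  expect_equal(max(med$cumulative_percent), 66.86, tolerance = 0.05 / 66.86)

  can <- select_dominant_species(cantabric_catch(), 0.65)
  expect_equal(can$species, c("Mackerel", "Sardine", "Blue whiting", "Tuna"))
  expect_equal(max(can$cumulative_percent), 71.84, tolerance = 1e-4)

  riv <- select_dominant_species(rivers_catch(), 0.9)
  expect_equal(riv$species, c("Brown trout", "Atlantic salmon"))
})

test_that("aggregate residual rows count toward the total but are never selected", {
  # "Others" outranks Anchovy by tonnage in the Mediterranean table
  med <- select_dominant_species(mediterranean_catch(), 0.65)
  expect_false("Others" %in% med$species)
  expect_equal(attr(med, "total_tonnage"), 30459)
})

test_that("dominant selection handles edge cases", {
  one <- select_dominant_species(
    tibble::tibble(species = "A", tonnage = 5), 0.2)
  expect_equal(one$cumulative_percent, 100)
  expect_error(select_dominant_species(
    tibble::tibble(species = c("A", "B"), tonnage = c(0, 0))), "zero")
  # idempotence: re-selecting on the selected subtable at threshold 1 keeps it
  dom <- select_dominant_species(cantabric_catch(), 0.65)
  again <- select_dominant_species(dom[, c("species", "tonnage")], 1.0)
  expect_equal(again$species, dom$species)
})

test_that("largest-remainder allocation reproduces hand-derived counts", {
  expect_equal(allocate_samples(tibble::tibble(
    species = c("a", "b"), fraction = c(0.5, 0.5)), 40)$n_samples, c(20L, 20L))
  med <- tibble::tibble(species = c("Sardine", "Anchovy", "Mackerel", "Hake"),
                        fraction = c(0.6477, 0.2055, 0.0815, 0.0654))
  expect_equal(allocate_samples(med, 40)$n_samples, c(26L, 8L, 3L, 3L))
  can <- tibble::tibble(species = letters[1:4],
                        fraction = c(0.4542, 0.2290, 0.1716, 0.1451))
  expect_equal(allocate_samples(can, 40)$n_samples, c(18L, 9L, 7L, 6L))
})

test_that("allocation conserves n, guarantees one sample each, errors when n < S", {
  for (seed in 1:5) {
    fr <- withr::with_seed(seed, stats::runif(6))
    al <- allocate_samples(tibble::tibble(species = letters[1:6], fraction = fr), 37)
    expect_equal(sum(al$n_samples), 37L)
    expect_true(all(al$n_samples >= 1L))
  }
  tiny <- tibble::tibble(species = c("big", "tiny"), fraction = c(0.999, 0.001))
  expect_equal(allocate_samples(tiny, 10)$n_samples, c(9L, 1L))
  expect_error(allocate_samples(tiny, 1), ">=")
})

test_that("Shannon index uses natural log on sample composition", {
  expect_equal(shannon_index(c(10, 10, 10, 10))$H, log(4))
  expect_equal(round(shannon_index(c(38, 2))$H, 4), 0.1985)
  expect_equal(round(shannon_index(c(26, 8, 3, 3))$H, 4), 0.9904)
  df <- tibble::tibble(species = c("a", "b"), n_samples = c(38, 2))
  expect_equal(shannon_index(df)$H, shannon_index(c(38, 2))$H)
})

test_that("Shannon is permutation-invariant, zero iff concentrated, merge-monotone", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, stats::rpois(6, 20) + 1)
    expect_equal(shannon_index(sample(x))$H, shannon_index(x)$H)
    merged <- c(x[1] + x[2], x[-(1:2)])
    expect_lte(shannon_index(merged)$H, shannon_index(x)$H)
    expect_lte(shannon_index(x)$H, log(length(x)))
  }
  expect_equal(shannon_index(c(40, 0, 0))$H, 0)
  expect_error(shannon_index(c(0, 0)), "zero")
})

test_that("mean trophic level is the unweighted mean with n-1 variance", {
  tl <- tibble::tibble(species = c("a", "b", "c"),
                       trophic_level = c(2, 3, 4))
  expect_equal(mean_trophic_level("a", tl),
               tibble::tibble(mean_trophic_level = 2, variance = 0, n_species = 1L))
  two <- mean_trophic_level(c("a", "c"), tl)
  expect_equal(two$mean_trophic_level, 3)
  expect_equal(two$variance, 2)
  three <- mean_trophic_level(c("a", "b", "c"), tl)
  expect_equal(three$mean_trophic_level, 3)
  expect_equal(three$variance, 1)
  expect_error(mean_trophic_level(c("a", "ghost"), tl), "ghost")
  # catch-weighted alternative
  expect_equal(mean_trophic_level(c("a", "c"), tl, weights = c(3, 1))$mean_trophic_level,
               2.5)
})
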