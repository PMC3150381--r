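test_that("haplotype collapsing groups exact matches and counts them", {
  ht <- collapse_haplotypes(rep("ACGT", 5))
  expect_equal(nrow(ht), 1L)
  expect_equal(ht$count, 5L)
  ht2 <- collapse_haplotypes(c("ACGT", "ACGT", "ACGA"))
  expect_equal(nrow(ht2), 2L)
  expect_equal(sort(ht2$count), c(1L, 2L))
  expect_error(collapse_haplotypes(c("ACGT", "ACG")), "equal length")
})

test_that("ambiguous sequences merge only into a unique compatible haplotype", {
  ht <- collapse_haplotypes(c("ACGT", "ACGN", "AGGT"))
  expect_equal(nrow(ht), 2L)
  expect_equal(ht$count[ht$haplotype == "ACGT"], 2L)
  # compatible with both ACGT and ACGA: kept distinct
  ht2 <- collapse_haplotypes(c("ACGT", "ACGA", "ACGN"))
  expect_equal(nrow(ht2), 3L)
  # species provenance follows the merge
  tbl <- tibble::tibble(sample_id = c("1", "2"),
                        species = c("Salmo trutta", "Salmo salar"),
                        sequence = c("ACGT", "ACGN"))
  ht3 <- collapse_haplotypes(tbl)
  expect_equal(ht3$species[[1]], c("Salmo salar", "Salmo trutta"))
})

test_that("haplotype diversity follows Nei's corrected estimator", {
  expect_equal(haplotype_diversity(rep(1, 7))$Hd, 1)        # all unique
  expect_equal(haplotype_diversity(c(5))$Hd, 0)             # monomorphic
  expect_equal(haplotype_diversity(c(2, 2))$Hd, (4 / 3) * 0.5)
  expect_error(haplotype_diversity(c(1)), "at least 2")
  # duplicating the sample changes Hd only through the n/(n-1) correction
  x <- c(4, 3, 1)
  n <- sum(x)
  hd1 <- haplotype_diversity(x)$Hd
  hd2 <- haplotype_diversity(2 * x)$Hd
  expect_equal(hd2 / hd1, (2 * n / (2 * n - 1)) / (n / (n - 1)))
})

test_that("nucleotide diversity equals the mean pairwise difference per site", {
  expect_equal(nucleotide_diversity(rep("ACGT", 4))$pi, 0)
  expect_equal(nucleotide_diversity(c("AAAAAAAAAA", "AAAAAAAAAT"))$pi, 0.1)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT", "AATT", "TTTT"))$pi,
               0.5416667, tolerance = 1e-6)
})

test_that("pi matches a brute-force double loop on small random samples", {
  bases <- c("A", "C", "G", "T", "N")
  for (seed in 1:6) {
    seqs <- withr::with_seed(seed, {
      n <- sample(3:8, 1)
      L <- sample(8:20, 1)
      vapply(seq_len(n), function(i) {
        paste(sample(bases, L, replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
              collapse = "")
      }, "")
    })
    expect_equal(nucleotide_diversity(seqs)$pi, brute_force_pi(seqs),
                 tolerance = 1e-12)
    expect_equal(nucleotide_diversity(sample(seqs))$pi,
                 nucleotide_diversity(seqs)$pi)
  }
})

test_that("pi never exceeds the maximum pairwise distance", {
  seqs <- c("AAAA", "AATT", "TTTT", "AAAT")
  max_pair <- max(hamming_matrix(seqs)) / 4
  expect_lte(nucleotide_diversity(seqs)$pi, max_pair)
  expect_error(nucleotide_diversity(c("NNNN", "ACGT")), "comparable")
})

test_that("translation follows the vertebrate mitochondrial code", {
  expect_equal(translate_coi("ATGGCC", frame = 1), "MA")
  expect_equal(translate_coi("TGA", frame = 1), "W")       # Trp, not stop
  expect_equal(translate_coi("ATA", frame = 1), "M")       # Met, not Ile
  expect_error(translate_coi("AGA", frame = 1), "stop")    # mito stop
  expect_equal(translate_coi("ATGNNN", frame = 1), "MX")
  expect_equal(translate_coi("AT-GCC", frame = 1), "XA")
})

test_that("frame auto-detection picks the unique stop-free frame", {
  expect_error(translate_coi("AGAGCC", frame = 1), "stop")
  # frames 1 (AGA...) and 3 (AGA TAA) hit stops; frame 2 reads GAG ATA = EM
  expect_equal(translate_coi("AGAGATAAA"), "EM")
  expect_error(translate_coi("AGAGAGAGG"), "stop-free")   # stops in all frames
  expect_error(translate_coi("AAAAAA"), "Ambiguous")      # several clean frames
})

test_that("protein collapsing merges synonymous haplotypes across species", {
  # three haplotypes differing at synonymous third positions -> one protein
  ht <- collapse_haplotypes(c("CTTGCC", "CTAGCC", "CTGGCC"))
  pt <- collapse_proteins(ht, frame = 1)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$protein, "LA")
  expect_equal(pt$count, 3)
  # nonsynonymous variants stay distinct
  ht2 <- collapse_haplotypes(c("CTTGCC", "CTTCCC", "CTTACC"))
  expect_equal(nrow(collapse_proteins(ht2, frame = 1)), 3L)
  # congeners with identical protein are merged into one variant
  tbl <- tibble::tibble(sample_id = c("t1", "s1"),
                        species = c("Salmo trutta", "Salmo salar"),
                        sequence = c("CTTGCC", "CTAGCC"))
  pt3 <- collapse_proteins(collapse_haplotypes(tbl), frame = 1)
  expect_equal(nrow(pt3), 1L)
  expect_equal(pt3$species[[1]], c("Salmo salar", "Salmo trutta"))
})

test_that("translation failures identify the offending haplotype", {
  ht <- collapse_haplotypes(c("ATGAGA", "ATGGCC"))  # AGA stop in frame 1
  expect_error(collapse_proteins(ht, frame = 1), "H[12]")
})

test_that("haplotypes-per-polypeptide ratio matches printed table values", {
  expect_equal(haplotypes_per_protein(14, 7), 2)
  expect_equal(haplotypes_per_protein(17, 4), 4.25)
  expect_equal(haplotypes_per_protein(15, 5), 3)
  expect_equal(haplotypes_per_protein(4, 4), 1)
  ht <- collapse_haplotypes(c("CTTGCC", "CTAGCC", "CTGGCC"))
  pt <- collapse_proteins(ht, frame = 1)
  expect_equal(haplotypes_per_protein(ht, pt), 3)
  expect_gte(haplotypes_per_protein(ht, pt), 1)
})
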