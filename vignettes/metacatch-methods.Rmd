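---
title: "Profiling fishery catches as barcode metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling fishery catches as barcode metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacatch)
```

## The idea

Microbial ecology routinely treats all DNA in an environmental sample as one
unit — a metagenome — so that diversity can be measured across species
boundaries. `metacatch` applies the same perspective to exploited fish
communities: all COI barcode sequences sampled from a regional catch are
pooled into a single sample, and diversity is profiled simultaneously at
three levels.

* **Genetic**: distinct haplotypes *k*, distinct translated polypeptides
  *P*, their ratio *k/P* (a proxy for synonymous, "hidden" variation),
  pooled haplotype diversity *Hd* and pooled nucleotide diversity *π* —
  all computed without separating species.
* **Ecological**: the Shannon index *H* of the sample composition and the
  mean trophic level of the dominant species.
* **Taxonomic**: total taxonomic distinctness (TTD) and total taxonomic
  path length (sΦ⁺) of the dominant species on a fixed six-rank Linnean
  tree.

The motivating observation is that a catch can be rich in species (high
ecological and taxonomic indices) yet poor in pooled genetic variation —
a pattern consistent with depletion of intraspecific diversity, e.g. under
heavy exploitation.

## Pipeline and estimators

### Dominant species and sample allocation

`select_dominant_species()` sorts species by annual tonnage and takes the
minimal prefix whose cumulative share of the **total** catch (including any
aggregate "Others" row in the denominator) reaches a threshold, 0.65 by
default. Aggregate rows themselves (`Others`, `Miscellaneous`) can never be
selected: they represent unidentified remainder, not a species — without
this rule a large residual row can displace a true species from the set.
River sport fisheries, where few species dominate the registered catch,
typically need a higher threshold (0.9) to span more than one species.

`allocate_samples()` apportions the sequencing effort (default n = 40
sequences per region) over the dominant species proportionally to their
catch weight using largest-remainder (Hamilton) rounding, with every
species guaranteed at least one sample. Real surveys are only
approximately proportional, so per-species counts can also be supplied
explicitly wherever a known composition must be reproduced.

### Pooled genetic diversity

`collapse_haplotypes()` groups aligned sequences by exact identity over
`A,C,G,T`. A sequence containing `N` or `-` is merged into an unambiguous
haplotype only when it is compatible (identical at all its unambiguous
sites) with **exactly one** of them; otherwise it stays distinct. The rule
is conservative by design: an ambiguous read never creates identity the
data cannot support, and never silently picks one of several compatible
partners.

`haplotype_diversity()` is Nei's small-sample corrected estimator
$Hd = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ with the sampling
standard deviation of Nei (1987, eq. 8.12). `nucleotide_diversity()` is
the mean proportion of differing sites over all $\binom{n}{2}$ pairs with
pairwise deletion of ambiguous sites — algebraically identical to the
frequency-weighted form $\frac{n}{n-1}\sum_{ij} x_i x_j \pi_{ij}$ used by
population-genetics software — with the standard deviation from Nei's
total-variance formula (1987, eq. 10.7). π is reported **per site**
(0–1), never ×100.

`translate_coi()` uses the vertebrate mitochondrial code (table 2:
`TGA`=Trp, `AGA`/`AGG`=Ter, `ATA`=Met). Because barcode amplicons do not
start in frame universally, the default frame policy is `auto`: the unique
reading frame without internal stops is chosen and anything else (none, or
several) is an error rather than a guess. Any codon containing an
ambiguous base translates to `X`, even when all resolutions would agree;
we found that fuzzy-codon resolution is genetic-code-dependent and prefer
the policy that can never mistranslate. `X` sites are pairwise-deleted in
protein distances.

### Taxonomic indices

Both indices live on a fixed six-rank tree (phylum, class, order, family,
genus, species) with a synthetic root above the phyla. Every edge carries
the same weight, normalised so that the longest possible inter-species
path — six ranks up to the root — equals 100, i.e. **100/6 per step**.
Under this convention congeners are 100/6 ≈ 16.7 apart, confamilial
species 33.3, and so on.

* `total_taxonomic_distinctness()` (TTD):
  $\mathrm{TTD} = \sum_i \left[ \sum_{j \ne i} \omega_{ij} / (S-1) \right]$ —
  the sum over species of the mean path weight to all others.
* `total_taxonomic_path_length()` (sΦ⁺): the summed edge weights of the
  subtree spanning the species set and the root — Faith-style
  phylogenetic diversity on Linnean ranks. With equal steps this is 100/6
  times the number of distinct taxa across the six ranks. A single species
  scores exactly 100 and a congener adds exactly one step.

Two design points deserve a note. First, the equal-step/100-maximum
normalisation is fixed rather than re-standardised per dataset: per-dataset
re-standardisation makes values incomparable across communities, which
defeats the purpose of a cross-regional profile. Second, sΦ⁺ is sometimes
glossed verbally as a variance of path lengths; the quantity implemented
here is the total path length, which is the one whose values behave as a
tree-complexity index (monotone under adding species, exactly +100/6 per
congener) and the one our reference values reproduce.

### Haplotype networks

`median_joining_network()` implements the median-joining construction of
Bandelt, Forster & Röhl (1999): iteratively build the ε-relaxed minimum
spanning network over the current states, add the majority-consensus
(median) state of each triple of mutually linked nodes when it is new, and
repeat until closure; finally prune obsolete medians (degree ≤ 2 and on no
shortest connection between observed haplotypes). ε defaults to 0, the
usual default in barcoding practice. Determinism: candidate medians are
added in lexicographic order, and the result is invariant under input
reordering. Sites with ambiguity in any haplotype are excluded from
network construction (and the exclusion reported); a site-level tie among
three different bases generates no median, a conservative reading of the
published algorithm's binary-coding behaviour. Observed haplotypes and
inferred medians are flagged on the graph, so the "real vs hypothetical
intermediate" node counts of a network figure are one `count_nodes()`
call.

### Protein trees

`protein_distance()` offers the p-distance (default) and
maximum-likelihood JTT distances (via `phangorn`), optionally
gamma-corrected at a user-supplied shape; model selection itself is out of
scope and the shape is treated as an input. `neighbor_joining()` wraps the
standard Saitou–Nei algorithm (`ape::nj`), clamping negative branch
estimates to zero with a warning, and `bootstrap_support()` resamples
alignment columns (default 2000 replicates, seedable) and reports per-split
support percentages on the point tree.

## The synthetic community generator

Real regional samples cannot be reconstructed from public data alone: the
per-sample haplotype frequencies behind a published table are typically
unprinted. The generator therefore *is* the test bed, and its defaults are
the study conditions the pipeline assumes:

* **n = 40** pooled sequences per community, allocated catch-proportionally;
* **L = 648 bp** (a codon multiple, a full-length COI barcode);
* **divergence floor of 24 substitutions** (~3.7% at the congener level,
  scaling up with the rank of the split — within the typical range of
  congeneric COI divergences in fishes);
* **geometric haplotype frequencies** (ratio 0.5) within species, matching
  the common-haplotype-dominated shape of barcode samples; uniform
  available.

`generate_ancestors()` evolves a random stop-free coding sequence down the
community's taxonomy, with every branch mutating a globally distinct set
of sites; pairwise distances are therefore exactly additive and
rank-consistent (congeners always closer than confamilials, etc.).
`generate_haplotypes()` adds `k − 1` single-site derivatives per species —
synonymous by default, so each species carries one protein; a configured
number of nonsynonymous variants yields exactly `1 + n_nonsynonymous`
proteins. The `synonymous_divergence` option constrains the *inter-species*
divergence to be synonymous too, reproducing the situation where congeneric
species share one identical COI polypeptide. When a species' allocation is
at least its designed haplotype number, each designed haplotype is sampled
at least once (mirroring surveys that deposit every unique haplotype);
remaining draws are multinomial. One PRNG stream, seeded from the spec,
drives the whole dataset, so identical specs produce byte-identical files.

What the generator deliberately does **not** emulate: coalescent genealogy
within species, indels and alignment error, sequencing error, or
recombination (absent in mtDNA). Passing parameter-recovery tests
therefore shows that the estimators measure what they claim on cleanly
structured data; it does not validate robustness to alignment or
sequencing artefacts in real barcodes.

## Numerical and testing choices

* Problem sizes in the test suite are chosen for exhaustive verifiability:
  brute-force π on ≤ 8 sequences × ≤ 20 sites, Steiner-tree enumeration on
  ≤ 4 haplotypes × ≤ 4 sites, NJ recovery on 5-leaf additive matrices, and
  one large-sample convergence check at n = 2000 where Hd and π must land
  within 2% of their closed-form expectations under the designed mixture.
* Remainder ties in allocation break by larger fraction then input order;
  tonnage ties in dominance keep input order; median candidates sort
  lexicographically — every tie-break is deterministic and documented.
* Cumulative-percentage values printed in official catch tables often
  accumulate per-species percentages that were already rounded; recomputed
  shares can differ from printed Σ% by a few hundredths of a percent, and
  comparisons should allow for that printing drift.
* `compute_profile()` reports fields it cannot compute (TTD with one
  species, trophic level without a table) as `NA` plus an explicit reason,
  rather than dropping or guessing them.

## Limitations

* The ambiguity-merging rule and the conservative `X` translation policy
  can each split haplotypes/proteins that deeper data would merge; both
  err on the side of inventing nothing.
* TTD and sΦ⁺ depend on the taxonomy table supplied; families split or
  lumped differently will change the indices, which is a property of the
  indices, not of the implementation.
* The median-joining implementation targets barcode-scale inputs (tens of
  haplotypes); it recomputes the full spanning network per sweep and is
  not tuned for hundreds of states.
* Bootstrap supports are reported for the point-estimate NJ topology only;
  no consensus-tree machinery is included.
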