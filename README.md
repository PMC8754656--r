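# reelscan

Design and analysis of iterative EMSA depletion screens for mapping
cis-regulatory elements (cis-REs) at 35-bp resolution.

## The problem

Functional cis-REs — short DNA sequences that regulate transcription by
recruiting regulatory proteins — exist both inside and outside epigenetically
marked regions, which makes them hard to enumerate from chromatin marks
alone. An in-vitro alternative is to synthesize a library of short DNA tiles
covering a region of interest, mix it with nuclear extract (NE), and run
repeated rounds of a native-gel electrophoretic mobility shift assay (EMSA):
tiles that bind a nuclear protein are shifted out of the free pool each
round, so after sequencing the recovered unshifted pool at several rounds,
protein-binding tiles reveal themselves by progressive depletion in the
NE-treated samples relative to buffer-treated controls.

`reelscan` implements the complete computational side of such a screen for R
users:

* **Library design** — two offset 35-bp tilings of a region (the second
  library covers the breakpoints of the first), with FASTA/BED/TSV export.
* **Screen simulation** — a forward model of the multi-round selection
  (retention weighting, pool resampling, PCR noise, sequencing), with
  ground-truth labels, usable both as a synthetic-data generator for testing
  and for power exploration.
* **Quantification** — exact full-length read matching (the screen counts
  only reads that match their template perfectly), percentages with
  pseudocounts, recovery-rate and replicate-concordance QC.
* **Candidate calling** — the screen's statistic: for each tile, the
  NE/buffer percentage ratio at rounds 1, 4, 7 and 10, an OLS slope over the
  four ratios, a per-round two-sided Student's t-test (3 NE vs 3 buffer
  replicates), and the conjunctive call

  `candidate  ⇔  slope < 0  and  p_r < α at every sequenced round (α = 0.05)`

  with no multiple-testing adjustment (downstream validation is assumed).
* **Concordance** — pairing of the two offset libraries by maximal overlap
  and a Pearson chi-squared test of candidate–candidate concordance against
  the independence expectation `n2·n1/N1`.
* **Genomic post-processing** — single-linkage clustering of candidates into
  enhancer-scale (140 bp) windows, candidate density within annotation
  intervals (BED), BED/TSV export.
* **FREP-MS binder calling** — the presence/absence rule for pulldown
  proteomics: a protein specifically binds a cis-RE iff it has peptide
  spectral counts in both pulldown samples and in neither control.

Functions take tibbles and return tibbles; results carry `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(reelscan)
library(dplyr)

# 1. design a dual tiling over a (here random) 35 kb region
set.seed(1)
region <- genomic_region(
  paste(sample(c("A", "C", "G", "T"), 35000, TRUE), collapse = ""),
  chrom = "chr9", start = 21994139
)
tiles <- design_tiling(region, tile_len = 35, offset = 17)
count(tiles, library_id)
#>   library_id     n
#> 1          1  1000
#> 2          2   999

# 2. simulate ten selection rounds; 100 binding tiles retained at 0.8/round
lib1 <- filter(tiles, library_id == 1)
screen <- simulate_screen(
  lib1,
  design = screen_design(depth = 1e6, pool_size = 1e7),
  n_functional = 100, effect = 0.8, seed = 37
)

# 3. percentages -> ratios -> slope + per-round t-tests -> calls
calls <- screen$counts |>
  to_percentages() |>
  depletion_records() |>
  call_candidates(alpha = 0.05)
glance(calls)
#>   n_tested n_slope_negative n_candidates alpha
#> 1     1000              225          100  0.05

# how well did the screen do?
truth <- screen$truth[match(calls$tile_id, screen$truth$tile_id), ]
mean(calls$is_candidate[truth$functional])   # sensitivity: 1
mean(calls$is_candidate[!truth$functional])  # false-positive rate: 0
```

`n_candidates = 100` means 100 of the 1000 tiles passed the conjunctive
rule; at this depth they are exactly the 100 truly functional tiles, and no
neutral tile was called. The FREP-MS step then works on spectral-count tables:

```r
read_peptide_counts(
  system.file("extdata", "frep_table1.tsv", package = "reelscan")
) |> summarize_binders()
#>   element n_specific binders
#> 1 S1606            5 DBN1,MVP,PABPC1,POLB,SERPINH1
#> 2 S961             1 FOXC2
```

## Acceptance script

`scripts/acceptance.R` rebuilds the dual tiling of a 58,415-bp region
(1669 + 1668 tiles), pairs the two libraries, marks 209 and 199 candidate
tiles at seed-drawn positions, and recomputes the independence-expected
cross-library candidate overlap from the pairing:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/` — implementation (design, simulation, quantification, calling,
  concordance, post-processing, FREP-MS).
* `tests/testthat/` — unit, property and acceptance tests; all fixtures are
  generated in code except the small spectral-count TSVs under
  `inst/extdata/` (`frep_synthetic_background.tsv` is synthetic, as named).
* `vignettes/reelscan-methods.Rmd` — the model, its assumptions and the
  numerical choices.
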