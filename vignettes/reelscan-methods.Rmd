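---
title: "reelscan: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{reelscan: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reelscan)
library(dplyr)
```

## The screen in one paragraph

A region of interest is tiled into 35-bp fragments, each synthesized between
two constant adapters used for PCR and sequencing. The pooled library is
incubated either with nuclear extract (NE) or with buffer, run on a native
gel, and the *unshifted* (unbound) band is excised, re-amplified and carried
into the next round; ten rounds are performed with three independent
replicate trajectories per condition, and the pool is sequenced at rounds 1,
4, 7 and 10 (24 sub-libraries per library). A tile that binds a nuclear
protein is removed from the unshifted pool at a constant per-round rate, so
its *percentage* of the NE pool decays relative to the buffer pool.
`reelscan` designs such libraries, simulates the selection, quantifies
reads, and calls candidates.

## Library design

`design_tiling()` produces Library 1 as abutting 35-bp tiles from position
0 and Library 2 as the same tiling shifted by `offset` (default 17 bp).
Because every internal Library 1 breakpoint then sits inside a Library 2
tile with at least `min(offset, 35 - offset)` = 17 bp of flank on each
side, an element straddling a Library 1 breakpoint is still captured intact
by Library 2. Trailing residues shorter than one tile are dropped rather
than padded — synthesized inserts must be exactly 35 bp, and the exact-match
quantifier depends on that. A 58,415-bp region yields 1669 + 1668 tiles.
Tiles containing N are designed but flagged and excluded from the synthesis
output, since a binding assay needs definite sequence. Inserts are taken
from the + strand; strandedness is handled at quantification, where the
reverse complement of each construct is also accepted.

The offset is configurable; 17 bp was chosen as the largest value for which
both flanks of every breakpoint are at least 17 bp. The published tile
counts constrain but do not uniquely determine the offset; any value in
(0, 35) preserves all coverage invariants, which the test suite checks
exhaustively for region lengths 35–700.

## The selection model

The simulator is deliberately minimal: it contains exactly the effects the
calling statistic must survive, and no more.

For each (condition, replicate) trajectory, tile abundances start from the
synthesized pool and evolve per round as

1. **retention**: tile *i* keeps weight `(1 - s0)(1 - f_i)` in NE and
   `1 - eps_buffer` in buffer, where `s0` is the nonspecific shift
   probability and `f_i` the tile's specific (protein-driven) shift
   probability;
2. **gel extraction**: the pool is multinomially resampled to `pool_size`
   molecules;
3. **amplification**: each tile's count is multiplied by an i.i.d.
   log-normal factor with log-sd `pcr_sigma`, then renormalized;
4. **sequencing** (at sequenced rounds): `depth` reads are drawn
   multinomially.

Because `s0` hits every tile equally it cancels exactly after
renormalization: the NE/buffer percentage ratio of a neutral tile has
expectation 1 at every round, and the ratio of a functional tile decays
essentially as `(1 - f_i)^r` (up to a normalization term that the test
suite's deterministic recursion oracle reproduces). Replicate trajectories
are fully independent from round 1 — each replicate's gel slice is carried
forward separately — but all replicates start from the *same* synthesized
abundance vector, drawn once per library.

### Parameter defaults, and why

* `s0 = 0.5`: the screen's gels show about half of all fragments shifted in
  NE-treated samples; the value only scales the surviving pool and cancels
  from every ratio.
* `eps_buffer = 0`: buffer contains no protein, so no specific loss; PCR
  noise still applies.
* `pcr_sigma = 0.01` per round: calibrated against the screen's replicate
  QC. Replicate percentage vectors are reported to agree at R² > 0.99 for
  *all* pairs including round 10, by which point amplification noise has
  compounded ten times; at `pcr_sigma = 0.02` the accumulated noise alone
  drops round-10 pairs below 0.99 at any sequencing depth, so 0.01 is the
  largest per-round jitter consistent with the observed QC.
* `library_sigma = 0` (log-sd of the synthesized pool's abundance spread):
  the model's one idealization, an equimolar pool. Real synthesized pools
  spread over orders of magnitude, and that spread is what makes replicate
  R² a meaningful QC — with an equimolar pool the buffer replicates differ
  only by noise and correlate near zero. The concordance property test
  therefore sets `library_sigma = 1` explicitly. The spread is shared across
  replicates and conditions (one synthesis, many aliquots) and so cancels
  from NE/buffer ratios.
* `mismatch_rate = 0.014` per base: with ~75-bp constructs this reproduces
  the screen's ~35% perfect-match recovery rate (0.986^75 ≈ 0.35).
* `depth = 1e5`, `pool_size = 1e6`: desk-scale defaults. Power is governed
  by per-tile coverage (see below), so tests that need the screen's power
  raise these.

A single integer seed drives everything; per-(library, condition,
replicate) sub-streams are derived deterministically, so adding a fourth
replicate does not perturb the first three (tested).

### What the generator does and does not emulate

It emulates: progressive depletion of binders, evenly distributed
nonspecific shifting, pool bottlenecks between rounds, multiplicative PCR
jitter, multinomial sequencing, per-base substitution errors, and synthesis
nonuniformity. It does not emulate gel-extraction efficiency gradients,
fragment-length effects, PCR jackpots or chimeras, protein titration, or
any systematic buffer-side loss. A green simulation test therefore
establishes that the statistics behave correctly under the model's noise
structure, not that the wet protocol is free of artifacts the model omits.

## Quantification

A read counts for a tile iff it equals the tile's full construct sequence
(or its reverse complement — toggleable) exactly; there is no alignment or
fuzzy matching, because the screen's own accounting counts only
perfect-template reads, and the matched fraction (recovery rate) is itself
a QC statistic. Percentages are computed over matched reads only — the only
self-consistent choice under exact matching — with a pseudocount (default
0.5) added per tile so that later NE/buffer ratios are always finite. With
pseudocount 0 an all-zero sub-library is an error rather than a silent NaN.

## Candidate calling

For each tile: replicate percentages are averaged per condition at rounds
1, 4, 7 and 10; the four NE/buffer ratios are formed; an ordinary
least-squares slope of ratio against round number is fitted; and at each
round a two-sided two-sample Student's t-test (pooled variance, df = 4 for
3 + 3 replicates) compares NE vs buffer replicate percentages. A tile is a
candidate iff the slope is negative **and** every round's p-value is below
α = 0.05. Choices worth stating:

* **Four per-round tests, all required.** The screen's description ("a
  P-value < 0.05 in round 1, 4, 7 and 10") is read as one test per round
  with all four significant. A single pooled test across rounds is
  available (`test_scope = "combined"`) for users who prefer the other
  reading.
* **Pooled-variance Student's t**, matching the named test; Welch is a
  flag. Degenerate zero-variance cells: equal means give p = 1 by
  convention; unequal means give the smallest positive double with a
  `degenerate` flag (p must stay in (0, 1]).
* **No multiplicity adjustment** gates the call — the screen deliberately
  trades false positives for sensitivity and validates downstream.
  Benjamini–Hochberg columns are emitted for reference only.
* **Ratios, not log-ratios**, are fitted by default (a `log_ratio` flag
  exists). The slope's x-values are the round numbers 1, 4, 7, 10; since
  only the sign is used, round indices would call identically (tested).
* The conjunction is strongly conservative under the null: with four
  approximately independent level-0.05 tests plus a sign constraint, the
  neutral false-positive rate sits far below 0.05 (measured 0 over 1200
  neutral tiles in the acceptance suite).

### Power and coverage

Detecting the round-1 difference (a 20% shift at retention 0.8) with three
replicates per arm needs per-tile, per-sub-library coverage of roughly
1000 reads: the t statistic scales as `0.2 * sqrt(coverage)` against a
df-4 critical value of 2.78, plus amplification and bottleneck noise. The
published screen ran at ~958 matched reads per tile per sub-library. Two
consequences, verified in the suite: at that coverage the caller recovers
≥ 90% (measured 99–100%) of 100 planted binders among 1000 tiles; and a
library in which most tiles are functional loses signal, because
renormalization measures each tile against the pool-average retention —
depletion is intrinsically relative.

## Concordance, clustering, density

Each Library 2 tile is paired to the Library 1 tile sharing most base pairs
(18 vs 17 bp at offset 17, so left; ties break left). Concordance uses the
one-to-one pairing: observed = Library 2 candidates whose partner is also a
candidate; expected under independence = `n2 * n1 / N1` (209, 199, 1669
give 24.92 ≈ 25); Pearson's chi-squared (no continuity correction, as in
the conventional `P < 2.2e-16` reporting style, with that value as the
reporting floor) on the 2×2 pairing table. An any-overlap counting mode
would roughly double the expectation and is deliberately not the default,
since only the one-to-one reading reproduces the published expectation.

Clustering joins two candidates when a single 140-bp window (four tile
lengths, an enhancer-scale unit) contains both, chained transitively
(single linkage). Chaining is a choice, not a given; a fixed 140-bp tiling
mode is provided. The implementation's union-find agrees with a brute-force
slide-every-window oracle on random instances (tested). Density counts a
candidate in an annotation interval on ≥ 1 shared bp (BED intersect
semantics; a `min_overlap_frac` switch gives majority-style rules), so a
boundary-straddling candidate counts in both neighbours — documented
double-counting, matching standard intersect behaviour.

## FREP-MS binder calling

Strict presence/absence on spectral counts: specific iff both pulldown
samples are positive and both controls are zero. No abundance modelling, no
thresholds beyond > 0 — the rule is the assay's own. Duplicate protein rows
are an error rather than being summed, to surface upstream table problems.
The shipped `frep_table1.tsv` fixture carries the screen's published counts;
`frep_synthetic_background.tsv` adds invented rejected rows (labelled
synthetic) because the eliminated background set is not published.

## Known limitations

* The simulator's noise model is multiplicative and i.i.d. per tile; real
  PCR noise is correlated within GC/length strata.
* Exact matching discards all reads with any error; at realistic error
  rates two-thirds of reads are unused, as in the screen itself.
* Calling treats rounds as independent tests although trajectories are
  autocorrelated; the conjunction is therefore conservative rather than
  calibrated.
* The cluster fraction and density statistics depend on candidate
  coordinates, not calling quality; they describe spatial structure only.
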