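---
title: "telorep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{telorep: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telorep)
```

This vignette is the package's own account of the four analyses it
implements: what each computes, under which assumptions, which parameters
matter, and where the design was genuinely open and a choice had to be
made. The numbers quoted here are the ones the test suite and
`scripts/acceptance.R` themselves compute; nothing is claimed beyond what
those runs show.

## 1. Terminal-permutation profiling

### The measurement

*Arabidopsis* telomeres are arrays of the 7-bp repeat TTTAGGG. A
blunt-ended telomere terminates at some phase of that repeat, so its
extreme 3′ end is one of the seven cyclic rotations
(`telomericPermutations()`). In the underlying assay a blunt hairpin is
ligated to the chromosome end, the junction fragment is amplified and
sequenced (single-end 50 bp), and the rotation found immediately 5′ of the
ligation junction names the terminal permutation. The quantity of interest
is the frequency vector over the seven rotations and its differences
between genotypes, in percentage points.

### Classification rules and why they are asymmetric

`classifyReads()` applies three rules with deliberately different
mismatch tolerances:

* **Adaptor (junction) match: tolerant.** The first 10 nt of the adaptor
  must match at some read offset with at most `maxMismatch` (default 1)
  substitutions; the smallest such offset wins. The adaptor is only a
  landmark, so sequencing errors in it should not cost the read.
* **Terminal 7-mer: exact.** The 7-mer immediately 5′ of the junction must
  equal one of the seven rotations exactly. The terminal base *is* the
  measured quantity: a tolerated substitution there would silently rename
  the permutation. Because the seven rotations are pairwise at least 3
  substitutions apart, a single error can only unclassify a read, never
  relabel it — at 1% per-base error about 6.8% of reads lose their
  terminal 7-mer and drop to `UNCLASSIFIED`, identically across rotations,
  so classified frequencies stay unbiased (this is what lets a 10⁶-read
  run recover an injected 58% to within ±0.5 points).
* **Upstream context: 90% identity.** At least `minRepeats` (default 2)
  complete repeats ending at the junction must match the phase-consistent
  consensus with ≥ 90% identity (one mismatch allowed in the 14-mer).
  This rejects non-telomeric fragments that happen to end in a
  rotation-like 7-mer.

Reads are canonicalized to G-strand orientation: a read whose forward
orientation yields no classifiable junction is retried as its reverse
complement, making results invariant to library orientation (tested).
Frequencies are computed over classified reads only; the unclassified
tally is reported but excluded from the denominator, since unclassifiable
reads carry no information about which rotation terminates the
chromosome.

The internal filters of the original instrument-side program are not
public; `minRepeats = 2` and `maxMismatch = 1` are this package's declared
defaults, not inferred values.

### Statistics

`aggregateReplicates()` uses unweighted means and sample SDs across
biological replicates (replicates are whole libraries, not reads, so
read-count weighting would be wrong). `compareProfiles()` reports
`Δ_p = (mean_A − mean_B) · 100` and an equal-variance two-tailed
two-sample t-test per permutation, matching the convention of reporting
"Student's t-test" contrasts; a null simulation in the test suite checks
the test holds its nominal 5% type-I rate on multinomial replicate
profiles.

### The generator

`simulateAmpliconReads()` emits `barcode + repeat-array + adaptor`
truncated to 50 nt, with the terminal rotation drawn from a preset vector
and iid per-base substitutions at `errorRate`; the true label is embedded
in the read name so the classifier's confusion matrix is computable
exactly. Preset anchors: TTTAGGG-3′ at 0.58 (C24) and 0.42 (Col-0); the
pol α preset sits 14 points below C24 with the loss moved to GTTTAGG-3′
and GGTTTAG-3′; the stn1 preset 16 points below Col-0 with the preference
shifted to GTTTAGG-3′; exo1 stn1 restored to a near-wild-type profile.
The unpublished components follow the rank order GTTTAGG > GGTTTAG >
other rotations and are documented fixture constants of this package.
The default adaptor is a fixed non-telomeric 20-mer: classification
depends only on locating the junction, so the exact sequence is
configurable. Default depth 10⁶ reads per sample sits at the low end of
the per-barcode depths such libraries actually produce; at that depth the
binomial SE of a frequency is ≈ 0.05 points, comfortably inside the
±0.5-point recovery target. What the generator does *not* model:
quality-dependent or indel errors, PCR duplication bias, chimeric reads.
Passing tests therefore demonstrate correctness of the classification
logic, not robustness to every real-library artifact.

## 2. Re-replication scoring from binned read depth

### The chain

For mutant and wild-type read placements from sorted 8C nuclei:

1. `collapseDuplicates()` — one read per (chromosome, start, strand).
2. `binCounts()` — reads summed into 10 kb bins by leftmost coordinate
   (trailing partial bins kept and flagged).
3. `filterBins()` — drop bins with mappability 0, then per sample drop
   bins with counts above `T = Q0.99 + median` over the mappable bins
   (type-7 linearly interpolated quantile, so `T` is bit-reproducible).
   The threshold reads the filter as *99th percentile plus median*; the
   alternative reading (remove the top 1% *and* everything above the
   median) would delete half the genome and is rejected. A bin removed
   for any sample is removed for all, keeping ratio grids aligned.
4. `averageReplicates()` — per-bin arithmetic mean across replicates.
5. `log2Ratio()` — `r_i = log2(mutant_i / wildtype_i)` over bins where
   both counts are positive; zero-count bins are dropped (no pseudocount —
   none is prescribed, and dropping keeps the choice auditable in the
   reported `nDropped`).
6. `baseWindowScale()` — per chromosome, a 5 Mb window slides one bin at a
   time; the window of minimum mean ratio is the **base window**, taken to
   represent the unreplicated copy-number level. Every bin becomes
   `z_i = (r_i − μ_b)/σ_b` with `μ_b`, `σ_b` the mean and sample SD inside
   the base window: 0 means base-level replication, and deviations are
   expressed in units of the sample's own variability, so noisier samples
   are automatically penalized.
7. `smoothProfile()` — centered 10-bin running mean (partial windows at
   chromosome edges).

Because `μ_b` is subtracted, any constant shift of the ratios — in
particular a library-size factor, which is additive in log space — cancels
exactly; the test suite asserts bit-level invariance of `z` under scaling
all mutant counts by an arbitrary constant. This subtraction *is* the
mechanism that accounts for differences in read numbers, so no separate
depth normalization exists or is needed.

### Open choices, resolved

* **Window stepping.** Per-bin stepping (not disjoint tiling) — finer
  placement of the base window at negligible cost.
* **σ in the scaling.** The SD *within the base window* is the default;
  the chromosome-wide SD is available via `sigma = "chromosome"`. The
  base-window SD is preferred because the base window is the sample's own
  estimate of replication-neutral variability, uncontaminated by the
  re-replicated regions themselves.
* **Window eligibility.** Only windows fully contained in the chromosome
  are candidates (a truncated trailing window with few bins would win the
  minimum by noise alone and mis-center the scaling); `minBins` (default:
  half the window's nominal bin capacity) guards against sparse windows.
  Chromosomes shorter than the span use the whole chromosome as the single
  candidate.
* **Degenerate SD.** A constant ratio profile has `σ_b = 0`; strict mode
  errors, permissive mode divides by 1 with a warning and yields an
  all-zero profile.
* **Duplicate collapse** is strand-aware: opposite-strand reads at one
  coordinate are distinct molecules.
* Best-alignment selection for multireads belongs to the upstream aligner;
  the module consumes placed positions. Cubic-spline display smoothing is
  cosmetic and intentionally not implemented; `smoothProfile()` is the
  quantitative smoother.

### Validation

A naive loop implementation (separate quantile, window search and running
mean written from their definitions) lives in the test helpers; the full
chain matches it bin-for-bin to 1e-12 on a 100-bin chromosome. On the toy
study condition — 2 chromosomes × 30 Mb, a centered pericentromere
covering 20% of each chromosome at 1.6× copy number, 2% unmappable bins,
10⁶ reads with 5% duplicates, two replicates per genotype — bins with
smoothed `z > 1` recover the true region with Jaccard ≈ 0.97 (threshold
0.8 asserted), and the selected base windows fall in the chromosome arms.
The toy genome is deliberately small so the whole run takes seconds; the
generator models bin-level copy number and a binary mappability mask, not
sequence composition, GC bias or mappability gradients.

## 3. Flow-cytometry peak normality

### Model

Leaf/seedling nuclei endoreduplicate, giving a 2C–32C doubling series.
`simulateNuclei()` draws a ploidy class from `classWeights` (defaults
0.35/0.30/0.20/0.10/0.05 for 2C…32C, a typical seedling distribution) and
a fluorescence `N(μ_c, (cv·μ_c)²)` with `cv = 0.05`, a mid-range CV for
plant nuclei on a linear-scale cytometer. Re-replication is modelled as a
*shoulder*: with probability `rerepProbability`, a nucleus of class ≥ 8C
gains `Uniform(0, extraFractionMax · μ_c)` extra DNA. The generative form
is this package's choice — the observed phenotype is only "a shoulder
towards higher DNA content" — and additive uniform extra DNA is the
simplest model producing exactly that phenotype with a tunable mass.
Histograms default to 512 equal-width channels over a full scale of
`24 · peak2C`, which puts ~60 channels across an 8C gate, the regime of a
typical acquisition.

### The statistic

The 8C peak is gated at geometric midpoints to its neighbors,
`[mode/√2, mode·√2]`, fitted by Levenberg–Marquardt least squares
(`A·exp(−(x−μ)²/2σ²)`), and scored with the per-event Pearson statistic

> X² = Σ_k (o_k − e_k)² / e_k / N_gate,

pooling adjacent channels from the gate edges inward until every expected
count is ≥ 1 (pooling preserves both totals). Under a truly Gaussian peak
with K effective channels and 3 fitted parameters, `X² ≈ χ²(K−3)/N_gate`,
so with ~3000 gated nuclei its 95% quantile lies below 0.04 — which is
why "X² < 0.04" works as a normality criterion at the 95% confidence
level for this acquisition regime. The acceptance run measures the 95th
percentile over 200 simulated pure-Gaussian peaks at ≈ 0.015. The exact
statistic of the original instrument software is proprietary; this
definition is a re-specification that reproduces the operational
criterion, not a reverse-engineering claim, and the 0.04 cutoff is only
claimed for ~3000 nuclei and ~60-channel gates.

`shoulderFraction()` integrates the positive excess over the fitted
Gaussian beyond `μ + 2σ` on the high side. With a shoulder present the
least-squares fit inflates `σ̂` somewhat (the shoulder drags the fit), so
S slightly underestimates the injected mass; paired-seed tests show it
stays within ±30% of the generator's truth at the strongest setting and
that both X² and S increase with the injected shoulder probability.
Gate placement is this package's convention — the original gating is not
specified. `compareChi2()` applies the same equal-variance t-test as the
permutation module. Debris, doublets and S-phase continuum are not
modelled; the χ² criterion transfers to real cytograms only to the extent
that the 8C gate isolates a single class.

## 4. Densitometry

`overhangSignal()` follows the stated order of operations: divide each
lane by its loading control, subtract the matched T4-pretreated lane
(T4 DNA polymerase removes 3′ overhangs, so that lane is the hybridization
background), then divide by the wild-type mean so the wild-type group is
exactly 1. Subtract-then-normalize alternatives differ under unequal
loading and are rejected. Negative background-subtracted signals are
floored at 0 with a warning (the assay measures a non-negative quantity;
propagating negatives would let background noise produce negative
overhang content). `dotblotContent()` is the same chain without the
subtraction step, with CEN180 as the repeat loading control.
`foldChange()` returns the ratio of group means with a first-order
propagated SD from the replicate SDs.

`makeDensitometryFixture()` builds tables whose normalization chain
recovers a known fold exactly at zero noise (the packaged check: fold 6,
wild-type mean exactly 1). Its log-normal noise (unit mean,
`cv = noiseCv`) applies to lane signals; loadings are the design values of
the table. With noise on signals only, a 4-lane fold-6 table recovers the
fold within [4.8, 7.5] in ≥ 95% of seeds (tested over 200); adding
independent loading noise would push recovery below that band, which is
why the signal-noise reading was adopted. The module consumes integrated
lane signals; image-level band quantification is out of scope.

## Problem sizes and reproducibility

Every generator takes an explicit integer seed and is bit-reproducible
given (parameters, seed); the command-line layer writes a JSON sidecar
with the full configuration next to every output. The suite and the
acceptance script use the sizes the analyses are designed around — 10⁶
amplicon reads per sample (4 replicates per genotype for contrasts), 10⁶
genomic reads per sample on the 2 × 30 Mb toy genome, 3000 nuclei per
cytogram with 200-seed sweeps — chosen so each matches the corresponding
real experiment's scale while the whole run stays in the minutes range on
a single core.

## Known limitations

* Presets, the shoulder model and the toy genome are calibrated to the
  *printed* anchor values; unpublished components are fixture constants,
  so recovery tests validate the pipeline's correctness, not the
  unpublished biology.
* The classifier assumes substitution-only errors; indels shift the
  repeat phase and unclassify reads rather than being corrected.
* Mappability is binary at bin resolution; fractional mappability is
  accepted on input but the filter only removes exact zeros, as specified.
* The χ² criterion's numeric cutoff is acquisition-regime-specific (see
  above); compare genotypes run on the same regime rather than absolute
  values across instruments.
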