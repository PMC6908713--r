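---
title: "Methods: the CpG-density lifespan clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CpG-density lifespan clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgclock)
```

## The model and its assumptions

The clock rests on one biological premise: the density of CpG dinucleotides
in gene promoters — the sites DNA methylation acts on — co-varies with a
species' maximum lifespan, plausibly because dense CpG islands buffer
long-lived species against the regulatory drift of accumulated methylation.
The statistical translation is deliberately plain:

1. **Features.** For each promoter in a fixed universe, the CpG density of
   its best homology hit in a species' genome: CpG count inside the hit
   interval divided by the hit's alignment length. A promoter with no hit
   above 70% identity (strict) contributes exactly 0. Density is computed
   on the forward strand only; since 5'-CG-3' is its own reverse
   complement, the count is strand-symmetric and no orientation handling is
   needed (this is asserted by property tests).

2. **Sparse regression.** Natural-log maximum lifespan is regressed on the
   density matrix under the elastic-net penalty with mixing α = 0.5, the
   penalty λ chosen as the cross-validation MSE minimum over 10 folds
   (`lambda.min`, not the 1-SE rule — "minimum λ" is the convention the
   clock was published with). The objective uses the 1/(2n) loss scaling so
   λ values are comparable across sample sizes; predictors are standardized
   internally and weights reported on the density scale. Natural-log
   transformation of lifespan is an assumption of linearity on the
   multiplicative scale: a promoter's density shift has the same
   proportional effect on a 5-year fish as on a 50-year mammal.

3. **Phylogenetic class calibration.** The raw score
   `x = w0 + sum(w_i d_i)` is re-regressed on ln lifespan with
   vertebrate-class intercept and slope offsets, by generalized least
   squares under a Brownian-motion trait covariance: `V_ij` is the shared
   evolutionary time of species *i* and *j* (from a time-calibrated tree,
   or `max(0, T - t_ij)` from pairwise divergence times under an
   ultrametric molecular clock). Pure Brownian motion is assumed — no
   Pagel's λ or Ornstein-Uhlenbeck transformation — matching the common
   default of comparative-methods packages. Amphibia is the reference
   class: its offsets are absorbed into the global constants, so any class
   without fitted coefficients predicts with a = b = 0.

Species contribute one observation each; lifespan records mix captive and
wild provenance, which the evaluation battery tests as a potential
confounder rather than modelling it. Body-mass and other life-history
covariates are deliberately excluded: the clock is meant to work from a
genome alone.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| identity threshold | 70 (strict) | % | homology filter defining a usable hit |
| α (elastic net) | 0.5 | — | equal L1/L2 mix; sparse but tolerant of correlated promoters |
| CV folds | 10 | — | standard; fold assignment is seed-derived |
| train fraction | 0.7 | — | class-stratified `round(0.7 n_class)` per class |
| TSS flank / bin | 5000 / 500 | bp | 20 gene-oriented bins around each TSS |
| promoter window | 600 | bp | the −499..+100 window promoter databases use |

A class with a single species goes to training (a lone species cannot be
both fitted and held out); a class with fewer than two training members is
excluded from calibration and falls back to a = b = 0, with a warning —
amphibians are routinely this sparse in real panels.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` generates the conditions the pipeline is validated
under: a Yule tree rescaled to 500 My depth; classes assigned to contiguous
clades (not at random) so class and phylogeny are confounded exactly as in
real vertebrate panels; ln lifespan evolving by Brownian motion (rate 0.05
ln-yr/√My) around class means and rescaled into 1.1–205 years, the span of
published vertebrate records; and 40 causal promoters among 500 whose
density is affine in ln lifespan with Gaussian noise, positive and negative
slopes planted in roughly the 22:12 ratio seen among significantly
correlated promoters. `realize_sequences()` turns any density matrix into
concrete FASTA/BED/hit-table fixtures whose recomputed densities round-trip
within the 1/600 quantization, and `simulate_ancient_variants()` plants
SNPs that each create or destroy exactly one CpG.

Two generator constants deserve explanation:

* **Density cap 0.4.** Realized promoters place CpGs at non-adjacent
  positions, so densities above 0.5 are impossible and 0.4 leaves headroom
  for random placement; the cap is applied to simulated densities so every
  matrix is realizable as sequence.
* **Noise level 0.02 (density units).** The per-promoter noise was fixed,
  once, at the value where end-to-end recovery is reliable at every seed:
  the elastic-net stage is robust (raw-score R² ≈ 0.95 on held-out
  species), but the GLS class offsets are identified mainly by a few deep
  phylogenetic contrasts — class indicators are constant within clades — so
  they inherit any raw-score error with high variance. At noise 0.02 the
  calibrated test-set R² stays in 0.80–0.96 across seeds; at 0.045 it
  averages ≈ 0.76, the regime reported for the clock on 252 real genomes,
  but with seed-level excursions below 0.7. Users wanting the harder
  regime can set `density_noise_sd = 0.045`.

What the generator does **not** emulate: realistic base composition
(isochores, repeats, CpG-island clustering), assembly quality differences,
homology-hit length decay with evolutionary distance, sequencing error or
ancient-DNA damage. Passing tests therefore demonstrate that the pipeline's
statistics recover a signal of the assumed form under realistic phylogenetic
confounding — not that promoter CpG density predicts lifespan in nature.

## Numerical choices

* **Coordinates** are 0-based half-open internally; BLAST's 1-based
  inclusive subject coordinates are converted on parse, with reversed
  coordinates marking the minus strand.
* **Top-hit ties** break by bitscore (desc), then e-value (asc), then input
  order — the ranking BLAST itself uses — making filtering deterministic
  and idempotent.
* **Density denominator** is the alignment-length column (which counts gap
  columns), not the subject-interval width; on the ancient-genome path no
  alignment exists, so the locus interval width is used, keeping densities
  comparable with reference intervals. Dinucleotides containing N never
  count; N is excluded from GC-content denominators.
* **GLS** is solved by Cholesky whitening and QR, with an explicit error
  naming the offending class when an indicator column is collinear (a class
  with constant raw score). With identity covariance it reproduces OLS to
  1e-8, and it matches `nlme::gls(correlation = corBrownian(...))` on
  Brownian data to 1e-6 (both are test oracles).
* **λ = 0 and λ → ∞** elastic-net limits are verified against the
  normal-equations OLS solution and the mean-only model; the univariate
  α = 1 path is verified against the closed-form soft-threshold solution.
* **REF-allele mismatches** when applying VCF records abort with the
  position, since they almost always mean a genome-build mismatch (e.g.
  variants called on a different assembly version than the supplied
  reference).
* **Degenerate inputs**: empty hit files parse to empty tables; empty VCFs
  edit nothing and reproduce the reference prediction bit-identically;
  zero-variance promoter columns are flagged (correlation screen) or
  dropped with a warning (PCA).

## Design decisions that were genuinely open

* **Which R² to report.** "Correlation between known and predicted
  lifespan" can mean the squared Pearson correlation or the regression R².
  For the simple regression of known on predicted the two coincide, but the
  evaluation reports both (`r_squared_log`, `r_squared_lm`) so either
  convention can be read off.
* **MAE** is the *median* absolute error in years, not the mean — the
  abbreviation is expanded this way in the clock's own reporting, and the
  median is robust to the heavy right tail of lifespans.
* **Group error comparisons** (train vs test, captivity vs wild) use
  Welch's t-test; "t-test" alone under-specifies, and the unequal-variance
  form is the safer default.
* **ANCOVA** for the class effect uses sequential (type-I) sums of squares
  with the covariate entered first — `anova(lm(known ~ predicted + class))`
  — the default of the analysis environment this model family is fitted in.
* **PCA** standardizes columns (correlation PCA), matching the convention
  of the usual multivariate toolkits for heterogeneous columns.
* **KS null calibration.** The exact two-sample Kolmogorov–Smirnov p-value
  at n = 20 per profile is discrete and conservative (measured type-I
  ≈ 0.03–0.04 at nominal 0.05); tests assert level control and median
  calibration rather than exact uniformity of null p-values.
* **Heterozygous calls** are applied unconditionally: ancient-DNA pipelines
  emit consensus-style calls, and genotype-aware editing is out of scope.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
the end-to-end design uses 250 species × 500 promoters (about 175/75
class-stratified train/test), matching the scale of real reference-genome
panels; sequence-level round-trips use 2–6 species × 4–10 promoters with
600-bp promoters; the GLS recovery study uses 100 replicates of 60-species
trees. A full run of suite plus acceptance script completes in a few
minutes on one core.

## Known limitations

* The published clock's 42 promoter weights are not redistributable, so the
  packaged `published_clock()` carries the calibration constants only; it
  evaluates the formula but cannot score a genome.
* The homology module's built-in `seed_extend_align()` is an ungapped
  seed-and-extend intended for generated fixtures; real promoter searches
  should use a production aligner and feed the tabular output to
  `read_blast_hits()`.
* Predictions carry no uncertainty intervals; the clock is a point
  predictor.
* Lifespans near the calibration boundary (very short- or very long-lived
  species) are compressed by the linear-in-ln model, and humans are not
  special-cased even though their recorded maximum is an outlier relative
  to the clock's training range.
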