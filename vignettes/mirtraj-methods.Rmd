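---
title: "Methods: trajectory-class differential expression and miRNA regulator nomination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-class differential expression and miRNA regulator nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtraj)
```

## The analysis problem

`mirtraj` analyses paired mRNA and miRNA count matrices from a factorial
differentiation experiment: two genotypes (wild type, `WT`, and a null
mutant, `dKO`) crossed with two developmental stages (embryonic stem
cells, `ESC`, and retinoic-acid-differentiated cells, `RA`), with
replicated libraries in each of the four cells. The scientific questions
it addresses are

1. which genes and miRNAs respond to differentiation, and how the null
   genotype modulates that response (four *trajectory classes*);
2. whether the modulated gene sets over-represent curated annotations
   (phenotype lists, cell-type markers, regulator-target sets); and
3. which miRNAs plausibly drive the mRNA changes, judged by the negative
   shift of the expression correlations between a miRNA and its
   annotated targets.

## Model and procedure

### Normalization

Library scaling uses the trimmed mean of M-values (TMM) with the
method's published defaults: the reference sample is the one whose
upper-quartile count fraction is closest to the mean; pairwise
log-ratios (M) and average log-abundances (A) are computed on
depth-scaled counts; the 30% most extreme M-values and 5% most extreme
A-values are trimmed symmetrically; the remaining M-values are averaged
with inverse asymptotic-variance weights. Factors are rescaled to a
geometric mean of one, and the effective library size is the raw column
sum times the factor. Expression is reported as log2 counts per million
against effective library sizes with a depth-adjusted prior count
(default 0.5) so that zeros stay finite.

One point worth stating explicitly: with the inverse-variance weights,
TMM factors are exactly invariant only under *composition-free* depth
changes (a column that is an entry-wise multiple of another, or a
uniform rescaling of all libraries). Scaling a single column changes
the per-gene weights and perturbs the factor slightly; this is a
property of the weighted estimator itself, not of the implementation.

### Differential expression

Per-feature testing uses a two-group exact test under a negative
binomial model with a single *fixed* dispersion
(variance $= \mu + \phi\mu^2$, default $\phi = 0.1$); no dispersion is
estimated from the data. Because the test conditions on a feature's
total count, the samples are first equalized: each column is scaled to
the geometric mean of the contrast samples' effective library sizes and
rounded (half to even). This is a deliberate, documented approximation
to quantile-adjusted pseudo-counts; the exactness claims of the test
suite are made on the equalized counts.

Conditional on the total $t = s_A + s_B$, the B-group sum of $n_B$
equalized NB samples follows a negative hypergeometric distribution
with shapes $n_B/\phi$ and $n_A/\phi$ — the NB probability parameter
cancels, so no mean needs to be estimated. The implementation
enumerates this distribution in closed log form; the two-sided p-value
doubles the smaller tail, includes the tie mass at the observed value
in both tails, and is capped at 1. A feature with zero total has
$p = 1$ and log-fold-change 0. Fold changes use prior-augmented
(0.5 per group mean) CPMs.

DE calling applies three joint thresholds — raw $p < 0.05$,
$|\log_2 \mathrm{FC}| > 0.75$, average $\log_2 \mathrm{CPM} > 0$ — all
configurable. BH-adjusted p-values are reported alongside but are *not*
used for calling: the filtering rule is stated in terms of the raw
p-value, and both columns are emitted so the choice can be revisited.

### Trajectory classes

Two contrasts define the classes: `differentiation` = WT-RA vs WT-ESC
and `genotype` = dKO-RA vs WT-RA. The genotype contrast is evaluated at
the RA stage only, because the downstream questions concern the
differentiated state; both contrasts are configurable, and an
alternative (pooling both genotypes' differentiation responses) is a
one-line change via `make_contrast()`. A feature significant in *both*
contrasts is assigned `up_up`, `up_down`, `down_up` or `down_down`
(first token: differentiation direction; second: genotype-effect
direction); everything else is `unclassified`. The same operation
classifies miRNAs from the miRNA DE calls.

### Gene-set enrichment

Over-representation uses the one-sided Fisher exact test: the
hypergeometric upper tail $P(X \ge \mathrm{overlap})$, with odds ratios
from the 2x2 table (0.5 continuity correction when a cell is zero). The
default universe is the set of features passing the expression filter
(average logCPM > 0) — enrichment against expressed genes avoids
detection bias — and is configurable to all annotated features. BH FDR
is applied across the entire query-by-set table; regulator-target
(ChIP-style) collections run through the same engine as GMT fixtures,
with no separate code path.

### miRNA regulator nomination

For every target-map edge whose endpoints are present and non-constant,
the Pearson correlation (Spearman reported alongside) is computed across
all 4xn samples from per-feature z-scores of TMM-log-CPM ("standard
normalized expression"). Using all samples, rather than a stage subset,
is a design choice: the anti-correlation signal spans both the
differentiation and the genotype factor. The transform and the sample
subset are both pluggable.

Per miRNA with at least `min_targets` (default 5 — the exact one-sided
signed-rank p cannot reach 0.05 below $n = 5$) tested edges, a
one-sample one-sided Wilcoxon signed-rank test asks whether the target
correlations are shifted below zero; the exact null distribution is used
for $n \le 25$ with no zeros or tied magnitudes, otherwise the normal
approximation with continuity and tie corrections. A *candidate
regulator* is a miRNA in a down class (`down_down`, labeled
`down_enhanced`, or `down_up`, `down_counteracted`) with shift
$p < 0.05$; candidates are ranked by ascending p, ties broken by more
negative mean correlation then id, so output is deterministic. Each
candidate carries its anti-correlated targets — tested targets with
$r < 0$ (no magnitude cut, consistent with testing the whole correlation
distribution; a cut is exposed as an option) in the `up_up`/`up_down`
classes. No multiplicity correction is applied across miRNAs by default
(the nomination rule is a raw-p threshold); BH is available behind the
`adjust` flag.

## The synthetic-data generator

Real data for this design are not bundled, so `simulate_dataset()` is
the canonical input source and the basis of validation. It emulates:

- NB counts with variance $\mu + \phi\mu^2$, $\phi_{true} = 0.1$
  matching the analysis' assumed dispersion;
- log-normal baseline abundances (sdlog 1.8, a realistic ~4 orders of
  magnitude of dynamic range, so the logCPM > 0 filter removes a real
  low tail);
- log-normal library sizes (default mean 2e6, CV 0.2 — desk-scale
  libraries with realistic depth variation);
- differentiation effects on a configurable fraction of genes (default
  15% up, 15% down at $|\log_2 \mathrm{FC}| = 2$), a genotype effect on
  30% of those (random sign), defining the planted four-class truth;
- planted regulator miRNAs (default 20 of 200), half `down_down`, half
  `down_up`, whose *functional* targets are drawn from the `up_up` and
  `up_down` pools respectively so repression reinforces the targets'
  planted trajectories;
- repression coupling through the regulator's standardized latent
  (noise-free) abundance — not the noisy count — so the planted
  anti-correlation strength is controlled by `repression_strength`
  (log2 units per SD, default 1);
- a target map mixing functional edges with decoys (default 25%)
  pointing at unregulated genes, and decoy-only edges for every
  non-regulator miRNA so the map does not leak regulator identity.

All draws derive from one seed in a fixed documented order; identical
configs are bit-identical. What the generator does *not* emulate: batch
effects, gene-specific dispersions, isoform structure, correlated gene
modules beyond the planted repression, or miRNA-specific library
chemistry. Green tests therefore certify the statistical machinery and
its calibration under the stated model, not robustness to every
property of real libraries.

## Numerical choices and degenerate inputs

- Equalization rounds half-to-even; the conditional enumeration uses
  log-space arithmetic normalized by the summed mass.
- Constant expression rows z-score to all-zero and are flagged;
  correlation edges touching them are dropped and counted.
- An all-zero sample is an error for TMM; a sample with no co-expressed
  genes against the reference gets factor 1 with a warning.
- Empty trajectory classes are emitted with `NA` summaries and a
  warning; no candidate regulators yields an empty enrichment table,
  not an error.
- z-scores use the sample (n-1) standard deviation.

## Validation scale and calibration

The test suite validates against independent oracles: a step-by-step
trimmed-mean implementation for TMM (1e-9), brute-force conditional
enumeration via `dnbinom` for the exact test (1e-9, totals <= 200), an
explicit hypergeometric tail sum for Fisher (1e-12), and full $2^n$
sign-pattern enumeration for the Wilcoxon exact branch (1e-12,
$n = 5..12$). Calibration runs use 20,000 genes (global null, both
contrasts) and a 2,000-miRNA decoy map — sizes chosen so the whole
suite completes in a few minutes on one CPU — and require empirical
false-positive rates in [0.03, 0.07] at nominal 0.05. Recovery runs the
full pipeline at the generator defaults (5,000 genes, 200 miRNAs, 20
planted regulators, 3 replicates).

## Known limitations

- With the realistic abundance spread (sdlog 1.8), planted effects land
  on some genes whose counts are too low for the exact test at
  $n = 3$ to detect, and on some below the expression filter entirely.
  Four-class recovery of planted genes is therefore ~85% overall
  (~88% among genes passing the filter) even at
  $|\log_2 \mathrm{FC}| = 2$: a power property of the fixed-dispersion
  exact test under the configured abundance distribution, not a
  classifier defect. Regulator recall/precision are unaffected
  (miRNA libraries concentrate counts on far fewer features).
- The fixed dispersion is an analysis *assumption*; when the true
  dispersion differs from 0.1 the test is mis-calibrated by design,
  and no tagwise estimation is offered.
- Equalization-by-rounding perturbs very small counts; the global-null
  calibration bounds the practical effect.
- The nomination rule tests each miRNA marginally; correlated targets
  (shared regulation) violate the signed-rank independence assumption
  and the raw-p threshold makes no family-wise claim.
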