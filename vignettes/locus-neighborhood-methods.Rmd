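---
title: "Models and methods behind locusecho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind locusecho}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusecho)
```

`locusecho` quantifies how strongly a focal gene's transcription echoes
through its genomic neighborhood, and what happens to that neighborhood
when the locus is engineered. This vignette explains the models, the
tunable parameters, the synthetic-data generator that underwrites the test
suite, and the numerical and design choices a maintainer would want to
know about.

## The neighborhood model

A locus is described by gene *rank order* along a chromosome, not by
strand or sequence. For a focal gene the package extracts up to `k`
neighbors per side (`neighborhood()`, default `k = 3` — the width over
which flanking shading is typically drawn in locus maps; it is a plain
argument, not a constant). Distances are midpoint-to-midpoint in bp:
symmetric under strand and gene length, and antisymmetric between the two
members of a pair. When a chromosome carries a centromere feature, each
neighbor is labelled *centromeric* or *telomeric* according to whether it
lies closer to or farther from the centromere than the focal gene;
otherwise the labels degrade gracefully to *left*/*right* so the type
stays total.

Coordinates are stored 1-based inclusive, the GFF3 convention, end to end.
Because every distance is computed between midpoints, the choice of
convention cancels; keeping the on-disk convention in memory avoids a
lossy boundary conversion in a tidy tabular container.

## Co-expression and its decay with distance

For each neighbor the package computes the Pearson product-moment
correlation between the focal and neighbor expression series
(`pcc()`), separately within each *condition block* — one stressor time
series (heat shock 25→37 °C, 29→33 °C, 30→37 °C, H~2~O~2~, menadione at
two doses, diamide, DTT, hyper- and hypo-osmotic shock) or the
synchronized cell-cycle course. Correlating within blocks matters:
condition-specific mean shifts would otherwise masquerade as
co-expression when samples are pooled.

Missing values are handled by pairwise complete-case deletion with a floor
of 3 complete pairs; below the floor, or on a zero-variance series, the
correlation is *undefined* and propagated as `NA`, never coerced to 0.
Self-comparison returns exactly 1. The locus-average PCC is the unweighted
arithmetic mean over the focal-vs-neighbor entries (a Fisher-z mean is
available via `method = "fisher_z"` for users who prefer variance
stabilization; the plain mean is the default because it is the common
convention for summarizing a handful of correlations).

Condition heatmaps (`condition_heatmap()`) keep rows in genomic order —
the biology is positional, so rows are never clustered — and reorder
columns by average-linkage agglomerative clustering on the Euclidean
distance between block PCC vectors. Average linkage on Euclidean distance
is the workhorse default for condition clustering; only the column *order*
enters downstream output, so the choice is cosmetic beyond tie behavior.
Cells with |PCC| > 0.5 are flagged as strong relationships, the
conventional threshold for calling a tight positive transcriptional
relationship in this kind of analysis.

## The decay model

Correlation as a function of distance is summarized by

$$\rho(d) = c + a\,e^{-|d|/\lambda}$$

with amplitude $a$ (excess correlation of immediate neighbors), decay
length $\lambda$ (bp; the distance over which the excess falls by a factor
of $e$) and baseline $c$. An exponential with offset is the simplest
monotone decay consistent with observed neighbor co-expression curves, and
it matches the synthetic generator's kernel exactly, which makes parameter
recovery a well-posed test. A power-law alternative
$\rho(d) = c + a(1+|d|/1\mathrm{kb})^{-b}$ sits behind `model = "power"`
for users who prefer heavy tails; nothing downstream depends on the
choice.

Fitting is multistart nonlinear least squares (`minpack.lm::nlsLM`) with
$\lambda$ initialized at 1, 5 and 25 kb — neighbor correlations rarely
have enough curvature to tolerate a single bad start — and bounded to
$[100\ \mathrm{bp}, 10\ \mathrm{Mb}]$ for numerical stability on
near-flat data. The best-RSS start wins. Two guards produce a *flat*
verdict (`a = 0`, `c = \bar\rho`, `flat_flag = TRUE`): the 95% confidence
interval of $a$ covering zero, and the decay model failing to beat the
flat model's RSS. Degenerate inputs (fewer than 4 points or fewer than 3
distinct $|d|$) are rejected up front; sign of distance is discarded, so
upstream and downstream neighbors constrain one curve.

## The synthetic-data generator

Every stage is tested against `simulate_genome()`,
`simulate_expression()`, `simulate_qpcr()` and `simulate_growth()`, which
share one principle: the generating parameters are the quantities the
analysis is supposed to recover.

- **Genomes**: exponential gene lengths (mean 1.5 kb) and intergenic gaps
  (mean 0.5 kb) — the scale of the *S. cerevisiae* gene density — with
  random strands and one centromere per chromosome.
- **Expression**: per chromosome, samples are multivariate normal with
  correlation $c_0 + a_0 e^{-d/\lambda_0}$ on midpoint distance;
  chromosomes are independent; each condition block adds per-gene mean
  shifts (SD `block_shift_sd`, default 0.25) emulating block-specific
  regulation. If an unusual spacing makes the assembled matrix indefinite
  it is repaired by nearest-PSD projection (`Matrix::nearPD`) with a
  message. The marginal SD is `noise_sd`; correlations are
  scale-free, so tests are insensitive to it.
- **qPCR**: reference-gene Ct constant in expectation across strains;
  target Ct offset by $-\log_2(\text{fold})$ relative to the calibrator;
  Gaussian cycle noise (default SD 0.1 cycles, typical for technical
  replicates); optional melt-curve failures.
- **Growth grids**: a control score profile that declines linearly with
  dilution step from 0.9 (kept off the score bounds so clamping the
  additive Gaussian noise, SD 0.05, does not bias means), and a stressed
  profile equal to the control profile scaled by the strain's relative
  fitness — zero fitness yields exactly zero scores.

What the generator does *not* emulate: microarray probe effects, dye bias,
normalization artifacts, amplification-efficiency drift, or plate imaging.
Passing tests therefore demonstrate that the estimators recover the
parameters of a clean generative model, not that they are robust to
platform-specific artifacts in archival compendia — on real data the
correlations inherit whatever preprocessing the deposited matrices had.

## Growth and qPCR statistics

A spotting-assay replicate is scored per dilution step in $[0,1]$; the
growth index is the plain sum, so it is bounded by the number of steps and
monotone in every spot. Relative growth is the ratio of mean stress to
mean control index, undefined (never 0) when the control index is zero.
Mutant-vs-WT comparisons use the two-sided Student's *t* test with pooled
variance at $\alpha = 0.05$ and no multiple-testing correction — matching
how such screens are conventionally reported — with Welch's correction
available via `var_equal = FALSE`. Technical replicates are averaged into
biological replicates before testing to avoid pseudo-replication.

qPCR quantification follows the classic 2^−ΔΔCt^ scheme: replicate Cts are
averaged on the Ct scale, ΔCt is target minus reference (*ACT1* by
default), ΔΔCt subtracts the calibrator strain, and the fold change is
$2^{-\Delta\Delta Ct}$ under the canonical efficiency-2 assumption (an
`efficiency` argument generalizes this). Fold SEM is delta-method
propagated from replicate Ct variability including the calibrator's.
Between-strain comparisons are *t* tests on replicate-level ΔCt (i.e.
log~2~ folds), because folds are log-normal under Gaussian Ct noise.
Identical constant replicate groups return $t = 0$, $p = 1$ exactly — the
textbook limit that `stats::t.test` refuses on zero variance.

## Synteny calls

Cross-species gene orders arrive as flat "pillar" exports: per species,
rank, gene id and homology family. The reference species' genes around the
anchor define the columns; a species' column is *present* when a homolog
of that family occurs in its list and survives the longest
order-consistent chain (computed forward and reversed, so calls are
orientation-agnostic), *lost* otherwise. Genes falling between two
adjacent present columns that belong to no column family are counted as
insertions attributed to the gap after the earlier column. A reconstructed
ancestor is just another species row. Homology inference itself is out of
scope — families are inputs.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data. The decay-recovery study fits
the full $(a_0, \lambda_0, c_0) \in \{0.8, 0.4\} \times \{2, 5, 25\ \mathrm{kb}\}
\times \{0, 0.1\}$ grid with 50 seeded replicates per combination, each on
an 81-gene array (~1.4 kb median spacing, so the ±40-rank window spans
roughly twice the largest $\lambda$) with 8000 samples. Those sizes were
chosen by power analysis: the window must resolve both the steepest decay
(points inside $\lambda = 2$ kb) and the shallowest (enough reach past
$\lambda = 25$ kb to pin the baseline), and per-point PCC noise
($\approx 1/\sqrt{n}$) must be small against the ±0.1 amplitude
tolerance. Type-I calibration uses 1000 null trials; kernel-convergence
checks use 2000-sample draws. The full suite and the acceptance script
each run in minutes on a single CPU.

## Known limitations

- The locus-average PCC reproduction on the archival cell-cycle compendium
  requires a user-supplied series-matrix export (see the README); the
  package ships no downloader.
- The published growth magnitudes of locus screens are not numerically
  reproducible because the original per-spot quantification metric is
  unspecified; growth comparisons here are exact about their own score
  semantics but map to published figures only qualitatively.
- Packaged *S. cerevisiae* coordinates are order-preserving
  approximations adequate for rank-order neighborhoods, not a substitute
  for a current genome annotation.
- Decay fits assume a single monotone component; loci whose correlation
  structure is non-monotone (e.g. a strong distal partner) will be
  summarized by the flat guard rather than a spurious $\lambda$.
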