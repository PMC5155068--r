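---
title: "Detecting Dam methylation from SMRT kinetics: models and choices"
author: "damscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Dam methylation from SMRT kinetics: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damscan)
```

## The measurement model

SMRT sequencing records an interpulse duration (IPD) for every nucleotide
incorporation. A methylated template adenine (6mA) delays incorporation of
the complementary thymine, so reads crossing a methylated GATC adenine show
systematically larger IPDs than reads crossing the same position
unmethylated. Raw IPDs are positive, heavily right-skewed, and contaminated
by rare extreme values (instrument pauses), which motivates the three
preprocessing steps this package applies in fixed order:

1. **Outlier removal on the raw scale.** Raw IPDs greater than 50,000 are
   discarded. The cutoff is applied before any transform.
2. **Coverage filter.** A (site, sample) cell enters the analysis only with
   at least 20 kept observations; the threshold is inclusive and applied
   per stranded site per sample. A site excluded in one sample can still be
   tested in others, but temporal tests require presence at all seven time
   points.
3. **Box-Cox normalization and centering.** The shifted-power transform
   `IPD_t = ((IPD + α)^λ − 1)/λ` with the shipped pair α = 0.311,
   λ = 0.151 brings the distribution close to normal; `|λ| < 1e-8` falls
   back to the exact log limit. Each sample's transformed values are then
   centered by subtracting that sample's grand mean over all assessed
   reference positions.

Two readings of the centering step are possible: one offset per sample, or
one offset per reference position. Per-position centering would subtract the
cross-sample mean at every site and thereby null the very signal the
detection step tests (a site methylated in all samples would be centered to
zero everywhere), so this package centers per sample. This is also why the
synthetic generator emits non-motif background adenines (below): in real
data the grand mean is anchored by the vast excess of non-GATC adenine
positions, and an all-GATC table would otherwise center its own signal away.

## Detection against a biological negative control

Per site and sample, the centered transformed values are compared with the
*dam*-mutant control's values at the same site — a biological null
distribution, in contrast to in-silico kinetic reference models. Two tests
run in parallel:

- **Welch t** (unequal variances, Welch–Satterthwaite df, two-sided).
  Welch rather than pooled-variance Student because coverage and variance
  differ between samples and control.
- **Wilcoxon rank-sum**, exact when the combined n ≤ 25 without ties,
  otherwise normal approximation with mid-rank tie correction and
  continuity correction. Rank tests are invariant under the monotone
  Box-Cox map, so raw and transformed values give identical p-values (a
  property the test suite asserts).

q-values are assigned per sample cohort and per method by Storey's method,
and `detected` means q below the FDR threshold (default 0.05). The FDR pass
is per sample cohort; output metadata records this scope. Sites not
significant in the primary pass can be re-tested under coverage
equalization — the larger group subsampled to the smaller's n (or both
bootstrapped at equal n), with the median p over seeded resamples reported.
The equalized p is a confirmatory column: re-calling detections outside the
FDR pass would break its error control, so the final call stays with the
cohort q-value.

## Temporal change, Storey q-values

Changes across the time course (8, 16, 24, 48, 72, 96, 120 h) are tested
per site by one-way fixed-effects ANOVA on centered transformed values and
by Kruskal–Wallis on raw values. π0 is estimated by the smoother method:
π0(λ) = #{p > λ}/(n(1 − λ)) on λ ∈ {0, 0.05, …, 0.90}, smoothed by a cubic
smoothing spline (df = 3), evaluated at λ = 0.90 and clamped to (0, 1].
With π0 = 1 the q-values coincide exactly with Benjamini–Hochberg adjusted
p-values, which the tests use as an oracle. Both thresholds used in
practice (0.05 strict, 0.3 exploratory) are supported; sites missing any
time point are excluded and listed rather than silently dropped.

## IPD-ratio patterns

For sites selected at q < 0.3, the package builds the sites × time points
matrix of IPD ratios — mean raw sample IPD over mean raw *dam* IPD at the
same position, so 1 means no kinetic shift. Ratios use raw values because
centered Box-Cox values can be negative, which would make a ratio
ill-defined. Rows are clustered on Euclidean distances with Ward's
minimum-variance criterion (`ward.D2` convention; the greedy merge sequence
is verified against a brute-force minimum-ESS-increase oracle in the test
suite), cut at k = 4, and each cluster centroid is scored against four
shape templates:

- **A** — stable between 8 and 16 h, then a gradual monotone increase;
- **B** — high early plateau, net decline from 24 to 72 h, recovery by 120 h;
- **C** — single peak at 72 h;
- **D** — maxima at 24 h and at the end of the course, with a dip near 72 h.

Labels are assigned by the one-to-one matching that maximizes the total
shape score (all 24 permutations enumerated). Template-based labeling is an
artifact decision — the four patterns are descriptive classes, and with
fewer (or more) than four clusters the function degrades gracefully with a
warning rather than failing.

## Enrichment and orthogonal assays

Significant sites map to a gene when inside its span, else to a gene whose
start lies within a configurable upstream window (default 300 bp; a site in
a divergent promoter may map to two genes). Term enrichment is flat
membership tested by Fisher's exact test; the threshold is raw P < 0.1 with
no multiple-testing correction, matching how such term tables are
thresholded, and the universe defaults to all annotated genes (this choice
changes p-values and is recorded in output metadata). Both the two-sided
(point-probability) p and the one-sided enrichment tail are available.

LC-MS quantification computes the methylated-adenine fraction
meA/(meA + A) from dilution-corrected peak areas, with Chargaff-ratio
checks ((A+meA)/T and G/C) as signal-response controls and percent CV
(100·sd/mean) per biological sample, propagated across samples by
root-sum-of-squares. qRT-PCR relative expression is 2^ΔCT with each CT
normalized for RNA mass (subtracting log2 of the mass ratio to a reference
mass) and primer efficiency (scaling CT by log2(1 + E); E = 1, perfect
doubling, leaves CT unchanged). These normalization forms are documented
choices — the arithmetic behind "normalized to mass and efficiency" admits
variants — and both default to no-ops under equal masses and perfect
efficiency.

## The synthetic-data generator

The generator defines the study conditions under which the package is
exercised end to end:

- **IPD law**: log-normal in both states — log-IPD ~ N(0, 0.6) for
  unmethylated and N(1.0, 0.6) for methylated adenines. The observation
  model for a site with methylated fraction f is the two-component mixture,
  reflecting that a population of cells carries the site methylated in
  different proportions.
- **Coverage**: Poisson with mean 67, truncated at ≥ 1, matching the
  study's average per-time-point fold-coverage (~67×).
- **Outliers**: with probability 0.005 a read's value is replaced by a
  uniform draw on [50,001, 10^6], exercising the 50,000 cutoff.
- **Controls**: the *dam* control and the WGA control are both fully
  unmethylated (f = 0 everywhere) and differ only in their labels,
  mirroring that both negative controls center at the same place.
- **Background anchor**: four non-motif adenine positions per stranded GATC
  site, unmethylated in every sample, so that per-sample grand-mean
  centering has the unmodified anchor it has in real data (where non-GATC
  adenines outnumber GATC adenines by orders of magnitude; four per site is
  enough to keep the anchor while staying cheap to simulate).
- **Pattern trajectories**: piecewise-linear methylated fractions between
  anchors at the seven default hours, per pattern:
  A 0.15→0.95 rising after 16 h; B 0.90 plateau dipping to 0.20 at 72 h and
  recovering; C peaking at 0.95 at 72 h; D 0.95 at 24 h, dip, 0.90 at
  120 h; constant sites at 0.92. The shapes follow the four described
  pattern classes; the amplitudes were chosen once so that the classes are
  distinct relative to ratio noise at the study's coverage — the patterns
  are presented as visually distinguishable classes, which narrow
  amplitudes (span ≲ 0.5) cannot reproduce at any realistic coverage.
- **Assay simulators**: LC-MS peak areas with multiplicative noise of a
  stated CV around areas consistent with the true meA fraction (equimolar
  T, G, C); qPCR plates whose dam-strain CT is offset by log2(fold) with
  additive Gaussian CT noise.

What the generator does **not** emulate: per-base sequence-context kinetic
variation, read errors, correlated noise along reads, instrument file
formats, and strand-specific coverage biases. Passing tests on synthetic
data therefore demonstrate the statistical machinery — calibration, power,
recovery — under the assumed observation model, not robustness to every
artifact of real SMRT data.

## Numerical and design notes

- **Box-Cox optimization** is a 50 × 50 grid over α, λ ∈ [0.01, 1] followed
  by a Nelder–Mead polish of Σ(skewness² + excess kurtosis²) over samples,
  using the standard moment estimators (g1, g2). The (α, λ) pair is only
  weakly jointly identified when the transformed-scale spread is small —
  α trades off against λ along a near-flat valley — so parameter-recovery
  checks use data with log-scale spread comparable to the IPD generator
  (sd 0.6), where λ recovers within 0.05 at n = 50,000.
- **Motif matching** translates IUPAC codes to character classes with a
  zero-width lookahead for overlapping matches. Genome N is matched only by
  motif N, never by other degenerate codes. Circular genomes are scanned
  with a wrapped prefix so origin-spanning sites are found; duplex
  collapsing (for gap statistics) represents each palindromic duplex by its
  plus-strand modified base.
- **Ties and degenerate input**: both groups entirely constant and equal →
  t = 0, p = 1; constant but different → flagged degenerate, not a silent
  zero; all observations tied in rank tests → p = 1 with a tie flag.
- **Determinism**: every resampling routine takes a seed that is recorded
  in its output; identical config + seed reproduce byte-identical pipeline
  outputs.
- **Problem sizes.** The test suite and acceptance script run the
  calibration at 1,000 sites per replicate (coverage 50, effect 1.5σ for
  power; 200 and 60 replicates respectively for the null false-positive
  rate) and the temporal-recovery conditions at 60 pattern-following plus
  940 constant sites per replicate (50 and 15 replicates respectively),
  sizes chosen to give stable Monte-Carlo estimates on a single CPU.

## Known limitations

- The centering interpretation (per sample, not per position) and the
  qPCR/LC-MS normalization arithmetic are documented choices among
  defensible readings; both are isolated behind single functions.
- Storey's smoother π0 is computed in-package (grid, spline df = 3 as
  above); bootstrap π0 is not offered.
- Temporal tests treat time as an unordered factor; no time-series
  modeling (autocorrelation, splines over time).
- Enrichment is flat term membership; no ontology-graph propagation.
- The pipeline tests stranded sites independently; it does not model
  hemimethylation explicitly (a hemimethylated duplex appears as one
  methylated and one unmethylated stranded site).
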