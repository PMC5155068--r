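# damscan

Genome-wide detection of Dam-mediated N6-methyladenine (6mA) from
single-molecule real-time (SMRT) sequencing kinetics.

## The problem

In *E. coli*, the Dam methyltransferase methylates the adenine of virtually
every 5'-GATC-3' site on both strands. SMRT sequencing measures, per
nucleotide incorporation, an interpulse duration (IPD): the polymerase
pauses opposite a methylated template adenine, so elevated IPDs at GATC
adenines report methylation. Because a single site is either methylated or
not in one chromosome, but a *population* of cells carries a mixture, the
per-site IPD distribution across reads reflects the methylated proportion of
the population — and that proportion can change as a culture moves through
stationary phase, death phase and long-term stationary phase.

`damscan` implements the corresponding analysis as a tested, reusable R
package, for microbiologists and bioinformaticians working with bacterial
methylomes:

- **Motif scanning** — stranded GATC/CCWGG/EcoK (bipartite) site discovery
  on linear or circular genomes, with duplex-collapsed inter-site gap
  statistics (relevant to MutH strand discrimination, which fails only in
  hypomethylated regions longer than ~1 kb).
- **Ingest & filtering** — long-format per-read IPD tables; raw IPDs
  > 50,000 are discarded as outliers; sites need coverage ≥ 20 per sample.
- **Normalization** — the shifted-power Box-Cox transform
  `IPD_t = ((IPD + α)^λ − 1)/λ` with the shipped pair (α = 0.311,
  λ = 0.151), or (α, λ) re-optimized by minimizing squared skewness plus
  squared excess kurtosis across samples; per-sample grand-mean centering
  across all reference positions.
- **Detection** — per site and time point, centered transformed IPDs are
  compared against a *dam*-mutant biological negative control with a Welch
  *t* test and a Wilcoxon rank-sum test; q-values per sample cohort by
  Storey's method; optional coverage equalization by subsampling or
  bootstrap.
- **Temporal change** — one-way ANOVA (transformed values) and
  Kruskal-Wallis (raw values) across the seven time points (8–120 h);
  Storey q-values; selection at FDR < 0.05 and < 0.3.
- **Pattern formation** — per-site IPD ratios (mean sample IPD / mean *dam*
  IPD), Euclidean + Ward hierarchical clustering, a k = 4 cut, and
  shape-template labeling of the clusters as patterns A–D.
- **Enrichment** — site→gene mapping (gene body or upstream window) and
  flat term enrichment by Fisher's exact test at raw P < 0.1.
- **Orthogonal assays** — LC-MS methylated-adenine fraction
  `[meA]/([meA]+[A])` with dilution correction, Chargaff-ratio checks and
  %CV error propagation; qRT-PCR relative expression `2^ΔCT` with RNA-mass
  and primer-efficiency normalization.
- **Synthetic data** — a seeded generator producing genomes with planted
  GATC sites, per-read IPD mixtures whose methylated fraction follows
  pattern trajectories over the time course, *dam*/WGA control samples,
  coverage and outlier structure, and LC-MS/qPCR tables, so the entire
  pipeline is testable without any download.

## Worked example

Simulate a small study (50 GATC duplexes, 40% of them following a temporal
pattern), detect methylation against the dam control, find temporally
changing sites, and cluster their IPD-ratio trajectories:

```r
library(damscan)

cfg <- sim_config(genome_length = 20000, gatc_count_target = 50, seed = 42,
                  pattern_mix = c(A = 0.1, B = 0.1, C = 0.1, D = 0.1,
                                  constant = 0.6))
sim  <- simulate_timecourse(cfg)
prep <- prepare_analysis(sim$ipd, sim$sites)

det <- detect_methylation(prep$analysis, offsets = prep$offsets,
                          methods = "welch_t")
det$summary[c(1, 8)]
#>    sample_id  method n_tested n_detected
#> 1:     t008h welch_t      100         99
#> 2:       wga welch_t      100          0
```

At 8 h, 99 of 100 stranded GATC sites differ significantly (q < 0.05) from
the dam control — the genome is essentially fully methylated — while the
whole-genome-amplified control, which carries no modifications, yields zero
detections against the dam control.

```r
tm  <- temporal_test(prep$analysis, offsets = prep$offsets)
sel <- select_significant(tm$results, fdr = 0.3)
nrow(sel)
#> [1] 45
head(sel[, c("position", "strand", "F", "p_anova", "q_anova")], 3)
#>    position strand        F      p_anova      q_anova
#> 1:     6010      + 19.16202 5.951099e-20 2.975549e-18
#> 2:    18047      - 19.12675 5.572195e-20 2.975549e-18
#> 3:    12974      - 17.86120 1.173498e-18 3.911662e-17
```

45 sites show temporally changing IPD distributions at FDR < 0.3 (40 are
truly changing in the simulation; the rest are the tolerated false
discoveries at this threshold). Clustering the recovered truly-changing
sites by their IPD-ratio trajectories and labeling the four clusters:

```r
mat    <- build_ratio_matrix(prep$analysis, sel)
labels <- label_patterns(cut_to_patterns(ward_cluster(mat), 4), mat)
table(labels$pattern_label)
#>  A  B  C  D
#> 12 16 10  7
```

Restricted to the truly-changing recovered sites, the confusion matrix
against the simulated truth is diagonal (38/38 correctly labeled):

```r
#>      A  B  C  D
#>   A 12  0  0  0
#>   B  0 10  0  0
#>   C  0  0 10  0
#>   D  0  0  0  6
```

A full run with fixed output layout (BED, TSVs, Newick dendrogram, JSON
manifest) goes through `run_pipeline(pipeline_config(...))`, or the thin CLI
in `inst/scripts/damscan.R`
(`Rscript damscan.R simulate|scan|run ... --seed N`).

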