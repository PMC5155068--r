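Package: damscan
Title: Genome-Wide Dam Methylation Analysis from SMRT Sequencing Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of bacterial N6-methyladenine at
    Dam (GATC) sites from single-molecule real-time (SMRT) sequencing
    interpulse durations (IPDs). Provides IUPAC motif scanning of genomes
    with inter-site gap statistics, ingestion and filtering of per-read IPD
    tables, Box-Cox normalization with moment-based parameter optimization,
    per-site detection against a dam-mutant biological negative control
    (Welch t and Wilcoxon tests with coverage equalization), temporal-change
    detection across a time course (one-way ANOVA and Kruskal-Wallis with
    Storey q-values), IPD-ratio pattern clustering (Ward linkage), flat term
    enrichment by Fisher's exact test, orthogonal LC-MS and qRT-PCR
    quantification, and a seeded synthetic-data generator that emulates the
    statistical structure of the assay for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    tools,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
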