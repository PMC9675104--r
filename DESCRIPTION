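Package: methSplice
Title: Pan-Cancer Correlation Analysis of DNA Methylation and Alternative Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for screening associations between CpG
    methylation and alternative splicing across many cancer cohorts.
    Gene expression is binarized with a StepMiner-style one-step fit to
    define gene-specific high-expression cohorts; Pearson correlations
    between CpG beta values and exon or isoform expression are screened
    per cancer with false-discovery-rate control and a minimum-cohort
    rule; CpG-exon pairs significant in several cancers are aggregated
    into consistency scores and rankings; per-CpG log-rank survival
    scans are compared with the exon-correlated CpG set by fold
    enrichment; and direction-matched exon-versus-isoform correlation
    strengths are summarized. A synthetic multi-omics generator with
    planted effects provides a ground-truth test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
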