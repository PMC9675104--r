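---
title: "Screening methylation-splicing associations across cancer cohorts"
author: "methSplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening methylation-splicing associations across cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methSplice)
```

## The analysis

DNA methylation is usually studied as a regulator of transcription, but CpG
methylation inside gene bodies can also track with alternative splicing: the
inclusion or exclusion of individual exons, and through them the usage of
transcript isoforms. methSplice implements a pan-cancer screen for such
associations on array-style methylation (450K-type beta values in $[0,1]$)
and exon/isoform/gene expression quantifications (log-scale, FPKM-like),
organized per gene and per cancer cohort:

1. **Cohort stratification.** For each gene, a one-step (two-level) function
   is fit to the sorted expression values of *all* samples of *all* cancers,
   minimizing the squared error of the two segment means (the StepMiner
   approach). The midpoint of the two means is the gene's global
   binarization threshold; samples strictly above it form the gene's
   *high-expression cohort* within each cancer. Splicing signal is only
   interpretable where the gene is expressed, which is why every downstream
   test runs on these gene-specific cohorts.
2. **Correlation screen.** Within each (cancer, gene) cohort, the Pearson
   correlation $r$ between each associated CpG's beta values and each
   exon's (or isoform's) expression is computed, with the two-sided p-value
   from the $t$ transform of $r$ on $n-2$ degrees of freedom. Cohorts (and
   pairwise-complete sample counts) below 10 are skipped — the minimum-
   patient rule. P-values are adjusted per cancer type and target kind;
   the default is Benjamini–Hochberg at a 5% FDR, with Bonferroni as an
   option, since the screen's significance language is an FDR threshold
   while the correction is applied "per cancer type".
3. **Multi-cancer aggregation.** CpG–exon pairs significant in two or more
   cancers get a *consistency score*: the fraction of their significant
   correlations sharing the majority direction, which by construction lies
   in $[0.5, 1]$. Pairs are ranked by the mean of the absolute values of
   their significant correlations.
4. **Survival scan and enrichment.** For each (cancer, gene, CpG), the
   cohort is dichotomized into methylated/unmethylated by the same one-step
   fit applied to the beta values, and the two groups are compared with the
   one-degree-of-freedom log-rank test (via the survival package), BH-
   adjusted per cancer. The overlap between exon-correlated and
   survival-associated CpGs is compared with the overlap expected under
   independence: with $k$ significant CpG–survival relationships among
   $M \times C$ examined units ($M$ CpGs, $C$ cancers), an exon-correlated
   set of size $m$ expects $m \cdot k/(MC)$ overlaps, and the fold
   enrichment is observed/expected.
5. **Exon-versus-isoform comparison.** For each significant CpG–exon
   correlation, among the isoforms that contain the exon and are
   significantly correlated with the same CpG in the same cancer, the
   strongest correlation *of the same sign* is selected, and
   $\mathrm{diff} = |r_\mathrm{exon}| - |r_\mathrm{isoform}|$ summarized.
   A positive difference means the exon-level association is stronger,
   for either correlation direction.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | adjusted-p significance threshold in both screens |
| `method` | `"bh"` | per-cancer adjustment (`"bonferroni"` available) |
| `minCohort` | 10 | minimum patients per (cancer, gene), after missing-data removal |
| `minGroup` | 2 | minimum size of each methylation group in the survival scan |

Thresholds are unitless; times in the clinical table are in arbitrary but
consistent units (the generator uses an exponential baseline hazard of 0.1
per unit, so a unit is on the order of months for realistic cohorts).

Numerical choices: equal-SSE step splits resolve to the smallest split
index; values exactly at a threshold are labeled low (a conservative high
cohort); constant genes/CpGs produce degenerate fits and are skipped rather
than guessed at; correlations of exactly $\pm 1$ get $p = 0$; zero
correlations carry no sign and are excluded from consistency scoring; |r|
ties among candidate isoforms resolve to the lexicographically smallest
isoform id; an even sign split scores 0.5 and its majority sign is broken
toward the larger summed $|r|$, flagged in the output. Missing beta values
are kept as missing and removed pairwise, with the cohort floor applied
after removal.

## What the generator emulates

`simulateDataset()` plants known structure so every stage can be scored:

* **Bimodal gene expression** — a low mode near 0 and a high mode near 8
  (log2 scale, sd 1), with a fraction `fracExpressed` of samples in the
  high mode, so the step fit recovers mode membership almost perfectly.
* **Beta values** — per-CpG mixtures of methylated/unmethylated states
  (logistic-transformed Gaussians centered at $\pm 1.5$, sd 0.7), giving
  the largely bimodal per-probe distributions of 450K arrays.
* **Planted CpG→exon effects** — for a fraction `fracPlanted` of CpG–exon
  pairs (at most one CpG per exon, so effects never stack), exon expression
  of high-mode samples gains a linear term in beta scaled against the
  empirical spreads so the within-cohort correlation is ≈ ±`effectR`. The
  first cancer carries the pair's base sign; each further cancer keeps it
  with probability `signConsistency`.
* **Exon co-expression** — exons share their gene's high-mode signal
  (offset sd 0.5, residual sd 0.8), reproducing the strong within-gene
  correlation of real exon quantifications; the effective number of
  independent tests per gene is therefore smaller than the pair count, as
  in real data.
* **Isoform dilution** — isoform expression is the mean of its member
  exons plus independent noise (`isoformNoiseSd`), so a planted single-exon
  effect is diluted at the isoform level; means rather than sums keep
  isoforms of different lengths on one scale.
* **Survival coupling** — each sample's exponential hazard is multiplied
  by `hazardRatio` for every *driver* CpG with beta > 0.5, with independent
  exponential censoring. Drivers are drawn among planted CpGs whose
  methylated fraction lies in [0.2, 0.8] — a CpG methylated in almost
  nobody (or everybody) cannot define survival groups — and the default
  driver fraction is small because simultaneous independent drivers act as
  frailty noise for one another, which is also why per-CpG survival
  associations are attenuated relative to the nominal hazard ratio. Setting
  `driversFromPlanted = FALSE` draws an equally sized driver set from
  non-planted CpGs, the independence control for enrichment checks.

Reproducibility: one master seed; each gene uses a substream derived
deterministically from (seed, gene index), so a run is bit-identical and
gene subsets are reproducible.

What the generator does *not* emulate: empirical TCGA beta/FPKM-UQ
distributions, probe-level artifacts, shared methylation structure between
neighboring CpGs, covariates such as tumor purity or age, and non-
proportional survival effects. Passing tests therefore demonstrate that the
pipeline recovers the structural signal it is designed for, not that any
particular biological dataset contains such signal.

## Design choices where the design was open

* **BH by default.** The screen is described by an FDR threshold but the
  correction "per cancer type" could be read as Bonferroni; both are
  implemented, BH is the default because every significance statement in
  the analysis is an FDR statement.
* **Adjustment family** — all tests of one target kind in one cancer,
  pooling genes; exon and isoform families are kept separate.
* **Survival dichotomy** — the same step-fit binarization used for
  expression, applied to the cohort's beta values, rather than a fixed 0.5
  cut; it reuses the pipeline's own machinery and adapts to each CpG's
  beta range. The minimum-cohort rule is extended to the survival scan for
  the same small-sample reason it exists in the correlation screen.
* **Overlap units** — (cancer, CpG) pairs, with the collapsed unique-CpG
  count also reported, since published overlap counts are sometimes quoted
  per CpG site.
* **Matched-isoform differences** are magnitude differences
  $|r_\mathrm{exon}| - |r_\mathrm{isoform}|$, so "positive = exon stronger"
  holds for negative pairs too; CpG–exon records with no direction-
  consistent significant isoform are excluded rather than scored, and the
  distribution is tallied both per (cancer, pair) and per unique pair.
* **Panel stratification** uses average-linkage hierarchical clustering on
  Euclidean distances of beta profiles, cut at two groups — the simplest
  reproducible choice for the two-cluster heatmap-style analysis.

## Problem sizes

The demo configuration — 200 genes × 3 cancers × 60 samples, 22 CpGs and
10 exons per gene (the 450K-scale per-gene averages), 4 isoforms — runs the
full pipeline in about two minutes on one core and yields a few thousand
significant exon correlations. The validation suite scales its Monte-Carlo
checks to that order: 1,000 random vectors for the step-fit oracle, 100
random datasets for the log-rank oracle, 20 null replicates of ~2,000 pairs
for FDR calibration, and 3 replicates each for the consistency, dilution
and enrichment-direction recoveries.

## A short session

```{r demo, eval = FALSE}
cfg <- pipelineConfig(simulate = list(nGenes = 50L), seed = 1L)
res <- runPipeline(cfg, outDir = "run1")
head(res$pairs)                      # ranked multi-cancer CpG-exon pairs
consistencySummary(res$pairs)        # fraction with perfect consistency
res$enrichment$fold                  # survival-overlap fold enrichment
res$comparison$summary$fracPositive  # exon-vs-isoform skew
```

## Known limitations

Correlation screens on heavy-tailed expression can be sensitive to
outliers; no rank-based alternative is provided because the screen is
defined as Pearson's r. No covariate adjustment or Cox modeling is
performed — group comparisons are log-rank only. The enrichment expectation
assumes independence between exon correlation and survival association
across CpGs; correlated CpGs within a gene violate the implicit
independence of units in both the expectation and its Poisson-scale error,
so folds near 1 should be read qualitatively. The published 450K-scale
counts are reproducible only in their self-contained arithmetic; the
genome-wide tallies require the original multi-omics download and are out
of scope.
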