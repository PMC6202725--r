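---
title: "Gene-body methylation analysis for targeted bisulfite sequencing"
author: "tbsmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-body methylation analysis for targeted bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbsmeth)
```

## The problem

Targeted bisulfite sequencing (TBS) combines exome capture with bisulfite
conversion: unmethylated cytosines read as T, methylated cytosines stay C, so
per-site C/T read counts encode methylation at single-base resolution over a
chosen target space — here, gene bodies. The design this package models is a
paired clone study in a long-lived tree: four genets, each consisting of an
*ortet* (the original tree, high elevation) and a *ramet* (its graft, low
elevation), giving eight libraries in which genetic variation is controlled
and methylation differences can be attributed to environment and tree history.

The package implements the full downstream analysis from per-cytosine count
tables: context annotation, weighted methylation with coverage filtering,
capture-efficiency QC, 20-bin metagene profiles, differential methylation
position (DMP) calling with a per-clone-pair consistency filter, PCA of
methylation profiles and GO bias analysis — plus a synthetic-data generator
with the same statistical structure, so every stage is testable without any
external download.

## Cytosine contexts

Every forward-strand C and every forward-strand G (a reverse-strand C) is a
site. The context is a pure function of the two bases downstream on the
site's own strand: CG, CHG or CHH with H ∈ {A, C, T}. Sites with fewer than
two downstream bases on their strand are labelled `unknown` and excluded from
all statistics rather than guessed; an N at a context-determining position
also yields `unknown`, but the third base is irrelevant once the second is G
("CGN" is CG). Symmetric CpG sites are never merged across strands: the
pipeline consumes and reports per-strand counts throughout.

Internally all containers are `GRanges`/`RleList` (1-based, closed
intervals); conversion to the 0-based half-open conventions of BED and
bedGraph happens in one place, the rtracklayer I/O boundary, so off-by-one
drift cannot accumulate.

## Weighted methylation, filtering, conversion rate

The per-site methylation level is the read-weighted estimate #C/(#C+#T).
Sites are retained when coverage lies in the closed interval [8, 100]
(defaults of `filterConfig()`): at least 8 reads for a stable estimate, at
most 100 to discard collapsed-repeat pileups. The filter is per library;
every cross-library analysis (PCA, DMP calling) uses only positions passing
in *all* libraries.

The bisulfite conversion rate is estimated from an unmethylated lambda
spike-in as the read-pooled proportion of converted reads,
sum(#T)/sum(#C+#T). Pooling reads (rather than averaging per-site rates)
matches the arithmetic of standard extractor reports; the per-site average is
available via `pool = FALSE` and coincides with the pooled value when
coverage is balanced.

## The synthetic-data generator

`simConfig()` defaults *are* the emulated study conditions: 4 genets (8
libraries), genes with three exons and three probe regions (the archetype
gene of the capture design), per-context mean gene-body methylation of 21.3 %
(CG), 11.0 % (CHG) and 1.3 % (CHH), negative-binomial per-base coverage with
mean 30 and size 5, a 99.5 % conversion rate, and an unmethylated lambda-like
spike-in.

Design choices worth recording:

* **Per-site truth** is Beta-distributed with the context mean and a
  concentration parameter (default 20). The concentration is a knob because
  only the context means are pinned down by the emulated study; 20 gives a
  realistic unimodal spread (for CHH the mode sits at 0, as in real plant
  data). `Inf` collapses the Beta to the mean exactly — used by tests.
* **Non-conversion inflates apparent methylation**: an unmethylated C fails
  to convert with probability 1 − conversion rate and then reads as
  methylated; methylated Cs never convert. Sequencing errors are not
  modelled, matching how conversion rates are estimated from spike-ins.
* **DMP planting**: a fraction of eligible (genic, known-context) sites gets
  the ramet truth shifted by ±0.35. Signs are balanced among sites where
  both directions stay inside [0, 1]; a site where one direction would be
  clipped to nothing receives the feasible sign instead. A strictly balanced
  assignment would silently erase about half the planted effects at
  low-methylation sites (truth − 0.35 clips to 0, leaving a difference below
  the 25-point call threshold), which would make planted-DMP recall
  meaningless as a calibration check.
* **Coverage is independent per base and library** (capture-coverage
  autocorrelation is out of scope), drawn over the captured space — gene
  bodies ± 1 kbp plus the lambda sequence — and zero elsewhere, so
  coverage tracks and count tables are consistent by construction.
* **Per-genet biological noise** is available (`genetNoiseSd`) but off by
  default: clonal pairs share a genet baseline, and the emulated study
  provides no estimate of within-genet noise to calibrate against.
* Reads are never simulated (no FASTQ/alignment); the generator produces the
  post-alignment artefacts the pipeline consumes (cytosine reports,
  bedGraphs, FASTA/GFF3/BED).

All randomness flows from one root seed through fixed per-stage sub-seeds
(reference, truth, counts), so adding a stage never perturbs earlier draws
and equal seeds give byte-identical output files.

What passing tests on these simulations do *not* show: robustness to capture
bias along probes, PCR duplicates, M-bias, SNP-induced context errors, or
spatially correlated methylation — none of which the generator emulates.

## Capture QC

`thresholdCurve()` reports, for thresholds 1–100, the proportion of
probe-region (or gene-body) base pairs covered by at least t reads; the
complementary per-feature summary (`featureCoveredFraction()`) reports the
fraction of features with any covered base. Both styles are emitted because
capture reports conventionally quote both. `libraryOverlap()` intersects the
per-library sets of genes with mean coverage ≥ 10× and reports the
intersection as a percentage of the reference gene list;
`flankCoverage()` counts covered flank base pairs strand-aware, quantifying
how thin the off-target rim around gene bodies is.

## Metagene profiles

Each gene body (introns included — bins are defined on the genomic span, not
concatenated exons) is split into 20 bins ordered 5′→3′ in transcription
direction; when the length is not divisible by 20 the first `length mod 20`
bins are one bp longer. A bin is retained iff its mean per-bp depth lies in
[8, 100] *and* it contains at least one call of the target context (a 0 %
call counts). Bin values average the site percentages unweighted by coverage
— "mean methylation percentage per bin" — with a coverage-weighted variant
behind `weightByCoverage`. Libraries are profiled separately and averaged
position-wise; `pooled = TRUE` pools all retained gene-bins instead. The
grand mean over the 20 bins and all libraries is the reported context-level
methylation; on synthetic data with defaults it recovers the configured
context means well within half a percentage point (the acceptance script
recomputes this).

## DMP calling

Per context, counts are pooled within environment and each site is tested
with a two-sided Fisher's exact test on the 2×2 table
[[#C~ortet~, #T~ortet~], [#C~ramet~, #T~ramet~]], implemented vectorised on
the hypergeometric density and verified against exhaustive enumeration to
1e-12. Fisher on pooled counts is the deterministic, oracle-checkable
default; a per-library binomial GLM with environment as covariate is
available (`test = "logistic"`). q-values are Benjamini–Hochberg within
context — a deliberate, documented choice of a reproducible correction over
framework-specific alternatives. A site is a DMP when

1. q < 0.01,
2. |ortet − ramet pooled difference| > 25 percentage points (sign
   convention: ortet minus ramet, i.e. high minus low elevation), and
3. every clone pair individually differs by > 10 points in the direction of
   the group difference — the consistency filter that makes four genets
   informative despite the tiny sample.

`dmpSummary()` prints the per-context table of analysed positions, DMPs
passing (1)+(2), and consistency-filtered DMPs. On null simulations (no
planted shift, perfect conversion) the consistency-filtered count is ~0; with
a planted 0.35 shift at coverage ~60× recall exceeds 0.8.

## PCA and GO bias

PCA operates on the libraries × sites percentage matrix of each context
(complete cases by the all-libraries filter), centred but not scaled —
percentages share a scale. PC signs are fixed by making each component's
largest-magnitude loading positive. The site-level matrix is the primary
input; profiling the retained metagene bins instead would also be defensible,
but sites retain the most information and feed the same variance-explained
summaries.

GO bias uses hypergeometric upper (enrichment) and lower (depletion) tails
per term, direction = the smaller tail, BH within namespace. The universe is
the annotated reference genes only (unannotated genes carry no information on
term bias), terms need ≥ 3 universe genes, and no ancestor propagation is
performed — annotation is taken as provided. DMPs are assigned to genes via
the gene span ± 1 kbp, matching the mapping reference of a gene-body capture
design; `simulateGoAnnotation()` provides clearly-labelled synthetic
annotations for end-to-end runs.

## Numerical and scale choices

* Fisher p-values use the standard two-sided convention (sum of table
  probabilities ≤ observed × (1 + 1e-7)).
* Degenerate inputs: zero-coverage sites are an error for
  `weightedMethylation()` and NA in `methLevel()`; genes shorter than 20 bp
  are excluded from binning with a warning; a constant matrix gives zero
  variance and zero scores in PCA; an empty region set is an error for
  threshold curves.
* Problem sizes: the packaged tests run simulations of 3–8 genes on single
  small scaffolds (seconds each), the type-I check uses 10 seeds of a
  4-gene design, and the acceptance script uses 200 genes × 1.5 kbp over
  four scaffolds with 8 libraries at 30× — large enough that the grand-mean
  recovery operates on > 10^5 reads per context, small enough to run on a
  laptop core in well under a minute.

## An end-to-end run

```{r, eval = FALSE}
cfg <- pipelineConfig(sim = simConfig(nGenes = 80), outdir = "tbs-demo",
                      seed = 1)
res <- runPipeline(cfg)
res$dmpSummary
metageneGrandMean(res$metagene)
```

`runPipeline()` writes every stage's table plus a manifest (package version,
seed, configuration hash, per-stage row counts); reruns with the same
configuration are byte-identical, timestamps appear only in messages. The
exported stage functions are the interface for scripted use; there is no
shell wrapper because the natural entry point for this audience is R itself.

## Known limitations

* The Fisher default ignores within-group replicate structure (counts are
  pooled); the logistic alternative uses replicates but is slower and not
  oracle-checkable.
* Conversion-rate pooling style and metagene averaging order
  (per-library-then-average) are conventions; both alternatives are
  implemented behind flags, and on balanced designs the differences are
  negligible.
* The generator's independence assumptions (coverage per base, truth per
  site) make the synthetic data cleaner than real capture data; calibration
  results transfer to real data only to the extent those assumptions hold.
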