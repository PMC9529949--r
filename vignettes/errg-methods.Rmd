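---
title: "Identifying eRNA-regulated genes and contrasting risk groups: methods"
author: "errg package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying eRNA-regulated genes and contrasting risk groups: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Enhancers are distal DNA regulatory elements; active enhancers are
transcribed into enhancer RNAs (eRNAs), and genes whose bodies fall in
the same self-interacting genomic neighbourhood (a *contact domain*,
median length about 185 kb) as an eRNA locus are plausible regulatory
targets. `errg` implements a reproducible, testable pipeline that
(i) nominates eRNA-regulated genes (eRRGs) from several independent
enhancer annotation resources, and (ii) contrasts two sample groups —
tumor against normal for expression, and high- against low-risk (from a
gene-signature risk score) for expression, DNA methylation, somatic
mutations and overall survival.

## The identification model

For every enhancer record the **eRNA region** is the window of
`halfWidth` bp (default 3000, i.e. a ±3 kb window) on either side of the
enhancer midpoint. All coordinates are 0-based half-open internally
(converted exactly to the 1-based closed `GRanges` convention in
memory); the midpoint of `[s, e)` is `floor((s + e) / 2)`. Only the
chromosome start is clamped — chromosome sizes are deliberately not
consulted, since none of the supported input formats carries them
reliably.

Regions with ≥1 bp overlap with *any* annotated gene (any biotype,
either strand) are discarded: an eRNA candidate lying inside a known
gene cannot be distinguished from ordinary transcription. Overlap is
strand-agnostic throughout, since enhancer activity is not strand
resolved.

Each surviving region is then given a **contact-domain window**: a
window of total length `domainLength` (default 185,000 bp) centred on
the region midpoint. The published notion of a contact domain does not
fix a window geometry; we chose a symmetric fixed-length window centred
on the eRNA midpoint, assigned on ≥1 bp overlap with the gene body, as
the most parameter-light operationalization consistent with the median
domain length. `domainLength` is exposed as an argument everywhere.
Genes overlapping the window are that eRNA's eRRGs.

This is run per enhancer resource, and the **final eRRG set is the
intersection of the per-resource gene sets** (gene-level intersection:
the same gene must be nominated by every resource, not necessarily from
the same eRNA locus — the per-locus alternative would require matching
enhancer records across databases, which the inputs do not support).
Overlapping enhancer records within one resource are kept as-is;
duplicate (region, gene) pairs collapse only at the gene-set level.
Consequences asserted by the test suite: the final set is monotone
non-increasing in the number of resources and non-decreasing in
`domainLength`, and removing a gene from the annotation can only remove
assignments or rescue previously filtered regions, never add a pair.

## Downstream statistics

**Mean/CV contrast.** Per-gene mean and coefficient of variation
(CV = 100·sd/mean, sample sd, undefined and flagged at zero mean) are
computed on the expression unit supplied. `compareToRandomSets()` draws
seeded size-matched random gene sets from a configurable universe
(default: all genes passing the "expressed in at least one sample"
filter), pools the per-gene values of all draws, and compares eRRGs to
the pool with a Wilcoxon rank-sum test. Pooling (rather than averaging
per set) was chosen so the null reflects gene-level variability; the
per-set alternative is a one-line change and is noted here for clarity.

**Wilcoxon rank-sum.** Exact two-sided p by the permutation
distribution of the rank sum when the pooled size is ≤ 12 with no ties;
otherwise a normal approximation with midranks, tie correction and
continuity correction. The exact path is verified against full
enumeration of all rank assignments, the approximate path against the
standard corrected large-sample test.

**Differential expression.** The built-in stage is a deliberately
simple, self-contained rank test: per gene, Wilcoxon on
log2(CPM + pseudocount), fold change from group mean CPM, BH FDR. It is
a substitute for a negative-binomial GLM DE tool so the pipeline is
testable without external tables; externally computed DE tables with
the same columns can be used instead for real data. Calls use the
strict thresholds FDR < 0.05 and |log2FC| > 1 (both configurable, both
strict inequalities as printed conventions dictate).
`resampleDeCounts()` gives the random-gene null for "how many DE genes
would a random set of this size contain"; its mean is verified against
the hypergeometric expectation.

**Differential methylation.** Per probe Δβ = mean(high) − mean(low)
and a two-sided Welch t-test on beta values with BH adjustment; calls
require FDR < 0.05 and |Δβ| > 0.15 (strict). The Welch t on betas is a
transparent substitute for array-toolkit internals and behaves well at
the planted effect sizes; beta matrices must be complete (impute
upstream). The sign convention is high-risk minus low-risk, so
"hypomethylated in high-risk" is Δβ < −0.15.

**Somatic mutations.** Gene × sample mutation status is binary;
`Silent` records do not qualify by default (`includeSilent` flips
this — the choice of qualifying classes is a judgement call, so it is a
flag). SNVs are collapsed to the six pyrimidine-reference substitution
classes, purine-reference records mapped through the reverse
complement. Differential mutation uses Fisher's exact test per gene on
the mutated/not × high/low table, restricted to genes with at least
`minMutated = 5` mutated samples (avoids degenerate tables; exposed as
a flag), and calls at raw p < 0.05 — unadjusted, as conventional for
this screen; a BH column is emitted alongside for transparency.
Co-occurrence tests each pair of the top-K most frequently mutated
genes on the both/only-i/only-j/neither table, two-sided, labelling by
odds-ratio direction (OR > 1 co-occurring, otherwise exclusive).
Because Fisher's test is exact on discrete tables it is conservative:
under a null of equal rates the fraction of genes rejected at p < 0.05
sits at or below 0.05, which is what the calibration tests assert.

**Risk score and survival.** The risk score is the plain linear
predictor Σ coefficient~g~ · expr~g~ with coefficients supplied as
input (model fitting — Cox, lasso, cross-validation — is out of scope
by design); expression units must match the coefficients' training
units and are the caller's responsibility (the pipeline scores
log2(count + 1)). The median split sends scores strictly above the
median to `high`; ties at the median go to `low`, preserving
"high = strictly above the median" (for an even sample count the median
is the midpoint of the two central order statistics, so with distinct
scores the split is exactly 50/50). Kaplan–Meier curves come from the
product-limit estimator and the two-group comparison from the standard
log-rank test (O − E with hypergeometric variance per event time,
χ² with 1 df); both are verified against hand-computed oracles,
including the worked four-subject example with χ² = 49/17 ≈ 2.882.

## The synthetic-data generator

`simulateErrgStudy()` emulates every input of a multi-omics tumor
cohort study so the whole pipeline is testable without downloads:

* **Annotation** — non-overlapping genes on a jittered regular grid
  (non-overlap keeps the planted truth unambiguous); "shared" enhancers
  present in all resources, placed in gene-free gaps so their eRNA
  regions survive the overlap filter with genes nearby in the domain
  window; "resource-private" enhancers, half placed on genes (exercising
  the filter), half in gaps kept at least a domain length away from
  other resources' private gaps so they never reach the all-resource
  intersection. Ground truth is derived by an internal all-pairs scan
  that shares no code with `identifyErrgs()` — the pipeline-level
  oracle test asserts exact equality on every generated bundle.
* **Expression** — negative-binomial counts with log-normal baseline
  means; planted eRRGs get a higher baseline (driving the mean/CV
  contrast: for a negative binomial, CV falls as the mean rises at
  fixed dispersion) and a subset of them planted ±log2FC between tumor
  and normal.
* **Methylation/mutations** — truncated-normal betas on [0, 1] (exact
  inverse-CDF truncation, not clamping) with planted Δβ probes, half
  hypo- and half hypermethylated in the high-risk group; mutation
  records drawn per gene and sample at configured rates with a
  configurable Silent/indel/SNV-class composition and VAF ~ U(0.05, 0.9).
* **Survival** — exponential event times with hazard
  `baselineHazard · exp(lp)` where `lp` is the standardized planted
  risk score times `survivalEffect`; a seeded Bernoulli
  (`censorFraction`) subset of samples is censored at a uniform
  fraction of its event time, giving the configured expected censoring
  fraction with uniform censoring times.

The risk-group truth is the generator's own median split of the planted
signature score (computed with its own order-statistic code), so the
pipeline's recomputed groups can be checked for exact equality.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: realistic TAD structure or
enhancer–gene distance distributions, overlapping/nested gene models
(a separate stress fixture covers overlap handling), batch effects,
tumor purity, methylation probe design biases, mutation signatures
beyond a global class mix, and non-proportional hazards.

## Sizes, seeds and numerical choices

The demo configuration runs 2 chromosomes × 10 Mb, 500 genes (60%
protein-coding), 90 enhancers per resource across four resources (2/3
shared), 200 tumor + 32 normal samples, 3000 probes with 100 planted
DMPs (Δβ = 0.3, sd = 0.05), 10 planted differentially mutated genes
(rates 0.4 vs 0.05 against a 0.08 background), and a 12-gene planted
signature; the full pipeline completes in well under a minute. These
sizes were chosen once as a desk-scale emulation of a TCGA-style
cohort. Every random draw is governed by a single config seed from
which each sub-generator derives its own stream; no function touches
the caller's RNG state, and regeneration from an identical config is
byte-identical.

Numerical conventions worth knowing: floored midpoints for even-length
enhancers; `domainLength %/% 2` on each side of the midpoint; strict
inequalities at every published-style threshold; Fisher's two-sided p
sums hypergeometric probabilities ≤ the observed one with the standard
1 + 1e-7 relative tolerance; BH is the step-up rule; co-occurrence ties
at OR = 1 fall to "exclusive"; degenerate zero-variance probes get
p = 1 when the group means agree and p = 0 otherwise; all-identical
risk scores are an error (no split exists) rather than an arbitrary
assignment.

## Known limitations

The contact-domain window is fixed-length and symmetric — locus-specific
domain boundaries (e.g. from Hi-C) would be strictly better and are out
of scope. The built-in DE and DMP tests are transparent substitutes,
not reimplementations of negative-binomial or array-specific
machinery. Coordinate lift-over is not provided: all inputs must
already share one assembly. The survival stage consumes fixed
coefficients; no fitting, time-dependent ROC or nomogram is included.
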