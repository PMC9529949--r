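# errg

Identification of enhancer RNA (eRNA) regulated genes and downstream
multi-omics group contrasts, as a tested, reproducible R package.

## The problem

Active enhancers are transcribed into eRNAs, and genes lying in the same
self-interacting genomic neighbourhood (*contact domain*, median length
~185 kb) as an eRNA locus are candidate regulatory targets (eRRGs —
eRNA-regulated genes). Nominating them robustly, and then asking how
they behave across tumor/normal and prognostic risk groups, requires a
chain of small, well-defined genomic and statistical operations that
are easy to get subtly wrong (coordinate conventions, half-open
overlaps, strict thresholds, exact tests). `errg` packages that chain
for analysts working with enhancer annotations, RNA-seq counts,
methylation beta values, somatic mutation tables and survival data.

## The method

For each enhancer resource *r* and each enhancer with interval
[s, e) (0-based half-open):

1. **eRNA region**: midpoint m = ⌊(s + e)/2⌋, region
   [max(0, m − w), m + w) with half-width w = 3000 bp (±3 kb).
2. **Gene-overlap filter**: regions with ≥1 bp overlap with any
   annotated gene (any biotype, either strand) are removed.
3. **Contact-domain assignment**: a window of total length L = 185,000
   bp centred on m; every gene body overlapping the window by ≥1 bp is
   an eRRG of that eRNA: G_r = { g : gene g overlaps [m − L/2, m + L/2) }.
4. **Intersection**: the final set is ∩_r G_r over all resources.

Downstream, the package provides: per-gene mean and CV
(100·sd/mean) contrasts against seeded size-matched random gene sets
(Wilcoxon rank-sum, exact by enumeration for pooled n ≤ 12 without
ties); a built-in rank-based DE stage on log2 CPM with strict
FDR < 0.05 and |log2FC| > 1 calls and a resampling null for DE counts
in random gene sets; differentially methylated probes by Welch t on
beta values with |Δβ| > 0.15 and FDR < 0.05; per-gene differential
mutation and pairwise co-occurrence/exclusivity by Fisher's exact test;
and a fixed-coefficient linear risk score with median split compared by
Kaplan–Meier and the log-rank test. A synthetic-data generator with
independently derived ground truth makes every stage testable end to
end.

## Worked example

```r
library(errg)

sim <- simulateErrgStudy(simConfig(seed = 11))   # demo synthetic study
asn <- identifyErrgs(sim$enhancers, sim$genes)
asn
#> ErrgAssignment
#>   resources: ensembl, fantom, roadmap, encode
#>   half-width: 3000 bp; contact domain: 185000 bp
#>   ensembl: 90 enhancers -> 75 eRNA regions -> 247 eRRGs
#>   fantom: 90 enhancers -> 75 eRNA regions -> 238 eRRGs
#>   roadmap: 90 enhancers -> 75 eRNA regions -> 237 eRRGs
#>   encode: 90 enhancers -> 75 eRNA regions -> 238 eRRGs
#>   final: 204 eRRGs (129 protein_coding, 75 lncRNA, 0 other)

res <- runErrgPipeline(sim, seed = 3)
```

The summary of that run reads (numbers printed by the code above):

```
eRRG mean 157.0 vs random 72.0 (p = 7.2e-35); CV 53.0 vs 58.3 (p = 1.1e-13)
DE eRRGs: 31 up, 20 down; random sets average 12.72 up, 8.14 down
DMPs: 50 hyper, 50 hypo; 25 differentially mutated genes
log-rank chi-square 63.8 (p = 1.3e-15), groups 100/100
```

Reading: of 500 simulated genes, 204 are nominated as eRRGs by all four
enhancer resources — exactly the generator's planted truth. They show
the planted expression signature (higher mean, lower CV than random
gene sets), carry far more differentially expressed genes than
size-matched random sets (31 + 20 observed vs ≈ 12.7 + 8.1 expected by
chance), and the 100 planted differential methylation probes are all
recovered. The risk-score median split separates survival sharply
(log-rank p ≈ 1e-15), as planted. The 25 differentially mutated genes
are the 10 planted ones plus the expected raw-p < 0.05 background.

`identifyErrgs()` equally accepts file paths: BED3/BED4 per resource,
genes as GTF (gene lines) or the package's 7-column TSV. A thin
command-line wrapper lives in `inst/scripts/errg.R`
(`simulate`, `identify`, `pipeline` subcommands).

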