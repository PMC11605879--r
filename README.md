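# ThanatoSeq

Post-mortem (thanatotranscriptomic) time-course analysis of paired
mRNA-seq and miRNA-seq data in R.

When an animal dies, transcription does not simply stop: genes keep
changing expression for hours, some in every post-mortem interval, some
at exactly one time point, and miRNA-mediated repression keeps acting on
its targets. ThanatoSeq implements the computational pipeline for
dissecting such a time course — two living reference groups (young and
old adults) followed by a series of post-mortem sampling times — for
researchers analysing their own post-mortem expression data or studying
the statistical behaviour of tipping-point detection on time courses.

The pipeline:

- **Normalization & filtering** — FPKM / TPM / CPM; genes kept at
  FPKM ≥ 0.1 in all samples; miRNAs kept when detected in ≥ 2 replicates
  at some time point with mean TPM ≥ 1; PCA and correlation QC.
- **Differential expression** — negative-binomial Wald test
  (median-of-ratios size factors, method-of-moments dispersion) for every
  control × post-mortem comparison; Benjamini–Hochberg within comparison;
  DEG/DEM at |log2FC| > 1, FDR < 0.05; *core post-mortem genes* = DE in
  every comparison.
- **Time-specific genes** — fuzzy c-means on z-scored time profiles
  (m = 1 hard limit supported exactly); clusters with a single sharp
  centroid peak define the TSGs of each time point.
- **DNB tipping point** — candidate gene modules from hierarchical
  clustering of replicate-level fluctuations; for each module and time
  point the average SD, intra-module |r|, inter-module |r|, and the
  composite index CI = SD·PCC_in/PCC_out; a time point is a critical
  transition when a module's SD and correlation strength peak
  simultaneously, and the peak-CI module is the DNB:

  $$\mathrm{CI}(t) = \overline{SD}(t)\cdot
    \frac{\overline{|r|}_{\text{in}}(t)}
         {\max(\overline{|r|}_{\text{out}}(t),\ \varepsilon)}$$

- **miRNA targets** — seed scan (miRNA positions 2–8, antiparallel
  Watson–Crick, optional G:U) plus duplex scoring over the full miRNA
  register; a pair needs both alignment ≥ 80 and energy ≤ −20.
- **Co-expression** — unsigned WGCNA-style network (|r|^6, topological
  overlap matrix), module detection and eigenprofile merging; exact
  small-sample Spearman filter (full 40,320-permutation enumeration at
  n = 8) keeping pairs with ρ < −0.8, p < 0.05.
- **Integration** — final targets = sequence ∩ expression evidence;
  *post-mortem pairs* = final targets whose mRNA is a DEG and miRNA a
  DEM.
- **Enrichment** — hypergeometric over-representation with BH-FDR.
- **Synthetic data** — a seeded generator planting DE genes, single-time
  peaks, a DNB module, and seed-complementary anti-correlated
  miRNA–target pairs, with full truth tables, so every stage is testable
  without any sequencing data.

## Worked example

Simulate the reference design with six mRNA replicates, filter, call
differential expression, and detect the planted tipping point:

```r
library(ThanatoSeq)
library(SummarizedExperiment)

cfg <- simConfig(nGenes = 2000, nMirnas = 50, nRepsMrna = 6, seed = 42)
sim <- simulateTimecourse(cfg)
sim$truth
#> SimTruth: 620 DE genes, 400 TSGs, 30 DNB genes (transition at index 3),
#> 20 true pairs

fpkm <- normalizeExpression(sim$mrna, "fpkm")
keep <- filterFeatures(fpkm, rule = "mrna")
length(keep)
#> [1] 1899

de <- callDEFeatures(sim$mrna, c("T0", "T1"), paste0("T", 2:7))
length(deFeatureUnion(de))       # DEG union over the 12 comparisons
#> [1] 666
length(coreSharedFeatures(de))   # DE in every comparison
#> [1] 199

lx  <- log2(assay(fpkm, "fpkm")[keep, ] + 1)
des <- as.data.frame(colData(fpkm))
report <- detectTippingPoint(candidateModules(lx, des), lx, des)
report
#> DNBReport: 31 genes, tipping point at time index 3
#>   peak CI: 3.568562
length(intersect(dnbGenes(report), sim$truth@dnbGenes))
#> [1] 28
```

The report recovers the planted transition time (index 3) and 28 of the
30 planted module genes. `runPipeline()` chains every stage — including
target prediction, co-expression, pair integration and enrichment — and
writes per-stage TSVs plus a manifest with md5 sums; rerunning a
configuration reproduces all outputs byte for byte.

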