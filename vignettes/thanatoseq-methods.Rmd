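---
title: "Models and methods in ThanatoSeq"
author: "ThanatoSeq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ThanatoSeq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ThanatoSeq analyses paired mRNA-seq / miRNA-seq time courses that span an
organism's transition from life to death: two living reference points
(young and old adults) followed by a series of post-mortem sampling times.
The pipeline asks four questions of such data. Which genes change after
death and which change in *every* post-mortem interval (core post-mortem
genes)? Which genes peak at exactly one time point (time-specific genes,
TSGs)? Is there a critical transition — a tipping point — in the global
expression dynamics, and which gene module drives it (the dynamical
network biomarker, DNB)? And which miRNA–mRNA pairs plausibly mediate
post-transcriptional regulation after death? This vignette records the
models behind each stage, the parameters that matter, and the choices made
where the design was genuinely open.

## Normalization and abundance filtering

Gene abundance is expressed as FPKM,
$\mathrm{FPKM}_{ij} = 10^9 c_{ij} / (\ell_i N_j)$, with $\ell_i$ the
feature length in nucleotides and $N_j$ the column total of the count
matrix. No alignment statistics are available at this level, so the
column total stands in for "total mapped reads". TPM first converts
counts to length-normalized rates and rescales each sample to $10^6$, so
every TPM column sums to one million by construction. Mature miRNAs are
nearly constant in length, so their abundance uses counts per million
reported in TPM units.

Filtering follows three rules, all thresholds inclusive exactly as
printed: an mRNA is kept when its FPKM is at least 0.1 in **all**
samples; a miRNA is kept when (a) it has a raw count above zero in at
least two replicates of some single time point and (b) its mean TPM over
all samples is at least 1. "Detected" is operationalized as raw count
> 0, which the source protocols leave undefined. Quality control offers
PCA on log2(x+1) (features centred) and inter-sample Pearson
correlation; replicates of a time point should correlate more strongly
with each other than with other times.

## Differential expression

Each living control group is compared against every post-mortem group
(2 × 6 = 12 comparisons in the reference design). The test is a Wald
statistic on the difference of log normalized group means, with the
negative-binomial variance $\mu + \alpha\mu^2$ propagated through the
delta method and median-of-ratios size factors. Dispersion is estimated
by method of moments. The default pools the per-gene moment estimates
into a single common $\hat\alpha$ (their mean over genes whose pooled
normalized mean exceeds 5): at three replicates per group the per-gene
moment estimate is so variable that a per-gene Wald test is either
anti-conservative (normal reference) or nearly powerless (t reference
with 4 degrees of freedom, whose smallest attainable p-value is too
large for step-up FDR control at realistic DE fractions). The common
estimate keeps the null fraction of p < 0.05 near 0.05 while retaining
power; `dispersion = "per-gene"` restores the per-gene formula for data
with genuinely heterogeneous dispersions, and the whole test sits behind
a small contract (log2FC, p per feature) so another engine can replace
it. A pseudocount of 0.5 stabilizes fold changes of low counts;
all-zero features report log2FC = 0, p = 1.

Benjamini–Hochberg adjustment is applied within each comparison (the
standard per-contrast convention; the alternative of pooling all
comparisons is not used). A feature is called DE at |log2FC| > 1 and
FDR < 0.05. The union of DE calls over comparisons gives the DEG/DEM
sets; their strict intersection over all comparisons gives the core
post-mortem-related genes.

## Time-specific genes by fuzzy c-means

Expression profiles are reduced to one value per time point (replicate
mean) and z-scored per gene along the time axis, so clustering sees
shape, not level. Fuzzy c-means minimizes
$\sum_{ij} u_{ij}^m \lVert x_i - c_j\rVert^2$. The fuzzifier default is
m = 1, the degenerate hard limit in which memberships become 0/1
indicators and the update is exactly Lloyd's k-means; this is the
setting the pipeline's reference protocol prescribes, even though it
makes "membership scores" trivial — m = 1.25 is exercised in the tests
for genuinely soft memberships. Five random restarts are run and
the best objective kept; the objective trace is non-increasing within a
run and the result is deterministic given the seed.

A cluster is *time-specific* for time t when its centroid peaks at t and
exceeds its second-highest value by at least 0.5 z-units (`peakMargin`);
the margin rule is this package's operationalization of distinct
time-specific upregulation, for which no standard definition exists.
A gene is assigned to the time of the time-specific cluster holding its
maximal membership, provided that membership reaches 0.5, so TSG sets
for different time points are disjoint by construction. The cluster
count is configurable; 36 is the reference scale for genome-wide runs,
while the synthetic runs use c = 12 for 8 time points.

## DNB tipping-point detection

The DNB model holds that approaching a critical transition, a dominant
gene group shows (i) sharply rising variance, (ii) rising internal
correlation, and (iii) falling correlation with the rest of the
transcriptome. All statistics are computed **across replicates within
one time point**: `sdAvg` (mean member SD), `pccIn` (mean |Pearson r|
over member pairs), `pccOut` (mean |r| between members and
non-members), correlation strength `pccIn / max(pccOut, 0.01)` — the
ratio jointly encodes (ii) and (iii) — and the composite index
CI = sdAvg × strength. The 0.01 floor keeps CI finite; |r| is used
throughout.

Candidate modules come from hierarchical clustering of genes. Two
choices matter and both were settled empirically on planted data.
First, the clustering correlation is computed on expression *centred
within each time point*: the DNB statistics quantify replicate-level
fluctuation, and removing the deterministic time-course shape prevents
banal co-expression (shared trends) from dominating the tree. Second,
Ward linkage (`ward.D2`) on 1 − |r| is the default: average linkage
chains background genes onto tight modules and complete linkage
fractures a module on its single weakest pair; Ward's compact,
balanced clusters recover planted modules far more reliably. The tree
is cut at several sizes (k = 50, 100, 200 by default) and all distinct
gene sets of at least `minSize = 5` genes are pooled — several candidate
sets, scored jointly. Very fine cuts are deliberately excluded from the
default: tiny sub-cliques mined from the same data show upward-biased
internal correlation and can outcompete the genuine module.

A candidate is *eligible* when its sdAvg and its correlation strength
peak at the same time (the simultaneous-peak rule); among eligible
candidates the one with the largest peak CI is selected, ties broken by
larger module then lexicographic gene ids. If no candidate is eligible
the result is an explicit no-transition report, not an error. An
optional permutation test shuffles the sample-to-time assignment and
reports the proportion of permutations whose CI at the called time
reaches the observed value (with the +1/+1 correction, so
p ≥ 1/(nPerm+1)).

Per-time correlations at two or three replicates are extremely noisy;
the synthetic validation runs therefore use six replicates, and results
on designs with fewer replicates should be read as exploratory.

## Sequence-based miRNA target prediction

The seed scan reports every UTR position whose seven bases pair
antiparallel and Watson–Crick with miRNA positions 2–8 (G:U wobble
admissible by flag). Each hit is scored over the full miRNA register:
one base 3′ of the seed site (pairing miRNA position 1) and the
remainder 5′-ward on the UTR, where the miRNA 3′ region pairs. Scoring
is gapless: +5 per Watson–Crick pair, +1 per G:U, −3 per mismatch, seed
positions doubled; the energy proxy sums −3.0 (G:C), −2.0 (A:U), −1.0
(G:U) over paired positions. A pair is a sequence target when at least
one site passes *both* the alignment threshold (default ≥ 80) and the
energy threshold (default ≤ −20) — two independent criteria intersected,
playing the role of a consensus between two independent predictors. These
scorers are deliberate simplifications, not re-implementations of
dynamic-programming aligners or duplex-folding energies, and the
interface admits wrapping such tools; the default cutoffs were
calibrated on synthetic decoys only (random 500-nt UTRs pass at well
under 5%).

## Co-expression evidence and integration

mRNA and miRNA profiles are combined on the shared time axis (replicate
means, per-feature z-scores) and an unsigned weighted network built:
adjacency $|r|^\beta$ with β = 6 (fixed; scale-free fitting is out of
scope), and the topological overlap measure
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i,k_j) + 1 - a_{ij})$ with unit diagonal. Modules come from
average-linkage clustering on 1 − TOM with small groups unassigned,
followed by iterative merging of modules whose eigenprofiles (first
principal component, sign-aligned to the module mean) correlate above
0.85 — a simpler, contract-equivalent stand-in for dynamic tree cutting
with eigengene merging. Because the network is unsigned, a repressive
miRNA and its anti-correlated target legitimately co-occupy one module.

Candidate pairs co-assigned to a module are then tested for negative
monotone association: Spearman ρ over the (default 8) time-point means,
with a two-sided p computed by full enumeration of all n! rank
permutations for n ≤ 8 (40,320 permutations; midranks and per-case
enumeration under ties; t approximation above n = 8). A pair passes at
ρ < −0.8 and p < 0.05. Final targets are the intersection of the
sequence route and the expression route; a final target whose mRNA is a
DEG and whose miRNA is a DEM is a post-mortem pair. The inclusion chain
post-mortem ⊆ final ⊆ (sequence ∩ expression) holds by construction.

## Enrichment

Over-representation of a gene set against a term→gene table uses the
hypergeometric upper tail (the one-sided Fisher test), BH adjustment
across tested terms, and FDR < 0.05. The background defaults to the
features surviving abundance filtering; set members absent from the
annotation count toward the set size but no term. Terms are tested
exactly as annotated — no ontology-graph propagation.

## The synthetic data generator

The generator emulates the reference design — 8 time points (2 living,
6 post-mortem), 3 mRNA and 2 miRNA replicates, negative-binomial counts
with variance $\mu + \alpha\mu^2$ and shared α = 0.1 — and plants four
recoverable structures in disjoint gene sets: DE genes (±2 log2 in every
post-mortem group), TSG genes (×4 at one uniformly drawn time point), a
DNB module, and miRNA–target pairs. Baseline means are log-normal
(log 50, sd 1.2 for mRNA; log 200, sd 1.0 for miRNA); gene lengths are
log-normal around 1.5 kb. All draws flow from one seeded generator, so
identical configurations give byte-identical fixtures.

Three generator decisions deserve record. First, planted truth for DE is
derived from the planted means themselves: a gene is truth-DE for a
comparison when its deterministic log2-mean difference between the two
groups exceeds 1 — TSG peaks and pair couplings also create genuine
differential expression, and a truth table restricted to the "designated
DE" subset would misclassify those recoveries as false positives.
Second, roles are planted only in adequately expressed genes (baseline
mean ≥ 10; ≥ 100 for DNB and pair members, whose planted effects swing
several log2 units): at lower baselines the downswings censor at zero
counts, which destroys the planted correlation — structure a real
analysis could never discover in unquantifiable genes. Third, the DNB
latent factor (additive shared Gaussian on the log scale at the
transition time only, with amplitude set so total SD inflates by
`dnbSdFactor` = 5 and pairwise correlation approaches `dnbRhoIn` = 0.8)
is standardized to zero mean and unit variance across the replicates:
with six replicates the realized variance of an unstandardized factor
varies by an order of magnitude across seeds, so the "planted"
transition would simply be absent from some datasets. Planted miRNA
profiles traverse an evenly spaced ladder of levels (amplitude
`lfcDE` = 2 log2 units) in random time order, in a few shared groups
mimicking co-regulated miRNA families; the ladder guarantees every time
point is distinguishable through replicate noise, and the grouping
gives co-expression modules of workable size. Planted target sites
embed the reverse complement of the full mature miRNA (recording the
7-nt seed interval), so true sites carry seed plus extended
complementarity and pass both duplex criteria.

What the generator does **not** emulate: read-level artifacts, batch
effects, library-preparation biases, pooling of individuals into
libraries, gene–gene correlation outside the planted structures,
per-gene dispersion heterogeneity (available as an option but off by
default), and UTR base composition. Passing the planted-recovery tests
therefore demonstrates the pipeline's logic and calibration under its
own model assumptions, not performance on real post-mortem libraries.

## Numerical choices and degenerate inputs

Problem sizes in the validation suite were chosen to exercise each stage
at desk scale: 2,000 genes × 6 replicates for DNB recovery (20 seeded
runs), 500 mRNAs / 50 miRNAs / 20 pairs for pair calling (10 runs),
10,000 genes for DE calibration. Other fixed choices: log2(x + 1) before
PCA and all correlation work (the source analyses do not state their
transform); fuzzy c-means tolerance 1e-6 on the objective with 200
iteration cap and empty clusters re-seeded from the worst-fit point;
dispersion floor 1e-8; Spearman requires n ≥ 4 (the p-value is
meaningless below); constant features are dropped with a warning before
z-scoring; an all-zero library is an error, never silently rescaled.
Ties in tipping-point selection are broken deterministically (larger
module, then lexicographic ids) so reruns are reproducible.

## Known limitations

The DE engine is a stand-in with moment dispersion, not a
shrinkage-based GLM; at two replicates (the miRNA design) its power is
limited and its dispersion estimate leans on the shared-α assumption.
DNB detection at the original design's three replicates is statistically
fragile — the package warns rather than pretends otherwise. The target
scorers rank duplexes on a simplified scale; absolute score values are
not comparable to MiRanda or RNAhybrid outputs. Enrichment treats
annotation terms independently. Absolute result counts on real data
(how many DEGs, core genes, DNB genes or final pairs a study reports)
depend on the underlying sequencing libraries and on external tool
internals, and cannot be reproduced at desk scale; the package's
validation is property-based on planted truth instead.
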