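---
title: "Models and methods behind popGSI"
author: "popGSI maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popGSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popGSI)
```

# Scope

popGSI implements the downstream half of a population-genomic study of
river-structured fish populations sampled both at their source rivers and
in an estuarine mixed-stock fishery: quality control of diploid biallelic
SNP genotypes, population structure, within-river diversity and effective
population size, a life-history-tactic outlier scan, and genetic stock
identification (GSI) of the mixed sample. A seeded synthetic-data
generator reproduces the essential features of such a study so that every
stage can be validated against known truth. Raw-read processing,
genotype calling, model-based ancestry clustering (ADMIXTURE-style) and
genome annotation are out of scope: the package starts from a VCF.

# The genotype container

`GenotypeExperiment` extends `RangedSummarizedExperiment`: the `dosage`
assay holds alternate-allele counts (0/1/2, `NA` missing) with loci as
rows (a `GRanges` with `ref`/`alt`) and samples as columns (`group`,
optional `tactic` and `year`). All filters return a new object and append
a row to a telescoping `FilterReport` kept in the metadata, so the
removal bookkeeping of a full cascade can always be reconstructed.

# The synthetic study

The generator is parameterised by a `SimConfig` and emulates, by default,
an eight-river system with the sample sizes 37, 30, 30, 42, 19, 39, 41
and 10 (mean 31, SD 11.39, total 248) and two estuarine sampling years of
152 and 128 fish (280 in total).

**Drift model.** Allele frequencies evolve down a rooted tree by
Balding–Nichols sampling: the ancestral alternate-allele frequency *p*
is drawn at the root and each branch with drift parameter *F* in (0,1)
replaces *p* by a draw from Beta(*p*(1−*F*)/*F*, (1−*p*)(1−*F*)/*F*).
Cumulative branch length therefore encodes divergence, and pairwise
Weir–Cockerham FST between two tips is approximately half the sum of
their non-shared branch *F*. The default tree places a very weakly
differentiated sister pair (GUE/DEL, realised FST ≈ 0.003) inside a
river-complex clade, a second coastal clade, and two strongly drifted
rivers on a shared ancestral branch, spanning realised pairwise FST of
roughly 0.003–0.15. Geographic distances are the cophenetic tree
distances rescaled to kilometres (`treeDistancesKm()`), so a genuinely
linear relation between linearised FST and distance exists for the
isolation-by-distance machinery to recover.

**Site-frequency spectrum.** The ancestral minor-allele frequency is
drawn as `mafFloor + (0.5 - mafFloor) * u^3` with *u* uniform, a
decreasing folded spectrum typical of reduced-representation SNP panels.
This choice is deliberate: a uniform ancestral spectrum would put
expected observed heterozygosity near 0.35, and the cascade's
heterozygosity ceiling of 0.3 would then remove every sample. With the
tilted spectrum, per-sample Ho sits near 0.2–0.25.

**Life-history tactic signal.** A configurable number of loci (default
20) carry a within-population allele-frequency shift of δ (default 0.25)
between estuarine and marine fish, split ±δ/2 and clipped to
[0.01, 0.99]. This is the simplest generator that produces "no overall
structure between tactics, but genomic regions associated with them".
Mixture years draw each fish's origin river from a year-specific
proportion vector and its tactic from a per-origin estuarine
probability (defaults 0.738 and 0.468 for the two years).

**Artifacts.** Read depth per genotype is negative binomial (mean 28,
size 3) scaled by a lognormal per-sample coverage multiplier
(sdlog 0.4), so a realistic minority of samples (~5%) exceeds the 5%
missingness ceiling. Allelic balance at heterozygotes is Beta(20, 20).
Merged paralogs are planted by summing the reads of two loci and
re-calling the merged genotypes (alt-read fraction < 0.15 → ref
homozygote, > 0.85 → alt homozygote, else heterozygote), which yields
the excess heterozygosity and read-ratio deviation that HDplot detects.
Kin pairs are planted as duplicated samples with 5% of genotypes
re-drawn from the origin's frequencies. All randomness flows from one
master seed through fixed per-stage sub-seeds.

A separate forward simulator, `simulateWrightFisher()`, produces a
closed random-mating population of constant size *N* with free
recombination. Unlinked-locus LD equilibrates within a few generations,
which makes it the truth-bearing input for the LD effective-size
estimator; the tree-based generator deliberately has no within-population
LD.

# Quality-control cascade

`standardFilterCascade()` runs, in order: genotype depth ≥ 3×; locus
pass 1 (every group ≤ 40% missing and ≥ 3 carriers of the rare allele);
sample missingness (strictly greater than 5% removed); locus pass 2
(50% / 5 carriers); kin removal; heterozygosity ceiling (Ho strictly
above 0.3 removed); locus pass 2 repeated; HDplot paralog removal;
LD pruning. Notes on the decisions inside:

* *Rare-allele support counts carrier samples*, not allele copies — a
  carrier has one or two copies of the minor allele. Both thresholds are
  inclusive.
* *Relatedness* is the unadjusted Yang et al. genomic relationship on
  pairwise-complete polymorphic loci; for each pair above 0.9 the member
  with more missing data (ties: lexicographically later id) is dropped,
  iteratively, so one representative per kin cluster remains.
* *HDplot*: H is the heterozygote fraction among called samples; D is
  (Σref − Σalt)/√(Σtotal) over heterozygous calls, 0 when there are no
  heterozygotes. Defaults flag H > 0.6 or |D| > 7; both are settings,
  since published variants of the method differ in their exact cut-offs.
* *LD pruning* scans loci in (chrom, pos) order and drops a locus whose
  dosage r² with any *retained* locus within 100 kb upstream exceeds
  0.5; the window is inclusive at exactly 100 000 bp, so loci 100 001 bp
  apart are never compared. "First of the linked loci kept" follows from
  the forward scan.
* *Identity-by-missingness* is a PCA of the binary missingness matrix
  followed by 2-means and a mean silhouette; a value above ~0.5 signals
  batch-structured missingness.

Every filter is idempotent, and the report counts telescope exactly.

# Diversity and LD effective size

Per-sample Ho is the heterozygous fraction of called genotypes; He is
the mean of 2p(1−p) over the sample's called loci with *p* the allele
frequency of the sample's own group (including the sample itself — the
simplest convention; tools differ in whether they exclude the focal
individual, a difference of order 1/2n); F = 1 − Ho/He. Groups of one
are flagged rather than given a fake He.

`ldNe()` implements the linkage-disequilibrium method on loci passing an
in-group MAF > 0.05, restricted to pairs on different chromosomes. The
pairwise statistic is the Burrows composite r², computed as the squared
Pearson correlation of dosages times the (S/(S−1))² covariance factor —
without that factor the sampling expectation E[r²|S] = 1/S + 3.19/S²
(S ≥ 30; the small-S polynomial otherwise) systematically overshoots the
measured r² and destroys the drift signal. The drift residual
r²′ = mean r² − E[r²|S] (harmonic-mean S across pairs) is inverted under
random mating, Ne = (1/3 + √(1/9 − 2.76 r²′))/(2 r²′); a non-positive
residual reports Ne = ∞ with a warning, which on drift-free data is the
correct answer about half the time (the other half lands a hair above
zero and reports a finite but enormous Ne — never a spuriously small
one). The confidence interval is a delete-one-chromosome jackknife on
the drift residual, transformed to the Ne scale; parametric chi-squared
intervals of other implementations depend on an effective-independence
heuristic we do not reproduce, and are typically narrower. A `maxLoci`
thinning cap (default 2000, evenly spaced) bounds the pair count.

# Population structure

* **PCA** mean-imputes missing dosages per locus, drops zero-variance
  loci, centres and unit-scales (conventions differ between tools; unit
  scaling is the common default for SNP data), and reports scores,
  loadings and variance fractions.
* **Pairwise FST** is multilocus Weir–Cockerham θ by ratio of sums of
  the per-locus a, b, c components; 1000 bootstrap resamples over loci
  give percentile 95% intervals and a one-sided p (share of resampled θ
  ≤ 0). Loci monomorphic across the pair contribute nothing.
* **Isolation by distance** regresses θ/(1−θ) on pairwise distance and
  ranks models by AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1), with k
  counting every estimated parameter including the residual variance
  (linear: 3; zero-parameter null, residuals = y: 1; optional
  intercept-only: 2). The literal "y ~ 0" null is the default companion
  model; the intercept-only variant is offered because published model
  tables sometimes mix the two.
* **AMOVA** partitions squared-Euclidean distances between mean-imputed
  dosage vectors into among-primary, among-secondary-within-primary and
  within components with the standard nested coefficients for unbalanced
  designs; percentages are components over their sum (negative
  components are reported as-is, as is conventional). Permutations:
  whole secondary cells are relabelled across primary groups for the
  primary test (cells stay distinct so the nesting never degenerates),
  samples are permuted within primary groups for the secondary test, and
  freely for the within test (small observed within-variance is the
  signal, so that tail is lower).
* **Directional relative migration** forms, for each pair, a hypothetical
  migrant pool with the unweighted mean of the two allele-frequency
  vectors (weighting is a free choice; equal weights are the simplest),
  computes Nei's GST (ratio of sums across loci) between the pool and
  each member, converts the source-side differentiation g into a raw
  flow ((1/g) − 1)/4, caps non-positive g at a configurable maximum, and
  normalises the directed matrix by its maximum. Identical populations
  give exactly symmetric flow.

# Outlier scan and q-values

The scan regresses each centred/scaled locus on the first K principal
component score vectors (K chosen by the automated scree elbow — the
largest second difference of the eigenvalues, with the scree table
returned for manual override and a warning at K = 1). The per-locus
z-vector is summarised by a Mahalanobis distance whose location and
covariance are estimated by a deterministic iteratively-trimmed
procedure: the first pass uses median/MAD marginals (which a minority
outlier cluster cannot drag), later passes use the mean/covariance of
loci below a median-rescaled chi-squared 97.5% cut. We deviate here from
the plain sample covariance: with a planted signal of 20 loci in a
10²-locus scan the sample covariance is inflated by the very outliers
being tested and power collapses, while the trimmed estimate restores
it without sacrificing null calibration (the genomic inflation factor
λ = median(D²)/median(χ²_K) stays in [0.8, 1.2] on null data). P-values
are the upper χ²_K tail of D²/λ; q-values are Storey's procedure with
π₀ estimated on the λ-grid 0.05–0.90 and a df-3 smoothing-spline
extrapolation, thresholded at q < 0.01.

Detectability is bounded by the usual spiked-covariance transition: an
axis carried by m loci of point-biserial correlation r is visible only
when 1 + (m−1)r² exceeds (1 + √(L/n))². With δ = 0.25 and n = 270 the
20-locus signal is recoverable at panel sizes of order 10² loci, and
invisible to any unsupervised scan at 5 × 10³ — the package's validation
therefore runs the scan at the former scale, and a genome-wide scan of a
weak polygenic signal should be expected to return few or no hits.
`tacticFstContrast()` reports multilocus θ between tactics over all loci
versus a flagged set, and their ratio.

# Genetic stock identification

**Balanced panels.** For every population pair, loci are ranked by
decreasing allele-frequency difference (AFD, on the alternate allele).
A greedy water-filling loop repeatedly tops up the pair with the
smallest running Σ AFD² (ties: lexicographic pair order; AFD ties:
chromosome, position), so all pair lists converge to equal sums — the
defining balance property, with the spread bounded by the largest
appended AFD². The loop stops when the deduplicated union reaches the
target size; a locus already in the union still accrues to another
pair's list and sum. Weakly differentiated pairs end with longer lists,
which is exactly why such panels help the hardest assignments.

**Self-assignment.** Monte-Carlo cross-validation sweeps training
proportions (70%, 90%) and locus proportions (50%, 100%) over 100
iterations: stratified training draw, allele frequencies smoothed by
+0.5 per allele count, held-out individuals assigned to the population
maximising the HWE genotype log-likelihood (the classifier is a
documented choice — deterministic, tuning-free, standard in GSI).
`pickPanel()` chooses a size lexicographically: maximise the minimum
per-population mean accuracy, then minimise the mean across-iteration
SD, then prefer the smaller panel.

**Mixture model.** Conditional GSI: reference allele frequencies are
fixed at their posterior means under a per-allele Dirichlet(1/2) prior;
the Gibbs sampler alternates origin indicators z (proportional to π
times the HWE likelihood over panel loci, missing genotypes skipped) and
π ~ Dirichlet(1 + counts), for 2000 sweeps with a 100-sweep burn-in
(burn-in and priors are package defaults with config overrides). Years
are estimated independently. Per-individual posteriors are the mean z
indicators; fish with no called panel genotype are flagged and shown
with a uniform posterior. The odds filter keeps a fish only when its top
posterior is at least 10 times the runner-up, inclusive at exactly
tenfold ("at least 10 times"); note that a two-way posterior of
(0.9, 0.1) is a 9:1 ratio and is therefore dropped. Contribution tables
report per-year percentages by assigned river (among kept fish) and by
tactic among tactic-scored fish (marine/estuarine; "mixed" and unscored
excluded), with chi-squared homogeneity tests across years, without
continuity correction since the study-scale tables have large expected
counts.

# Pipeline, seeds and problem sizes

`runPipeline(subcommand, config)` orchestrates
simulate → filter → diversity → structure → outliers → panel → assign →
mix → report, writing TSV/JSON artifacts and a manifest (inputs, config
hash, master seed, derived stage seeds, versions). One global seed
drives everything; each stage derives a fixed sub-seed, so reruns are
byte-identical and stages are insensitive to each other's draw counts.
A thin command-line wrapper ships in `inst/scripts/popgsi.R`.

The default fixture (8 populations, 5000 loci, 280 mixture fish)
completes on one CPU in a few minutes. The test-suite and the
acceptance script use deliberately smaller problem sizes — hundreds to a
few thousand loci, 4–10 seeds per stochastic check — chosen so the full
validation runs in minutes while keeping each check's Monte-Carlo error
well inside its assertion margin; the thresholds themselves (±0.05
mixture recovery, factor-2 Ne, FDR ≤ 0.05, accuracy > 0.95) are fixed
properties of the methods, not of the problem sizes.

# What passing tests do and do not show

The generator draws genotypes independently per locus given population
frequencies. It reproduces hierarchical drift, a weak tactic signal,
GBS-like depth/missingness, paralog collapse and kin duplication; it
does not model within-population linkage (except in the dedicated
Wright–Fisher simulator), genotyping batch effects beyond coverage,
allele dropout, null alleles, or selection over generations.
Consequently the suite validates the estimators and their plumbing —
not, for example, LD-pruning behaviour on realistic haplotype structure,
and real data can violate the HWE assumptions inside the assignment
likelihood in ways the synthetic data cannot.

# Known limitations

* The LD-Ne confidence interval is a jackknife, typically wider than
  the parametric intervals printed by dedicated Ne software.
* The outlier scan's trimmed covariance is deterministic but not a
  high-breakdown MCD estimator; contamination above ~40% of loci would
  defeat it (and the scan's premise).
* `divMigrate` flows are relative; the cap applied when differentiation
  is non-positive makes zero-divergence pairs saturate at the maximum.
* The mixture model is conditional (reference frequencies fixed), so
  reference sampling noise is not propagated into the posterior.
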