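# popGSI

Population structure and genetic stock identification (GSI) from SNP
genotypes, for studies of river-structured fish populations harvested in
a mixed-stock fishery.

The setting popGSI serves: several source populations (rivers) are
genotyped at thousands of biallelic SNPs, a mixed sample of unknown
origin is taken where their migrants mingle (an estuary fishery), and
the questions are *how structured are the sources*, *which loci track a
life-history tactic*, and *who contributes how much to the mixed
catch*. The package covers the whole downstream chain:

* a `GenotypeExperiment` container (a `RangedSummarizedExperiment` of
  dosage/depth/allele-depth assays) with VCF + popmap input;
* the post-genotyping QC cascade: genotype depth (3×), per-group
  missingness and rare-allele carriers (40%/3 then 50%/5), sample
  missingness (5%), Yang relatedness (0.9), heterozygosity (0.3),
  HDplot paralog flags, LD pruning (r² > 0.5 within 100 kb) and an
  identity-by-missingness diagnostic — with a telescoping
  `FilterReport`;
* diversity (Ho, He, F per individual, per river) and the
  linkage-disequilibrium effective population size
  (Burrows composite r², MAF > 0.05, cross-chromosome pairs,
  Ne = (1/3 + √(1/9 − 2.76 r²′))/(2 r²′));
* structure: PCA, pairwise Weir–Cockerham θ = Σa / Σ(a+b+c) with a
  1000-resample locus bootstrap, isolation-by-distance model selection
  on θ/(1−θ) by AICc, two-level AMOVA with permutation tests, and
  directional relative migration from migrant-pool GST;
* a PCA-based outlier scan (Mahalanobis distances of per-locus
  regression z-scores, genomic-inflation rescaling, Storey q-values at
  q < 0.01) and the FST contrast between life-history tactics;
* GSI: allele-frequency-difference (AFD) balanced panels whose per-pair
  Σ AFD² are equalised by greedy water-filling, Monte-Carlo
  cross-validated self-assignment (70%/90% training individuals,
  50%/100% loci, 100 iterations), Bayesian mixture composition by Gibbs
  sampling (2000 sweeps), a 10×-odds posterior filter, and per-year
  contribution tables with chi-squared homogeneity tests;
* a seeded synthetic-study generator (Balding–Nichols drift down a
  population tree, tactic signal, GBS-like depth artifacts, planted kin
  and paralogs) plus a Wright–Fisher forward simulator, so every stage
  is testable against known truth.

## A worked example

Simulate the default eight-river study (Table-1-style sample sizes,
two mixture years) at 1500 loci, build a balanced 500-SNP panel, check
self-assignment, and estimate the 2020 mixture composition:

```r
library(popGSI)

cfg <- defaultSimConfig(seed = 42, nLoci = 1500, nChrom = 10)
ref <- simulateReference(cfg)
ref$gm
#> GenotypeExperiment: 1500 loci x 248 samples
#> groups: BAL(39) CAN(19) DEL(42) FEU(37) GEO(41) GUE(30) MEL(30) NST(10)

fst <- pairwiseFst(ref$gm, nBoot = 100, seed = 1)
fst
#> FstMatrix over 8 groups; theta range 0.003647-0.1215
```

The sister rivers GUE and DEL are nearly indistinguishable
(θ = 0.0037) while the two drifted rivers sit an order of magnitude
higher (NST–FEU θ = 0.116) — the hierarchical pattern the panel
construction has to cope with.

```r
panel <- buildBalancedPanel(alleleFreqs(ref$gm), 500)
panel
#> PanelSpec: union 500/500 loci over 28 pairs; pair sums 4.415-4.761

cv <- selfAssignCv(ref$gm, panel, trainProps = 0.7, lociProps = 1,
                   nIter = 20, seed = 2)
round(colMeans(cv@accuracy), 2)
#>  BAL  CAN  DEL  FEU  GEO  GUE  MEL  NST
#> 1.00 1.00 1.00 1.00 1.00 0.94 1.00 1.00
```

The per-pair sums of squared AFD agree to within one locus's worth of
information (4.42–4.76) — that balance is what buys the weakly
differentiated GUE/DEL pair its longer locus list, and even that pair
assigns at 94%. Now the estuary sample:

```r
af   <- AlleleFreqTable(freq = ref$truth@popFreq,
                        nCalled = matrix(10000L, 1500, 8),
                        loci = SummarizedExperiment::rowRanges(ref$gm))
mix  <- simulateMixture(cfg, af, ref$truth)
mr   <- mixtureEstimate(ref$gm, mix$gm, panel,
                        nSweeps = 2000, burnIn = 100, seed = 3)
mr   <- oddsFilter(mr, 10)
mr
#> MixtureResult: 280 individuals, 8 candidate populations;
#>   238 kept by the odds filter

subset(mr@mixingProps, year == "2020" & mean > 0.02)
#>  year population  mean    sd
#>  2020        DEL 0.663 0.041
#>  2020        GUE 0.194 0.035
#>  2020        CAN 0.106 0.025
```

The 2020 catch is dominated by the two sister tributaries with a
smaller CAN contribution, close to the generator's design proportions
(0.616 / 0.291 / 0.073) — the GUE↔DEL gap is the expected leakage
between near-identical stocks at this panel size, and the posterior SDs
quantify it. `contributionSummary(mr, ...)` turns the kept fish into
per-year river and tactic percentage tables with chi-squared tests.

The whole pipeline — QC from a VCF, diversity, structure, outliers,
panels, assignment, mixture, report — runs from one config:

```r
cfg <- defaultPipelineConfig(outDir = "out", seed = 1)
runPipeline("all", cfg)     # or per stage: "simulate", "filter", ...
```

or from the shell via `Rscript inst/scripts/popgsi.R all --out out
--seed 1`.

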