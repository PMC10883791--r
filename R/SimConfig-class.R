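#' SimConfig: parameterisation of the synthetic study
#'
#' Describes an entire synthetic population-genomic study: a drift tree
#' over source populations, locus layout over chromosomes, per-population
#' sample sizes, mixed-stock sampling years with origin and life-history
#' tactic proportions, a polygenic tactic signal, a depth/missingness
#' model, and planted kinship and merged-paralog artifacts.
#'
#' The drift model is Balding-Nichols: an ancestral minor-allele
#' frequency is drawn at the root from a decreasing folded spectrum on
#' (mafFloor, 0.5), and along each branch with drift parameter F in
#' (0,1) the child frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F). Tree depth thus encodes genetic (and,
#' after scaling, geographic) distance.
#'
#' @slot seed integer master seed; all stage seeds derive from it.
#' @slot nLoci total locus count.
#' @slot chromLayout data.frame (chrom, lengthBp, nLoci) per chromosome.
#' @slot popTree `ape::phylo` with branch lengths holding per-branch F
#'   values in (0,1); tip labels are population codes.
#' @slot sampleSizes named integer vector, samples per source population.
#' @slot mixtureDesign list of per-year designs: each a list with `year`,
#'   `n`, `origin` (named proportions over populations, summing to 1) and
#'   `estuarineProb` (per-origin probability that a fish is estuarine
#'   rather than marine).
#' @slot refTacticProps named numeric, per-population estuarine proportion
#'   among reference fish (NA = tactic not scored in that river).
#' @slot tacticLoci numeric `c(count, delta)`: number of tactic-associated
#'   loci and the allele-frequency shift between tactics (split +/- delta/2
#'   around the population frequency, clipped to [0.01, 0.99]).
#' @slot missingModel numeric `c(meanDepth, dispersion, minCallDepth,
#'   sampleSdLog)`: negative-binomial per-genotype depth with a lognormal
#'   per-sample coverage multiplier (sdlog `sampleSdLog`); genotypes with
#'   depth below `minCallDepth` are set missing.
#' @slot kinPairs integer, planted full-sib-like duplicate samples.
#' @slot dupLoci integer, planted merged-paralog loci.
#' @slot mafFloor numeric, minimum ancestral allele frequency.
#' @aliases SimConfig-class
#' @export SimConfig
#' @exportClass SimConfig
SimConfig <- setClass("SimConfig", slots = c(
  seed = "integer", nLoci = "integer", chromLayout = "data.frame",
  popTree = "ANY", sampleSizes = "integer", mixtureDesign = "list",
  refTacticProps = "numeric", tacticLoci = "numeric",
  missingModel = "numeric", kinPairs = "integer", dupLoci = "integer",
  mafFloor = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  tr <- object@popTree
  if (!inherits(tr, "phylo")) msg <- c(msg, "popTree must be a phylo")
  else {
    if (length(tr$tip.label) < 2)
      msg <- c(msg, "popTree must have at least two leaf populations")
    f <- tr$edge.length
    if (is.null(f) || any(f <= 0) || any(f >= 1))
      msg <- c(msg, "every branch drift F must lie in (0, 1)")
  }
  if (any(object@sampleSizes <= 0L))
    msg <- c(msg, "sample sizes must be positive")
  if (inherits(tr, "phylo") &&
      !all(names(object@sampleSizes) %in% tr$tip.label))
    msg <- c(msg, "sampleSizes names must match popTree tips")
  for (yr in object@mixtureDesign) {
    if (abs(sum(yr$origin) - 1) > 1e-9)
      msg <- c(msg, sprintf("origin proportions for year %s must sum to 1",
                            yr$year))
    if (yr$n <= 0L) msg <- c(msg, sprintf("year %s has n <= 0", yr$year))
  }
  if (object@tacticLoci[["delta"]] < 0 ||
      object@tacticLoci[["delta"]] > 0.5)
    msg <- c(msg, "tactic delta must lie in [0, 0.5]")
  if (sum(object@chromLayout$nLoci) != object@nLoci)
    msg <- c(msg, "chromLayout locus counts must sum to nLoci")
  if (object@mafFloor <= 0 || object@mafFloor >= 0.5)
    msg <- c(msg, "mafFloor must lie in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@popTree$tip.label), "populations,",
      object@nLoci, "loci on", nrow(object@chromLayout),
      "chromosomes, seed", object@seed, "\n")
  cat("reference n:", paste0(names(object@sampleSizes), "=",
                             object@sampleSizes, collapse = " "), "\n")
  for (yr in object@mixtureDesign)
    cat("mixture", yr$year, ": n =", yr$n, "\n")
})

#' Default synthetic study configuration
#'
#' Returns a [SimConfig-class] emulating an eight-river hierarchical
#' study system: Table-1-style sample sizes (37, 30, 30, 42, 19, 39, 41,
#' 10; mean 31, SD 11.39), a drift tree with a weakly differentiated
#' sister pair (GUE/DEL), a river-complex clade, and two strongly
#' diverged rivers (CAN, NST), spanning pairwise FST roughly 0.003-0.15;
#' two estuarine mixed-stock sampling years (n = 152 and 128) whose origin
#' and tactic proportions mirror the contributions reported for such
#' fisheries; a weak polygenic tactic signal (20 loci, delta = 0.25); and
#' GBS-like depth, kinship and paralog artifacts.
#'
#' @param seed master seed.
#' @param nLoci total locus count (default 5000, spread over 29
#'   chromosomes proportionally to length).
#' @param nChrom number of chromosomes.
#' @param tacticCount,tacticDelta tactic-signal size and shift.
#' @param meanDepth,depthDispersion,minCallDepth,sampleDepthSdLog depth
#'   model (mean read depth, negative-binomial size, minimum depth for a
#'   call, and the sdlog of the per-sample coverage multiplier).
#' @param kinPairs,dupLoci artifact counts.
#' @return A validated `SimConfig`.
#' @export
defaultSimConfig <- function(seed = 1L, nLoci = 5000L, nChrom = 29L,
                             tacticCount = 20L, tacticDelta = 0.25,
                             meanDepth = 28, depthDispersion = 3,
                             minCallDepth = 1, sampleDepthSdLog = 0.4,
                             kinPairs = 8L, dupLoci = 50L) {
  tree <- ape::read.tree(text = paste0(
    "((((GUE:0.003,DEL:0.003):0.012,MEL:0.020):0.008,BAL:0.030):0.006,",
    "(FEU:0.022,GEO:0.022):0.025,(CAN:0.100,NST:0.170):0.060);"))
  sizes <- c(FEU = 37L, MEL = 30L, GUE = 30L, DEL = 42L, CAN = 19L,
             BAL = 39L, GEO = 41L, NST = 10L)
  zero <- setNames(rep(0, 8), names(sizes))
  orig2020 <- zero
  orig2020[c("GUE", "DEL", "MEL", "CAN")] <- c(0.291, 0.616, 0.020, 0.073)
  orig2021 <- zero
  orig2021[c("GUE", "DEL", "MEL", "CAN")] <- c(0.349, 0.587, 0.040, 0.024)
  mix <- list(
    list(year = "2020", n = 152L, origin = orig2020,
         estuarineProb = setNames(rep(0.738, 8), names(sizes))),
    list(year = "2021", n = 128L, origin = orig2021,
         estuarineProb = setNames(rep(0.468, 8), names(sizes))))
  # estuarine fractions among the tactic-scored reference rivers
  refTactic <- c(FEU = NA, MEL = 7 / 27, GUE = 23 / 30, DEL = 31 / 42,
                 CAN = 1, BAL = NA, GEO = NA, NST = NA)
  lens <- rep(floor(3e9 / nChrom / 1e3) * 1e3, nChrom)
  per <- rep(nLoci %/% nChrom, nChrom)
  per[seq_len(nLoci %% nChrom)] <- per[seq_len(nLoci %% nChrom)] + 1L
  layout <- data.frame(
    chrom = sprintf("chr%02d", seq_len(nChrom)),
    lengthBp = lens, nLoci = as.integer(per))
  SimConfig(
    seed = as.integer(seed), nLoci = as.integer(nLoci),
    chromLayout = layout, popTree = tree, sampleSizes = sizes,
    mixtureDesign = mix, refTacticProps = refTactic,
    tacticLoci = c(count = as.integer(tacticCount), delta = tacticDelta),
    missingModel = c(meanDepth = meanDepth, dispersion = depthDispersion,
                     minCallDepth = minCallDepth,
                     sampleSdLog = sampleDepthSdLog),
    kinPairs = as.integer(kinPairs), dupLoci = as.integer(dupLoci),
    mafFloor = 0.05)
}

#' TruthTable: ground truth behind a simulated dataset
#'
#' @slot samples data.frame: sampleId, origin, tactic, year, kinDuplicate.
#' @slot loci data.frame: chrom, pos, ancestralFreq, tacticSignal,
#'   dupArtifact.
#' @slot popFreq matrix loci x populations of true frequencies.
#' @slot kin data.frame of planted kin pairs (id1, id2).
#' @aliases TruthTable-class
#' @export TruthTable
#' @exportClass TruthTable
TruthTable <- setClass("TruthTable", slots = c(
  samples = "data.frame", loci = "data.frame", popFreq = "matrix",
  kin = "data.frame"))

setValidity("TruthTable", function(object) {
  msg <- character()
  if (!is.logical(object@loci$tacticSignal) ||
      !is.logical(object@loci$dupArtifact))
    msg <- c(msg, "locus flags must be logical")
  f <- object@popFreq[!is.na(object@popFreq)]
  if (length(f) && (any(f < 0) || any(f > 1)))
    msg <- c(msg, "true frequencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", nrow(object@samples), "samples,",
      nrow(object@loci), "loci,", nrow(object@kin), "kin pairs\n")
})

# deterministic per-stage sub-seed derived from the master seed
subSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}
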