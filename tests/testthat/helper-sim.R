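# small fixture builders used across the suite

# GenotypeExperiment from a bare loci x samples matrix
gmFromMatrix <- function(d, chrom = NULL, pos = NULL, group = NULL,
                         tactic = NULL, year = NULL, depth = NULL,
                         refDepth = NULL, altDepth = NULL) {
  d <- as.matrix(d)
  L <- nrow(d); n <- ncol(d)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(group)) group <- rep("P1", n)
  GenotypeExperiment(
    dosage = d, chrom = chrom, pos = pos,
    ref = rep("A", L), alt = rep("G", L),
    sampleId = sprintf("s%03d", seq_len(n)), group = group,
    tactic = tactic, year = year, depth = depth,
    refDepth = refDepth, altDepth = altDepth)
}

# custom SimConfig over an arbitrary tree
simpleConfig <- function(seed, treeText, sizes, nLoci = 1000L,
                         nChrom = 4L, mixture = list(),
                         tacticCount = 0L, tacticDelta = 0,
                         kinPairs = 0L, dupLoci = 0L,
                         minCallDepth = 1) {
  per <- rep(nLoci %/% nChrom, nChrom)
  per[seq_len(nLoci %% nChrom)] <- per[seq_len(nLoci %% nChrom)] + 1L
  SimConfig(
    seed = as.integer(seed), nLoci = as.integer(nLoci),
    chromLayout = data.frame(chrom = sprintf("chr%d", seq_len(nChrom)),
                             lengthBp = 1e8, nLoci = as.integer(per)),
    popTree = ape::read.tree(text = treeText),
    sampleSizes = sizes, mixtureDesign = mixture,
    refTacticProps = setNames(rep(NA_real_, length(sizes)),
                              names(sizes)),
    tacticLoci = c(count = as.integer(tacticCount),
                   delta = tacticDelta),
    missingModel = c(meanDepth = 25, dispersion = 4,
                     minCallDepth = minCallDepth, sampleSdLog = 0.3),
    kinPairs = as.integer(kinPairs), dupLoci = as.integer(dupLoci),
    mafFloor = 0.05)
}

twoPopConfig <- function(seed, Fdrift, nLoci = 2000L, n = 50L, ...) {
  simpleConfig(seed,
               sprintf("(A:%.6f,B:%.6f);", Fdrift, Fdrift),
               c(A = as.integer(n), B = as.integer(n)),
               nLoci = as.integer(nLoci), ...)
}

# flat-structure sample with a two-tactic allele-frequency shift at the
# first nSig loci; the configuration under which the scan's power and
# FDR properties are assessed
tacticScanSim <- function(seed, L = 100L, nSig = 20L, n = 270L,
                          delta = 0.25) {
  set.seed(seed)
  p <- runif(L, 0.2, 0.8)
  tac <- rep(c("estuarine", "marine"), length.out = n)
  d <- sapply(seq_len(n), function(j) {
    pj <- p
    shift <- if (tac[j] == "estuarine") delta / 2 else -delta / 2
    pj[seq_len(nSig)] <- pmin(pmax(pj[seq_len(nSig)] + shift, 0.01),
                              0.99)
    rbinom(L, 2, pj)
  })
  chrom <- sort(rep(sprintf("chr%d", 1:4), length.out = L))
  gm <- gmFromMatrix(d, chrom = chrom, pos = seq_len(L) * 100L,
                     group = rep("P", n), tactic = tac)
  list(gm = gm, signal = lociIds(gm)[seq_len(nSig)])
}

# true allele-frequency table from a simulation truth
truthFreqTable <- function(ref) {
  AlleleFreqTable(
    freq = ref$truth@popFreq,
    nCalled = matrix(10000L, nrow(ref$truth@popFreq),
                     ncol(ref$truth@popFreq),
                     dimnames = dimnames(ref$truth@popFreq)),
    loci = SummarizedExperiment::rowRanges(ref$gm))
}
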