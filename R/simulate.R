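#' Simulate reference-population genotypes under Balding-Nichols drift
#'
#' Draws ancestral allele frequencies, lets them drift down the
#' configured population tree (child frequency ~ Beta(p(1-F)/F,
#' (1-p)(1-F)/F) along each branch of drift F), then draws diploid
#' genotypes as Binomial(2, p) for each sample in each source population.
#' Loci flagged as tactic-associated get their within-population
#' frequency split by +/- delta/2 between estuarine and marine fish
#' (clipped to [0.01, 0.99]). Fully deterministic given `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return `list(gm = GenotypeExperiment, truth = TruthTable)`.
#' @export
simulateReference <- function(config) {
  methods::validObject(config)
  tree <- config@popTree
  L <- config@nLoci
  set.seed(subSeed(config@seed, 1L))
  # ancestral minor-allele frequencies follow a decreasing (GBS-like)
  # folded spectrum; a uniform spectrum would put typical observed
  # heterozygosity near 0.35, above the QC ceiling of 0.3
  maf <- config@mafFloor + (0.5 - config@mafFloor) * runif(L)^3
  anc <- ifelse(runif(L) < 0.5, maf, 1 - maf)
  popFreq <- driftDown(tree, anc)
  layout <- config@chromLayout
  chrom <- rep(layout$chrom, layout$nLoci)
  pos <- unlist(lapply(seq_len(nrow(layout)), function(i)
    sort(sample.int(layout$lengthBp[i], layout$nLoci[i]))))
  tacticIdx <- sort(sample.int(L, config@tacticLoci[["count"]]))

  sizes <- config@sampleSizes
  pops <- names(sizes)
  ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%03d", p, seq_len(sizes[[p]]))))
  group <- rep(pops, sizes)
  tac <- vapply(seq_along(group), function(i) {
    pe <- config@refTacticProps[[group[i]]]
    if (is.na(pe)) NA_character_
    else if (runif(1) < pe) "estuarine" else "marine"
  }, character(1))

  dos <- matrix(NA_integer_, L, length(ids))
  delta <- config@tacticLoci[["delta"]]
  for (j in seq_along(ids)) {
    p <- popFreq[, group[j]]
    if (!is.na(tac[j]) && delta > 0) {
      shift <- if (tac[j] == "estuarine") delta / 2 else -delta / 2
      p[tacticIdx] <- pmin(pmax(p[tacticIdx] + shift, 0.01), 0.99)
    }
    dos[, j] <- rbinom(L, 2L, p)
  }
  gm <- GenotypeExperiment(
    dosage = dos, chrom = chrom, pos = pos,
    ref = rep("A", L), alt = rep("G", L),
    sampleId = ids, group = group, tactic = tac,
    year = rep(NA_character_, length(ids)))
  truth <- TruthTable(
    samples = data.frame(sampleId = ids, origin = group, tactic = tac,
                         year = NA_character_, kinDuplicate = FALSE,
                         stringsAsFactors = FALSE),
    loci = data.frame(chrom = chrom, pos = pos, ancestralFreq = anc,
                      tacticSignal = seq_len(L) %in% tacticIdx,
                      dupArtifact = FALSE, stringsAsFactors = FALSE),
    popFreq = `dimnames<-`(popFreq, list(paste0(chrom, ":", pos),
                                         colnames(popFreq))),
    kin = data.frame(id1 = character(), id2 = character(),
                     stringsAsFactors = FALSE))
  # truth rows follow the canonical (chrom, pos) locus order of gm
  o <- order(truth@loci$chrom, truth@loci$pos)
  truth@loci <- truth@loci[o, , drop = FALSE]
  truth@popFreq <- truth@popFreq[o, , drop = FALSE]
  list(gm = gm, truth = truth)
}

# Balding-Nichols drift of a frequency vector down every branch of a tree;
# returns loci x tips matrix of leaf frequencies.
driftDown <- function(tree, anc) {
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  freqs <- vector("list", nTip + tree$Nnode)
  freqs[[root]] <- anc
  # edges in preorder so a parent is visited before its children
  for (e in ape::reorder.phylo(tree, "postorder")$edge[rev(seq_len(
         nrow(tree$edge))), , drop = FALSE] |> asplit(1)) {
    parent <- e[1]; child <- e[2]
    Fdrift <- tree$edge.length[which(tree$edge[, 1] == parent &
                                     tree$edge[, 2] == child)]
    p <- freqs[[parent]]
    freqs[[child]] <- rbeta(length(p), p * (1 - Fdrift) / Fdrift,
                            (1 - p) * (1 - Fdrift) / Fdrift)
  }
  out <- do.call(cbind, freqs[seq_len(nTip)])
  colnames(out) <- tree$tip.label
  out
}

#' Simulate an estuarine mixed-stock sample
#'
#' For every sampling year in the design, draws each fish's river of
#' origin from the year's origin-proportion vector, a life-history tactic
#' from the per-origin estuarine probability, and genotypes from the
#' origin population's true allele frequencies (with the tactic shift at
#' tactic-signal loci when `truth` is supplied).
#'
#' @param config a [SimConfig-class].
#' @param refFreqs an [AlleleFreqTable-class] of true or estimated
#'   per-population frequencies (loci in canonical order).
#' @param truth optional reference [TruthTable-class]; enables the tactic
#'   signal in mixture genotypes.
#' @return `list(gm = GenotypeExperiment, truth = TruthTable)`.
#' @export
simulateMixture <- function(config, refFreqs, truth = NULL) {
  set.seed(subSeed(config@seed, 2L))
  freq <- refFreqs@freq
  pops <- colnames(freq)
  delta <- config@tacticLoci[["delta"]]
  tacticIdx <- if (!is.null(truth)) which(truth@loci$tacticSignal)
               else integer()
  ids <- character(); origin <- character(); tac <- character()
  year <- character(); cols <- list()
  for (yr in config@mixtureDesign) {
    if (yr$n <= 0L) stop("mixture year with n = 0")
    if (!all(names(yr$origin)[yr$origin > 0] %in% pops))
      stop("origin proportions reference unknown populations")
    org <- sample(names(yr$origin), yr$n, replace = TRUE,
                  prob = yr$origin)
    for (j in seq_len(yr$n)) {
      p <- freq[, org[j]]
      tj <- if (runif(1) < yr$estuarineProb[[org[j]]]) "estuarine"
            else "marine"
      if (length(tacticIdx) && delta > 0) {
        shift <- if (tj == "estuarine") delta / 2 else -delta / 2
        p[tacticIdx] <- pmin(pmax(p[tacticIdx] + shift, 0.01), 0.99)
      }
      cols[[length(cols) + 1L]] <- rbinom(length(p), 2L, p)
      ids <- c(ids, sprintf("KOK%s_%03d", yr$year, j))
      origin <- c(origin, org[j]); tac <- c(tac, tj)
      year <- c(year, yr$year)
    }
  }
  dos <- do.call(cbind, cols)
  gr <- refFreqs@loci
  gm <- GenotypeExperiment(
    dosage = dos, chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    ref = gr$ref, alt = gr$alt,
    sampleId = ids, group = rep("KOK", length(ids)),
    tactic = tac, year = year)
  mtruth <- TruthTable(
    samples = data.frame(sampleId = ids, origin = origin, tactic = tac,
                         year = year, kinDuplicate = FALSE,
                         stringsAsFactors = FALSE),
    loci = if (!is.null(truth)) truth@loci else
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 pos = GenomicRanges::start(gr),
                 ancestralFreq = NA_real_, tacticSignal = FALSE,
                 dupArtifact = FALSE, stringsAsFactors = FALSE),
    popFreq = freq,
    kin = data.frame(id1 = character(), id2 = character(),
                     stringsAsFactors = FALSE))
  list(gm = gm, truth = mtruth)
}

#' Inject sequencing-style artifacts into simulated genotypes
#'
#' Adds (a) a negative-binomial per-genotype read depth, setting calls
#' below the configured minimum depth to missing and emitting ref/alt
#' allele depths with Beta(20,20) allelic-balance noise at heterozygotes;
#' (b) merged-paralog loci: pairs of loci whose reads are summed into one
#' apparent locus, producing excess heterozygosity and skewed read
#' ratios (the partner locus is removed and the merged locus flagged in
#' the truth table); (c) planted kin: duplicated samples with 5% of
#' genotypes re-drawn from the origin population's frequencies.
#'
#' @param gm a `GenotypeExperiment` from [simulateReference()] or
#'   [simulateMixture()].
#' @param config a [SimConfig-class].
#' @param truth the matching [TruthTable-class].
#' @return `list(gm = GenotypeExperiment, truth = TruthTable)`.
#' @export
injectArtifacts <- function(gm, config, truth) {
  set.seed(subSeed(config@seed, 3L))
  if (config@dupLoci > nrow(gm) %/% 2L)
    stop("dupLoci exceeds half the locus count")
  d <- dosage(gm)
  L <- nrow(d); N <- ncol(d)

  # (b) merged paralogs first, on clean genotypes
  dupFlag <- rep(FALSE, L)
  drop <- integer()
  if (config@dupLoci > 0L) {
    pick <- sample.int(L, 2L * config@dupLoci)
    keepL <- pick[seq_len(config@dupLoci)]
    dropL <- pick[config@dupLoci + seq_len(config@dupLoci)]
    dupFlag[keepL] <- TRUE
    drop <- dropL
    mergedFrom <- dropL
  } else keepL <- integer()

  # (a) depths and allele depths on the (possibly merged) genotype table
  mm <- config@missingModel
  sdlog <- if ("sampleSdLog" %in% names(mm)) mm[["sampleSdLog"]] else 0
  # per-sample coverage multiplier: library-size heterogeneity
  mult <- if (sdlog > 0)
    exp(stats::rnorm(N, -sdlog^2 / 2, sdlog)) else rep(1, N)
  dp <- matrix(rnbinom(L * N, mu = rep(mult * mm[["meanDepth"]],
                                       each = L),
                       size = mm[["dispersion"]]), L, N)
  refd <- matrix(0L, L, N); altd <- matrix(0L, L, N)
  het <- which(d == 1L)
  hom0 <- which(d == 0L); hom2 <- which(d == 2L)
  refd[hom0] <- dp[hom0]
  altd[hom2] <- dp[hom2]
  bal <- rbeta(length(het), 20, 20)
  refd[het] <- rbinom(length(het), dp[het], bal)
  altd[het] <- dp[het] - refd[het]

  # merge reads of paralog pairs and re-call the merged locus
  if (length(keepL)) {
    refd[keepL, ] <- refd[keepL, ] + refd[mergedFrom, ]
    altd[keepL, ] <- altd[keepL, ] + altd[mergedFrom, ]
    dp[keepL, ] <- dp[keepL, ] + dp[mergedFrom, ]
    tot <- dp[keepL, , drop = FALSE]
    ar <- altd[keepL, , drop = FALSE] / pmax(tot, 1L)
    call <- matrix(1L, length(keepL), N)
    call[ar < 0.15] <- 0L
    call[ar > 0.85] <- 2L
    d[keepL, ] <- call
  }
  miss <- dp < mm[["minCallDepth"]]
  d[miss] <- NA_integer_

  keep <- setdiff(seq_len(L), drop)
  truth@loci <- truth@loci[keep, , drop = FALSE]
  truth@loci$dupArtifact <- dupFlag[keep]
  truth@popFreq <- truth@popFreq[keep, , drop = FALSE]
  d <- d[keep, , drop = FALSE]; dp <- dp[keep, , drop = FALSE]
  refd <- refd[keep, , drop = FALSE]; altd <- altd[keep, , drop = FALSE]
  gr <- SummarizedExperiment::rowRanges(gm)[keep]
  cd <- SummarizedExperiment::colData(gm)

  # (c) planted kin duplicates
  ids <- cd$sampleId; group <- cd$group
  tac <- cd$tactic; year <- cd$year
  kin <- truth@samples[0, c("sampleId", "sampleId")]
  names(kin) <- c("id1", "id2")
  if (config@kinPairs > 0L) {
    src <- sample.int(N, config@kinPairs)
    for (s in src) {
      newId <- paste0(ids[s], "_kin")
      col <- d[, s]
      redraw <- which(runif(length(col)) < 0.05)
      origin <- truth@samples$origin[
        match(cd$sampleId[s], truth@samples$sampleId)]
      pf <- truth@popFreq[, origin]
      col[redraw] <- rbinom(length(redraw), 2L, pf[redraw])
      d <- cbind(d, col)
      dpc <- rnbinom(nrow(d), mu = mm[["meanDepth"]],
                     size = mm[["dispersion"]])
      dp <- cbind(dp, dpc)
      refc <- rbinom(nrow(d), dpc, 0.5)   # heterozygote-style split
      refc[!is.na(col) & col == 0L] <- dpc[!is.na(col) & col == 0L]
      refc[!is.na(col) & col == 2L] <- 0L
      refc[is.na(col)] <- 0L
      refd <- cbind(refd, as.integer(refc))
      altd <- cbind(altd, as.integer(dpc - refc))
      ids <- c(ids, newId); group <- c(group, group[s])
      tac <- c(tac, tac[s]); year <- c(year, year[s])
      kin <- rbind(kin, data.frame(id1 = cd$sampleId[s], id2 = newId,
                                   stringsAsFactors = FALSE))
      truth@samples <- rbind(truth@samples, data.frame(
        sampleId = newId, origin = group[s],
        tactic = tac[length(tac)], year = year[length(year)],
        kinDuplicate = TRUE, stringsAsFactors = FALSE))
    }
  }
  truth@kin <- kin
  out <- GenotypeExperiment(
    dosage = d, chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr), ref = gr$ref, alt = gr$alt,
    sampleId = ids, group = group, tactic = tac, year = year,
    depth = dp, refDepth = refd, altDepth = altd)
  list(gm = out, truth = truth)
}

#' Simulate a closed Wright-Fisher population
#'
#' Forward-simulates `gens` generations of a diploid population of
#' constant size `N` with free recombination between loci (each
#' offspring gamete picks one parental allele per locus independently),
#' then returns the whole final generation as a `GenotypeExperiment`.
#' Unlinked-locus linkage disequilibrium accumulates towards its drift
#' equilibrium within a few generations, which makes this the natural
#' truth-bearing input for the LD effective-population-size estimator.
#'
#' @param seed RNG seed.
#' @param N diploid population size (the true Ne under random mating).
#' @param nLoci locus count.
#' @param gens generations simulated.
#' @param nChrom chromosomes the loci are spread over.
#' @param pRange range of founding allele frequencies.
#' @return a `GenotypeExperiment` with one group `"WF"`.
#' @export
simulateWrightFisher <- function(seed, N = 50, nLoci = 300, gens = 8,
                                 nChrom = 6, pRange = c(0.2, 0.8)) {
  set.seed(seed)
  L <- nLoci
  p <- runif(L, pRange[1], pRange[2])
  hap <- matrix(rbinom(2 * N * L, 1, rep(p, each = 2 * N)), 2 * N, L)
  for (g in seq_len(gens)) {
    newhap <- matrix(0L, 2 * N, L)
    for (i in seq_len(2 * N)) {
      par <- sample.int(N, 1)
      pick <- runif(L) < 0.5
      newhap[i, ] <- ifelse(pick, hap[2 * par - 1, ], hap[2 * par, ])
    }
    hap <- newhap
  }
  d <- t(hap[seq(1, 2 * N, 2), ] + hap[seq(2, 2 * N, 2), ])
  per <- rep(L %/% nChrom, nChrom)
  per[seq_len(L %% nChrom)] <- per[seq_len(L %% nChrom)] + 1L
  chrom <- rep(sprintf("chr%02d", seq_len(nChrom)), per)
  pos <- unlist(lapply(per, function(k) seq_len(k) * 1000L))
  GenotypeExperiment(
    dosage = d, chrom = chrom, pos = pos,
    ref = rep("A", L), alt = rep("G", L),
    sampleId = sprintf("wf_%03d", seq_len(N)),
    group = rep("WF", N))
}

#' Geographic distances implied by the drift tree
#'
#' Converts cophenetic (cumulative branch) distances on the configured
#' population tree into kilometres by scaling the maximum to `maxKm`, so
#' that a genuinely linear relation between linearised FST and distance
#' exists for the isolation-by-distance machinery to recover.
#'
#' @param config a [SimConfig-class].
#' @param maxKm distance assigned to the most separated pair.
#' @return square symmetric matrix (km) with population dimnames.
#' @export
treeDistancesKm <- function(config, maxKm = 1500) {
  d <- ape::cophenetic.phylo(config@popTree)
  d * (maxKm / max(d))
}

#' Write a simulated study to disk
#'
#' Emits a plain-text VCFv4.2 (GT:DP:AD when depths are present), a
#' sample-to-population map TSV, a tactic TSV (sampleId, tactic, year), a
#' square distance-matrix TSV, and truth TSVs. Files round-trip through
#' [readVcfGenotypes()] losslessly.
#'
#' @param gm a `GenotypeExperiment`.
#' @param truth the matching [TruthTable-class] (optional).
#' @param dir output directory (created if needed).
#' @param distances optional square km matrix (e.g. [treeDistancesKm()]).
#' @return invisibly, the named vector of file paths written.
#' @export
writeStudy <- function(gm, truth = NULL, dir, distances = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             tactic = file.path(dir, "tactics.tsv"))
  writeVcfText(gm, paths[["vcf"]])
  cd <- SummarizedExperiment::colData(gm)
  write.table(data.frame(sampleId = cd$sampleId, population = cd$group),
              paths[["popmap"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sampleId = cd$sampleId, tactic = cd$tactic,
                         year = cd$year),
              paths[["tactic"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(distances)) {
    paths["distances"] <- file.path(dir, "distances.tsv")
    write.table(distances, paths[["distances"]], sep = "\t",
                quote = FALSE, col.names = NA)
  }
  if (!is.null(truth)) {
    paths["truthSamples"] <- file.path(dir, "truth_samples.tsv")
    paths["truthLoci"] <- file.path(dir, "truth_loci.tsv")
    write.table(truth@samples, paths[["truthSamples"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth@loci, paths[["truthLoci"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
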