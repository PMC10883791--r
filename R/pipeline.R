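#' Default pipeline configuration
#'
#' Returns the full configuration list driving [runPipeline()]:
#' paths, filter thresholds, structure options (bootstraps,
#' permutations, IBD exclusions), outlier options, GSI options (panel
#' sizes, training/locus proportions, iteration and sweep counts, odds
#' ratio) and the global seed. Any entry can be overridden via a YAML
#' file ([readPipelineConfig()]) or the `overrides` list.
#'
#' @param outDir output directory.
#' @param seed global seed; per-stage sub-seeds derive from it.
#' @param overrides named list merged over the defaults.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(outDir = "popgsi_out", seed = 1L,
                                  overrides = list()) {
  cfg <- list(
    paths = list(vcf = NULL, popmap = NULL, tactics = NULL,
                 distances = NULL, outDir = outDir),
    seed = as.integer(seed),
    sim = list(nLoci = 5000L, nChrom = 29L),
    filters = list(),
    structure = list(nBoot = 1000L, nPerm = 1000L,
                     ibdExclude = list(c("NST"), c("NST", "CAN")),
                     migrateBoot = 100L),
    outliers = list(K = NULL, kMax = 20L, qThreshold = 0.01,
                    rivers = c("MEL", "GUE", "DEL")),
    gsi = list(panelSizes = c(500L, 1000L, 2000L),
               trainProps = c(0.7, 0.9), lociProps = c(0.5, 1.0),
               nIter = 100L, nSweeps = 2000L, burnIn = 100L,
               oddsRatio = 10))
  utils::modifyList(cfg, overrides)
}

#' @rdname defaultPipelineConfig
#' @param path YAML file whose entries override the defaults.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  defaultPipelineConfig(overrides = y)
}

stageFile <- function(cfg, name) file.path(cfg$paths$outDir, name)

needsStage <- function(cfg, file, producer) {
  p <- stageFile(cfg, file)
  if (!file.exists(p))
    stop(sprintf("missing '%s'; run the '%s' stage first", file,
                 producer))
  p
}

loadFiltered <- function(cfg) {
  vcf <- needsStage(cfg, "filtered.vcf", "filter")
  readVcfGenotypes(vcf, stageFile(cfg, "popmap.tsv"),
                   stageFile(cfg, "tactics.tsv"))
}

writeTsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Config-driven orchestration of the whole chain. Subcommands:
#' `simulate` (synthetic study written to the output directory),
#' `filter` (QC cascade), `diversity` (Ho/He/F and LD-Ne per river),
#' `structure` (PCA, pairwise FST, IBD models, AMOVA, migration),
#' `outliers` (tactic outlier scan and FST contrast), `panel`
#' (AFD-balanced panels), `assign` (self-assignment sweeps and panel
#' choice), `mix` (mixture composition, odds filter, contributions),
#' `report` (collated summary), or `all`. Each stage writes TSV/JSON
#' artifacts plus a manifest recording inputs, config hash, seed and
#' versions; a stage whose inputs are missing fails with the name of
#' the producing subcommand.
#'
#' @param subcommand one of the stage names above.
#' @param config a configuration list from [defaultPipelineConfig()] /
#'   [readPipelineConfig()].
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(subcommand = "all",
                        config = defaultPipelineConfig()) {
  stages <- c("simulate", "filter", "diversity", "structure",
              "outliers", "panel", "assign", "mix", "report")
  if (!subcommand %in% c(stages, "all"))
    stop("unknown subcommand: ", subcommand)
  dir.create(config$paths$outDir, recursive = TRUE,
             showWarnings = FALSE)
  todo <- if (subcommand == "all") stages else subcommand
  artifacts <- list()
  for (st in todo)
    artifacts[[st]] <- switch(st,
      simulate = stageSimulate(config),
      filter = stageFilter(config),
      diversity = stageDiversity(config),
      structure = stageStructure(config),
      outliers = stageOutliers(config),
      panel = stagePanel(config),
      assign = stageAssign(config),
      mix = stageMix(config),
      report = stageReport(config))
  writeManifest(config, todo, artifacts)
  invisible(artifacts)
}

writeManifest <- function(cfg, stages, artifacts) {
  cfgFile <- stageFile(cfg, "config.json")
  jsonlite::write_json(cfg, cfgFile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    stages = stages,
    seed = cfg$seed,
    subSeeds = setNames(lapply(seq_along(stages), function(i)
      subSeed(cfg$seed, 10L + i)), stages),
    configHash = unname(tools::md5sum(cfgFile)),
    packageVersion = as.character(packageVersion("popGSI")),
    rVersion = R.version.string,
    artifacts = lapply(artifacts, function(a) unname(unlist(a))))
  jsonlite::write_json(manifest, stageFile(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

stageSimulate <- function(cfg) {
  sc <- defaultSimConfig(seed = cfg$seed, nLoci = cfg$sim$nLoci,
                         nChrom = cfg$sim$nChrom)
  ref <- simulateReference(sc)
  afTrue <- AlleleFreqTable(
    freq = ref$truth@popFreq,
    nCalled = matrix(1e6L, nrow(ref$truth@popFreq),
                     ncol(ref$truth@popFreq)),
    loci = SummarizedExperiment::rowRanges(ref$gm))
  mix <- simulateMixture(sc, afTrue, ref$truth)
  combined <- combineStudies(ref, mix)
  art <- injectArtifacts(combined$gm, sc, combined$truth)
  writeStudy(art$gm, art$truth, cfg$paths$outDir,
             distances = treeDistancesKm(sc))
}

# stack reference and mixture samples over the shared loci
combineStudies <- function(ref, mix) {
  stopifnot(identical(lociIds(ref$gm), lociIds(mix$gm)))
  gr <- SummarizedExperiment::rowRanges(ref$gm)
  cdR <- SummarizedExperiment::colData(ref$gm)
  cdM <- SummarizedExperiment::colData(mix$gm)
  gm <- GenotypeExperiment(
    dosage = cbind(dosage(ref$gm), dosage(mix$gm)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr), ref = gr$ref, alt = gr$alt,
    sampleId = c(cdR$sampleId, cdM$sampleId),
    group = c(cdR$group, cdM$group),
    tactic = c(cdR$tactic, cdM$tactic),
    year = c(cdR$year, cdM$year))
  truth <- ref$truth
  truth@samples <- rbind(ref$truth@samples, mix$truth@samples)
  list(gm = gm, truth = truth)
}

stageFilter <- function(cfg) {
  if (!is.null(cfg$paths$vcf)) {
    vcf <- cfg$paths$vcf; popmap <- cfg$paths$popmap
    tactics <- cfg$paths$tactics
  } else {
    vcf <- needsStage(cfg, "genotypes.vcf", "simulate")
    popmap <- stageFile(cfg, "popmap.tsv")
    tactics <- stageFile(cfg, "tactics.tsv")
  }
  gm <- readVcfGenotypes(vcf, popmap, tactics)
  gm <- standardFilterCascade(gm, cfg$filters)
  out <- stageFile(cfg, "filtered.vcf")
  writeVcfText(gm, out)
  writeFilterReport(filterReport(gm),
                    tsv = stageFile(cfg, "filter_report.tsv"),
                    json = stageFile(cfg, "filter_report.json"))
  ibm <- ibmCheck(gm)
  writeTsv(data.frame(metric = "ibm_silhouette",
                      value = ibm$silhouette, status = ibm$status),
           stageFile(cfg, "ibm_check.tsv"))
  c(out, stageFile(cfg, "filter_report.tsv"))
}

refOnly <- function(gm) gm[, popGroups(gm) != "KOK"]

stageDiversity <- function(cfg) {
  gm <- refOnly(loadFiltered(cfg))
  div <- diversity(gm)
  f1 <- writeTsv(div$perGroup, stageFile(cfg, "diversity_groups.tsv"))
  nes <- lapply(sort(unique(as.character(popGroups(gm)))), function(g) {
    sub <- gm[, popGroups(gm) == g]
    if (ncol(sub) < 10)
      return(data.frame(group = g, ne = NA, ciLow = NA, ciHigh = NA,
                        nPairs = NA, note = "n too small"))
    ne <- tryCatch(suppressWarnings(ldNe(gm, g)), error = function(e) NULL)
    if (is.null(ne))
      return(data.frame(group = g, ne = NA, ciLow = NA, ciHigh = NA,
                        nPairs = NA, note = "failed"))
    data.frame(group = g, ne = ne@ne, ciLow = ne@ci[1],
               ciHigh = ne@ci[2], nPairs = ne@nComparisons, note = "")
  })
  f2 <- writeTsv(do.call(rbind, nes), stageFile(cfg, "ne_ld.tsv"))
  c(f1, f2)
}

stageStructure <- function(cfg) {
  gm <- refOnly(loadFiltered(cfg))
  pc <- pcaGenotypes(gm, nAxes = 4)
  f1 <- writeTsv(data.frame(sampleId = rownames(pc$scores),
                            group = as.character(popGroups(gm)),
                            pc$scores),
                 stageFile(cfg, "pca_scores.tsv"))
  fst <- pairwiseFst(gm, nBoot = cfg$structure$nBoot,
                     seed = subSeed(cfg$seed, 21L))
  pairs <- t(combn(fst@groups, 2))
  f2 <- writeTsv(data.frame(
    a = pairs[, 1], b = pairs[, 2], theta = fst@theta[pairs],
    ciLow = fst@ciLow[pairs], ciHigh = fst@ciHigh[pairs],
    p = fst@pValue[pairs]), stageFile(cfg, "fst_pairs.tsv"))
  arts <- c(f1, f2)
  distPath <- stageFile(cfg, "distances.tsv")
  if (file.exists(distPath)) {
    dm <- readDistanceMatrix(distPath)
    rows <- list()
    for (ex in cfg$structure$ibdExclude) {
      fits <- ibdFit(fst, dm, exclude = unlist(ex))
      for (f in fits)
        rows[[length(rows) + 1L]] <- data.frame(
          excluded = paste(unlist(ex), collapse = "+"),
          model = f@model, n = f@nPairs, AICc = f@aicc,
          adjR2 = f@adjR2, p = f@pSlope)
    }
    arts <- c(arts, writeTsv(do.call(rbind, rows),
                             stageFile(cfg, "ibd_models.tsv")))
  }
  tac <- tactics(gm)
  hasTac <- !is.na(tac)
  if (sum(hasTac) >= 12 &&
      length(unique(popGroups(gm)[hasTac])) >= 2) {
    sub <- gm[, hasTac]
    am1 <- amovaTwoLevel(sub, "group", "tactic",
                         nPerm = cfg$structure$nPerm,
                         seed = subSeed(cfg$seed, 22L))
    am2 <- amovaTwoLevel(sub, "tactic", "group",
                         nPerm = cfg$structure$nPerm,
                         seed = subSeed(cfg$seed, 23L))
    tab <- rbind(cbind(model = "river/tactic", am1@table),
                 cbind(model = "tactic/river", am2@table))
    arts <- c(arts, writeTsv(tab, stageFile(cfg, "amova.tsv")))
  }
  mg <- divMigrate(gm, nBoot = cfg$structure$migrateBoot,
                   seed = subSeed(cfg$seed, 24L))
  edges <- which(upper.tri(mg@m) | lower.tri(mg@m), arr.ind = TRUE)
  arts <- c(arts, writeTsv(data.frame(
    from = rownames(mg@m)[edges[, 1]],
    to = colnames(mg@m)[edges[, 2]],
    m = mg@m[edges]), stageFile(cfg, "migration_edges.tsv")))
  arts
}

stageOutliers <- function(cfg) {
  gm <- loadFiltered(cfg)
  sel <- popGroups(gm) %in% cfg$outliers$rivers & !is.na(tactics(gm))
  if (sum(sel) < 10) stop("too few tactic-labelled samples for the scan")
  sub <- gm[, sel]
  K <- cfg$outliers$K
  if (is.null(K)) K <- as.integer(screeSelectK(sub, cfg$outliers$kMax))
  scan <- pcadaptScan(sub, K = K, qThreshold = cfg$outliers$qThreshold)
  f1 <- writeTsv(data.frame(locus = scan@loci, d2 = scan@d2,
                            p = scan@p, q = scan@q,
                            significant = scan@significant),
                 stageFile(cfg, "outlier_scan.tsv"))
  outSet <- scan@loci[scan@significant]
  res <- if (length(outSet))
    tacticFstContrast(sub, outSet)
  else list(thetaAll = multilocusFst(sub, tactics(sub)),
            thetaOutliers = NA_real_, ratio = NA_real_)
  f2 <- writeTsv(data.frame(K = K, lambda = scan@lambda,
                            nOutliers = length(outSet),
                            thetaAll = res$thetaAll,
                            thetaOutliers = res$thetaOutliers,
                            ratio = res$ratio),
                 stageFile(cfg, "tactic_contrast.tsv"))
  c(f1, f2)
}

stagePanel <- function(cfg) {
  gm <- refOnly(loadFiltered(cfg))
  af <- alleleFreqs(gm)
  arts <- character()
  for (sz in cfg$gsi$panelSizes) {
    ps <- buildBalancedPanel(af, min(sz, nrow(af@freq)))
    rows <- do.call(rbind, lapply(names(ps@pairLists), function(pr) {
      ids <- ps@pairLists[[pr]]
      if (!length(ids)) return(NULL)
      data.frame(pair = pr, rank = seq_along(ids), locus = ids)
    }))
    arts <- c(arts,
              writeTsv(rows, stageFile(cfg, sprintf("panel_%d_pairs.tsv",
                                                    sz))),
              writeTsv(data.frame(locus = ps@union),
                       stageFile(cfg, sprintf("panel_%d_union.tsv", sz))))
  }
  arts
}

stageAssign <- function(cfg) {
  gm <- refOnly(loadFiltered(cfg))
  cvs <- list()
  arts <- character()
  for (sz in cfg$gsi$panelSizes) {
    unionFile <- needsStage(cfg, sprintf("panel_%d_union.tsv", sz),
                            "panel")
    panel <- read.table(unionFile, header = TRUE,
                        stringsAsFactors = FALSE)$locus
    cv <- selfAssignCv(gm, panel, trainProps = cfg$gsi$trainProps,
                       lociProps = cfg$gsi$lociProps,
                       nIter = cfg$gsi$nIter,
                       seed = subSeed(cfg$seed, 31L))
    cvs[[as.character(sz)]] <- cv
    arts <- c(arts, writeTsv(
      data.frame(size = sz,
                 population = colnames(cv@accuracy),
                 meanAccuracy = colMeans(cv@accuracy, na.rm = TRUE),
                 sdAccuracy = apply(cv@accuracy, 2, sd, na.rm = TRUE)),
      stageFile(cfg, sprintf("assign_cv_%d.tsv", sz))))
  }
  chosen <- pickPanel(cvs)
  arts <- c(arts, writeTsv(data.frame(chosenPanelSize = chosen),
                           stageFile(cfg, "panel_choice.tsv")))
  arts
}

stageMix <- function(cfg) {
  gm <- loadFiltered(cfg)
  ref <- refOnly(gm)
  mix <- gm[, popGroups(gm) == "KOK"]
  choice <- needsStage(cfg, "panel_choice.tsv", "assign")
  sz <- read.table(choice, header = TRUE)$chosenPanelSize[1]
  unionFile <- needsStage(cfg, sprintf("panel_%d_union.tsv", sz),
                          "panel")
  panel <- read.table(unionFile, header = TRUE,
                      stringsAsFactors = FALSE)$locus
  mr <- mixtureEstimate(ref, mix, panel, nSweeps = cfg$gsi$nSweeps,
                        burnIn = cfg$gsi$burnIn,
                        seed = subSeed(cfg$seed, 32L))
  mr <- oddsFilter(mr, cfg$gsi$oddsRatio)
  f1 <- writeTsv(data.frame(sampleId = rownames(mr@posterior),
                            year = mr@year, kept = mr@kept,
                            round(mr@posterior, 6)),
                 stageFile(cfg, "mixture_posterior.tsv"))
  f2 <- writeTsv(mr@mixingProps, stageFile(cfg, "mixing_props.tsv"))
  cd <- SummarizedExperiment::colData(mix)
  contrib <- contributionSummary(mr, data.frame(
    sampleId = cd$sampleId, tactic = cd$tactic, year = cd$year))
  f3 <- writeTsv(as.data.frame(contrib$riverPercent),
                 stageFile(cfg, "contrib_river.tsv"))
  arts <- c(f1, f2, f3)
  if (!is.null(contrib$tacticPercent))
    arts <- c(arts, writeTsv(as.data.frame(contrib$tacticPercent),
                             stageFile(cfg, "contrib_tactic.tsv")))
  tests <- data.frame(
    test = c("river_homogeneity", "tactic_homogeneity"),
    chisq = c(if (!is.null(contrib$riverTest))
      unname(contrib$riverTest$statistic) else NA,
      if (!is.null(contrib$tacticTest))
        unname(contrib$tacticTest$statistic) else NA),
    p = c(if (!is.null(contrib$riverTest))
      contrib$riverTest$p.value else NA,
      if (!is.null(contrib$tacticTest))
        contrib$tacticTest$p.value else NA))
  c(arts, writeTsv(tests, stageFile(cfg, "contrib_tests.tsv")))
}

stageReport <- function(cfg) {
  files <- c("filter_report.tsv", "diversity_groups.tsv", "ne_ld.tsv",
             "fst_pairs.tsv", "ibd_models.tsv", "amova.tsv",
             "tactic_contrast.tsv", "panel_choice.tsv",
             "contrib_river.tsv", "contrib_tactic.tsv",
             "contrib_tests.tsv")
  present <- files[file.exists(stageFile(cfg, files))]
  lines <- unlist(lapply(present, function(f)
    c(paste0("== ", f, " =="),
      readLines(stageFile(cfg, f)), "")))
  out <- stageFile(cfg, "report.txt")
  writeLines(lines, out)
  out
}
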