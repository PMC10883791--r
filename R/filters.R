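#' FilterReport: bookkeeping for the post-genotyping filter cascade
#'
#' One row per filter step with sample/locus counts in and out and the
#' identifiers removed. Counts telescope: the "out" counts of step k are
#' the "in" counts of step k+1.
#'
#' @slot steps data.frame (step, samplesIn, samplesOut, lociIn, lociOut).
#' @slot removed named list of removed identifier vectors, one per step.
#' @aliases FilterReport-class filterReport
#' @export FilterReport
#' @exportClass FilterReport
FilterReport <- setClass("FilterReport",
  slots = c(steps = "data.frame", removed = "list"))

setValidity("FilterReport", function(object) {
  s <- object@steps
  if (nrow(s) > 1) {
    ok <- all(s$samplesIn[-1] == s$samplesOut[-nrow(s)]) &&
      all(s$lociIn[-1] == s$lociOut[-nrow(s)])
    if (!ok) return("filter step counts must telescope")
  }
  TRUE
})

setMethod("show", "FilterReport", function(object) {
  print(object@steps, row.names = FALSE)
})

#' @rdname FilterReport-class
#' @param x a `GenotypeExperiment` carrying a report, or a `FilterReport`.
#' @export
setMethod("filterReport", "GenotypeExperiment", function(x) {
  fr <- S4Vectors::metadata(x)$filterReport
  if (is.null(fr)) FilterReport(steps = emptySteps(), removed = list())
  else fr
})

emptySteps <- function() data.frame(
  step = character(), samplesIn = integer(), samplesOut = integer(),
  lociIn = integer(), lociOut = integer(), stringsAsFactors = FALSE)

# append one step to the report carried in metadata
recordStep <- function(gmIn, gmOut, step, removedIds) {
  fr <- filterReport(gmIn)
  fr@steps <- rbind(fr@steps, data.frame(
    step = step, samplesIn = ncol(gmIn), samplesOut = ncol(gmOut),
    lociIn = nrow(gmIn), lociOut = nrow(gmOut),
    stringsAsFactors = FALSE))
  fr@removed[[step]] <- removedIds
  S4Vectors::metadata(gmOut)$filterReport <- fr
  gmOut
}

#' Export a filter report
#'
#' @param fr a [FilterReport-class].
#' @param tsv,json optional output paths.
#' @return the steps data.frame, invisibly when writing.
#' @export
writeFilterReport <- function(fr, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(fr@steps, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(steps = fr@steps, removed = fr@removed),
                         json, auto_unbox = TRUE, digits = NA)
  if (is.null(tsv) && is.null(json)) fr@steps else invisible(fr@steps)
}

#' Genotype depth filter
#'
#' Sets genotype calls with read depth below `minDepth` to missing
#' (3x in the standard cascade). Requires the depth assay.
#'
#' @param gm a `GenotypeExperiment` with a `"depth"` assay.
#' @param minDepth minimum per-genotype read depth for a call.
#' @return filtered `GenotypeExperiment` (report updated).
#' @export
genotypeDepthFilter <- function(gm, minDepth = 3) {
  dp <- readDepth(gm)
  if (is.null(dp))
    stop("genotypeDepthFilter requires a depth assay; none present")
  d <- dosage(gm)
  d[dp < minDepth] <- NA_integer_
  out <- gm
  SummarizedExperiment::assay(out, "dosage") <- d
  recordStep(gm, out, "genotype_depth", character())
}

#' Locus filter: group missingness and rare-allele support
#'
#' Keeps a locus only if (i) every sample group has at most
#' `maxGroupMissing` missing data at it and (ii) at least
#' `minRareAlleleSamples` samples carry the rarer allele (a carrier has
#' dosage 1 or 2 copies of the minor allele). Both thresholds are
#' inclusive. The standard cascade runs this twice (0.40/3 then 0.50/5),
#' with the mixture sample treated as one additional group.
#'
#' @param gm a `GenotypeExperiment` with group labels.
#' @param maxGroupMissing maximum per-group missing fraction.
#' @param minRareAlleleSamples minimum number of minor-allele carriers.
#' @return filtered `GenotypeExperiment`.
#' @export
locusFilter <- function(gm, maxGroupMissing = 0.40,
                        minRareAlleleSamples = 3) {
  d <- dosage(gm)
  grp <- popGroups(gm)
  if (any(table(grp) == 0)) stop("empty sample group")
  missOk <- rep(TRUE, nrow(d))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    frac <- rowMeans(is.na(d[, idx, drop = FALSE]))
    missOk <- missOk & frac <= maxGroupMissing
  }
  n <- rowSums(!is.na(d))
  altCnt <- rowSums(d, na.rm = TRUE)
  altFreq <- ifelse(n > 0, altCnt / (2 * n), NA_real_)
  minorIsAlt <- !is.na(altFreq) & altFreq <= 0.5
  carriers <- ifelse(minorIsAlt,
                     rowSums(d >= 1L, na.rm = TRUE),
                     rowSums(d <= 1L, na.rm = TRUE))
  carriers[is.na(altFreq)] <- 0L
  keep <- missOk & carriers >= minRareAlleleSamples
  out <- gm[keep, ]
  recordStep(gm, out, sprintf("locus_%g_%g", maxGroupMissing,
                              minRareAlleleSamples),
             lociIds(gm)[!keep])
}

#' Sample missingness filter
#'
#' Removes samples whose missing-genotype fraction strictly exceeds
#' `maxFraction` (a sample at exactly the threshold is kept).
#'
#' @param gm a `GenotypeExperiment`.
#' @param maxFraction maximum tolerated missing fraction (default 5%).
#' @return filtered `GenotypeExperiment`.
#' @export
sampleMissingnessFilter <- function(gm, maxFraction = 0.05) {
  frac <- colMeans(is.na(dosage(gm)))
  keep <- frac <= maxFraction
  out <- gm[, keep]
  recordStep(gm, out, "sample_missingness", colnames(gm)[!keep])
}

#' Heterozygosity filter
#'
#' Removes samples whose observed heterozygosity (fraction of called
#' genotypes that are heterozygous) strictly exceeds `hetThreshold`.
#'
#' @param gm a `GenotypeExperiment`.
#' @param hetThreshold maximum tolerated observed heterozygosity.
#' @return filtered `GenotypeExperiment`.
#' @export
heterozygosityFilter <- function(gm, hetThreshold = 0.3) {
  d <- dosage(gm)
  ho <- colSums(d == 1L, na.rm = TRUE) / colSums(!is.na(d))
  keep <- ho <= hetThreshold
  out <- gm[, keep]
  recordStep(gm, out, "heterozygosity", colnames(gm)[!keep])
}

#' LD pruning by forward scan
#'
#' Scans loci in (chrom, pos) order and drops a locus whose squared
#' Pearson correlation of dosages (pairwise-complete) with any *retained*
#' locus within `windowBp` upstream on the same chromosome exceeds `r2`
#' (so of a linked pair, the first locus is kept). The window is
#' inclusive at exactly `windowBp` and loci further apart are never
#' compared.
#'
#' @param gm a `GenotypeExperiment`.
#' @param r2 squared-correlation threshold (strictly-greater removal).
#' @param windowBp comparison window in base pairs.
#' @return filtered `GenotypeExperiment`.
#' @export
ldPrune <- function(gm, r2 = 0.5, windowBp = 100000) {
  d <- dosage(gm)
  chrom <- as.character(GenomicRanges::seqnames(gm))
  pos <- GenomicRanges::start(gm)
  keep <- rep(TRUE, nrow(d))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    retained <- integer()
    for (i in idx) {
      near <- retained[pos[i] - pos[retained] <= windowBp]
      drop <- FALSE
      if (length(near)) {
        r <- suppressWarnings(
          cor(d[i, ], t(d[near, , drop = FALSE]),
              use = "pairwise.complete.obs"))
        drop <- any(!is.na(r) & r^2 > r2)
      }
      if (drop) keep[i] <- FALSE else retained <- c(retained, i)
    }
  }
  out <- gm[keep, ]
  recordStep(gm, out, "ld_prune", lociIds(gm)[!keep])
}

#' Standard post-genotyping filter cascade
#'
#' Runs the full quality-control chain in its canonical order: genotype
#' depth (3x), locus pass 1 (40% group missingness, 3 rare-allele
#' carriers), sample missingness (5%), locus pass 2 (50%, 5), kin removal
#' at relatedness 0.9, heterozygosity (0.3), locus pass 2 repeated,
#' HDplot paralog removal, and LD pruning (r2 0.5 within 100 kb).
#' Steps needing absent assays (depth, AD) are skipped with a message.
#'
#' @param gm a `GenotypeExperiment`.
#' @param params named list overriding any of the documented defaults:
#'   `minDepth`, `groupMissing1`, `rare1`, `groupMissing2`, `rare2`,
#'   `sampleMissing`, `relatedness`, `het`, `hdH`, `hdD`, `ldR2`,
#'   `ldWindow`.
#' @return filtered `GenotypeExperiment` with a complete
#'   [FilterReport-class] in its metadata.
#' @export
standardFilterCascade <- function(gm, params = list()) {
  p <- utils::modifyList(list(
    minDepth = 3, groupMissing1 = 0.40, rare1 = 3,
    groupMissing2 = 0.50, rare2 = 5, sampleMissing = 0.05,
    relatedness = 0.9, het = 0.3, hdH = 0.6, hdD = 7,
    ldR2 = 0.5, ldWindow = 100000), params)
  if (!is.null(readDepth(gm)))
    gm <- genotypeDepthFilter(gm, p$minDepth)
  gm <- locusFilter(gm, p$groupMissing1, p$rare1)
  gm <- sampleMissingnessFilter(gm, p$sampleMissing)
  gm <- locusFilter(gm, p$groupMissing2, p$rare2)
  gm <- kinFilter(gm, p$relatedness)
  gm <- heterozygosityFilter(gm, p$het)
  gm <- locusFilter(gm, p$groupMissing2, p$rare2)
  if (!is.null(alleleDepth(gm)))
    gm <- hdplotFilter(gm, p$hdH, p$hdD)
  ldPrune(gm, p$ldR2, p$ldWindow)
}
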