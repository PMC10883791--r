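#' GenotypeExperiment: diploid biallelic SNP genotypes with metadata
#'
#' `GenotypeExperiment` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] for diploid biallelic
#' SNP data. The mandatory `"dosage"` assay holds alternate-allele counts
#' (0, 1, 2 or `NA` for a missing call) with loci as rows and samples as
#' columns. Optional assays `"depth"` (total read depth per genotype),
#' `"refDepth"` and `"altDepth"` (per-allele read depths) support
#' depth-based filtering and paralog diagnostics. Loci live in the
#' `rowRanges` (a `GRanges` with `ref`/`alt` metadata columns), sorted by
#' chromosome and position; samples carry `group` (population label) and
#' optional `tactic` (life-history tactic) and `year` columns in `colData`.
#'
#' @param dosage integer matrix, loci x samples, values in \{0,1,2,NA\}.
#' @param chrom,pos,ref,alt per-locus chromosome, 1-based position and
#'   alleles (single bases or short strings; one ref and one alt only).
#' @param sampleId,group,tactic,year per-sample metadata; `tactic` and
#'   `year` may be `NULL`.
#' @param depth,refDepth,altDepth optional integer matrices matching
#'   `dosage` in shape.
#'
#' @return A `GenotypeExperiment`.
#' @examples
#' gm <- GenotypeExperiment(
#'   dosage = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'   ref = c("A", "C"), alt = c("G", "T"),
#'   sampleId = c("s1", "s2"), group = c("POP1", "POP1")
#' )
#' dosage(gm)
#' @aliases GenotypeExperiment-class
#' @export
GenotypeExperiment <- function(dosage, chrom, pos, ref, alt,
                               sampleId, group,
                               tactic = NULL, year = NULL,
                               depth = NULL, refDepth = NULL,
                               altDepth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  L <- nrow(dosage)
  if (length(chrom) != L || length(pos) != L)
    stop("chrom/pos must have one entry per dosage row")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
    ref = as.character(ref), alt = as.character(alt)
  )
  names(gr) <- paste0(as.character(chrom), ":", as.integer(pos))
  cd <- S4Vectors::DataFrame(
    sampleId = as.character(sampleId),
    group = as.character(group)
  )
  cd$tactic <- if (is.null(tactic)) NA_character_ else as.character(tactic)
  cd$year <- if (is.null(year)) NA_character_ else as.character(year)
  rownames(cd) <- cd$sampleId
  assays <- list(dosage = dosage)
  if (!is.null(depth)) {
    storage.mode(depth) <- "integer"; assays$depth <- depth
  }
  if (!is.null(refDepth)) {
    storage.mode(refDepth) <- "integer"; assays$refDepth <- refDepth
  }
  if (!is.null(altDepth)) {
    storage.mode(altDepth) <- "integer"; assays$altDepth <- altDepth
  }
  assays <- lapply(assays, function(a) {
    dimnames(a) <- list(names(gr), cd$sampleId); a
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = gr, colData = cd
  )
  gm <- new("GenotypeExperiment", se)
  sortLoci(gm)
}

#' @rdname GenotypeExperiment
#' @export
setClass("GenotypeExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    v <- d[!is.na(d)]
    if (length(v) && (any(v < 0L) || any(v > 2L)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sampleId", "group") %in% colnames(cd)))
    msg <- c(msg, "colData must contain sampleId and group")
  else if (anyDuplicated(cd$sampleId))
    msg <- c(msg, "sample ids must be unique")
  key <- paste(as.character(GenomicRanges::seqnames(object)),
               GenomicRanges::start(object))
  if (anyDuplicated(key))
    msg <- c(msg, "loci must be unique by (chrom, pos)")
  if (length(msg)) msg else TRUE
})

# canonical locus order: chromosome name, then position
sortLoci <- function(gm) {
  chrom <- as.character(GenomicRanges::seqnames(gm))
  o <- order(chrom, GenomicRanges::start(gm))
  gm[o, ]
}

#' Accessors for GenotypeExperiment components
#'
#' `dosage()` returns the loci x samples alt-allele dosage matrix;
#' `readDepth()` and `alleleDepth()` the depth assays (`alleleDepth()` as a
#' `list(ref=, alt=)`); `popGroups()`, `tactics()` and `sampleYears()` the
#' per-sample metadata vectors (named by sample id); `lociIds()` the
#' canonical `"chrom:pos"` locus identifiers.
#'
#' @param x a `GenotypeExperiment`.
#' @return See individual descriptions.
#' @name dosage
#' @aliases readDepth alleleDepth popGroups tactics sampleYears lociIds
NULL

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeExperiment", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname dosage
#' @export
setMethod("readDepth", "GenotypeExperiment", function(x) {
  if (!"depth" %in% SummarizedExperiment::assayNames(x)) NULL
  else SummarizedExperiment::assay(x, "depth")
})

#' @rdname dosage
#' @export
setMethod("alleleDepth", "GenotypeExperiment", function(x) {
  an <- SummarizedExperiment::assayNames(x)
  if (!all(c("refDepth", "altDepth") %in% an)) return(NULL)
  list(ref = SummarizedExperiment::assay(x, "refDepth"),
       alt = SummarizedExperiment::assay(x, "altDepth"))
})

#' @rdname dosage
#' @export
setMethod("popGroups", "GenotypeExperiment", function(x)
  setNames(SummarizedExperiment::colData(x)$group, colnames(x)))

#' @rdname dosage
#' @export
setMethod("tactics", "GenotypeExperiment", function(x)
  setNames(SummarizedExperiment::colData(x)$tactic, colnames(x)))

#' @rdname dosage
#' @export
setMethod("sampleYears", "GenotypeExperiment", function(x)
  setNames(SummarizedExperiment::colData(x)$year, colnames(x)))

#' @rdname dosage
#' @export
setMethod("lociIds", "GenotypeExperiment", function(x)
  paste0(as.character(GenomicRanges::seqnames(x)), ":",
         GenomicRanges::start(x)))

setMethod("show", "GenotypeExperiment", function(object) {
  cat("GenotypeExperiment:", nrow(object), "loci x", ncol(object),
      "samples\n")
  grp <- table(popGroups(object))
  cat("groups:", paste0(names(grp), "(", grp, ")", collapse = " "), "\n")
  cat("assays:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "),
      "\n")
  fr <- S4Vectors::metadata(object)$filterReport
  if (!is.null(fr)) cat("filter steps applied:", nrow(fr@steps), "\n")
  invisible(NULL)
})

#' Per-group allele frequency table
#'
#' Computes, for every locus and every population group, the alternate
#' allele frequency among called genotypes together with the number of
#' called genotypes supporting it.
#'
#' @param gm a `GenotypeExperiment`.
#' @param labels optional per-sample grouping vector overriding the
#'   `group` column (e.g. tactic labels).
#' @return An [AlleleFreqTable-class] object.
#' @export
alleleFreqs <- function(gm, labels = NULL) {
  if (is.null(labels)) labels <- popGroups(gm)
  labels <- as.character(labels)
  d <- dosage(gm)
  groups <- sort(unique(labels))
  called <- !is.na(d)
  freq <- matrix(NA_real_, nrow(d), length(groups),
                 dimnames = list(rownames(d), groups))
  n <- matrix(0L, nrow(d), length(groups),
              dimnames = list(rownames(d), groups))
  for (g in groups) {
    idx <- which(labels == g)
    n[, g] <- as.integer(rowSums(called[, idx, drop = FALSE]))
    s <- rowSums(d[, idx, drop = FALSE], na.rm = TRUE)
    freq[, g] <- ifelse(n[, g] > 0, s / (2 * n[, g]), NA_real_)
  }
  new("AlleleFreqTable", freq = freq, nCalled = n,
      loci = SummarizedExperiment::rowRanges(gm))
}

#' AlleleFreqTable: per-population alternate-allele frequencies
#'
#' Holds a loci x populations matrix of alternate-allele frequencies
#' (`freq`), the number of called genotypes behind each cell (`nCalled`),
#' and the locus coordinates (`loci`).
#'
#' @aliases AlleleFreqTable-class
#' @export AlleleFreqTable
#' @exportClass AlleleFreqTable
AlleleFreqTable <- setClass("AlleleFreqTable",
  slots = c(freq = "matrix", nCalled = "matrix", loci = "GRanges"))

setValidity("AlleleFreqTable", function(object) {
  f <- object@freq[!is.na(object@freq)]
  if (length(f) && (any(f < 0) || any(f > 1)))
    return("frequencies must lie in [0, 1]")
  if (!all(dim(object@freq) == dim(object@nCalled)))
    return("freq and nCalled must share a shape")
  TRUE
})

setMethod("show", "AlleleFreqTable", function(object) {
  cat("AlleleFreqTable:", nrow(object@freq), "loci x",
      ncol(object@freq), "populations\n")
})
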