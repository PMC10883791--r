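#' Read a VCF of biallelic SNPs into a GenotypeExperiment
#'
#' Parses a VCFv4.2 file with vcfR, keeping GT (as alt-allele dosage;
#' missing genotypes become `NA`) and, when present, the DP and AD format
#' fields. Indel or multiallelic records are rejected with the offending
#' locus named; every VCF sample must appear in the popmap.
#'
#' @param path VCF file (plain text or gzipped).
#' @param popmap data.frame with columns `sampleId`, `population`, or the
#'   path of a TSV with those columns.
#' @param tacticTable optional data.frame / TSV path with columns
#'   `sampleId`, `tactic`, `year`.
#' @return A [GenotypeExperiment].
#' @export
readVcfGenotypes <- function(path, popmap, tacticTable = NULL) {
  if (is.character(popmap)) popmap <- readPopmap(popmap)
  if (is.character(tacticTable)) tacticTable <- readTacticTable(tacticTable)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bad <- grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L |
    is.na(alt)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("record %s:%s is not a biallelic SNP (REF=%s, ALT=%s)",
                 fix[i, "CHROM"], fix[i, "POS"], ref[i], alt[i]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  vcfSamples <- colnames(gt)
  unknown <- setdiff(vcfSamples, popmap$sampleId)
  if (length(unknown))
    stop("samples absent from popmap: ", paste(unknown, collapse = ", "))
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  core <- gsub("\\|", "/", gt)
  dos[core == "0/0"] <- 0L
  dos[core %in% c("0/1", "1/0")] <- 1L
  dos[core == "1/1"] <- 2L
  fmt <- v@gt[, 1]
  depth <- refd <- altd <- NULL
  if (any(grepl("DP", fmt))) {
    depth <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    storage.mode(depth) <- "integer"
  }
  if (any(grepl("AD", fmt))) {
    ad <- vcfR::extract.gt(v, element = "AD")
    refd <- matrix(as.integer(sub(",.*", "", ad)), nrow(ad), ncol(ad))
    altd <- matrix(as.integer(sub(".*,", "", ad)), nrow(ad), ncol(ad))
  }
  meta <- popmap[match(vcfSamples, popmap$sampleId), ]
  tac <- yr <- NULL
  if (!is.null(tacticTable)) {
    m <- match(vcfSamples, tacticTable$sampleId)
    tac <- tacticTable$tactic[m]
    yr <- as.character(tacticTable$year[m])
  }
  GenotypeExperiment(
    dosage = dos, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = ref, alt = alt,
    sampleId = vcfSamples, group = meta$population,
    tactic = tac, year = yr,
    depth = depth, refDepth = refd, altDepth = altd)
}

#' @rdname readVcfGenotypes
#' @param tsv path of a two-column TSV (sampleId, population).
#' @export
readPopmap <- function(tsv) {
  df <- read.table(tsv, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c("sampleId", "population")
  df
}

#' @rdname readVcfGenotypes
#' @export
readTacticTable <- function(tsv) {
  df <- read.table(tsv, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(df)[1:3] <- c("sampleId", "tactic", "year")
  df
}

#' Read a square distance matrix TSV (km)
#'
#' @param tsv path; first row and column hold population codes.
#' @return symmetric numeric matrix.
#' @export
readDistanceMatrix <- function(tsv) {
  m <- as.matrix(read.table(tsv, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  m
}

# plain-text VCFv4.2 writer; GT only, or GT:DP:AD when depths exist
writeVcfText <- function(gm, path) {
  gr <- SummarizedExperiment::rowRanges(gm)
  if (any(grepl(",", gr$alt)) || any(nchar(gr$ref) != 1L) ||
      any(nchar(gr$alt) != 1L))
    stop("only biallelic SNPs can be written to VCF")
  d <- dosage(gm)
  gtStr <- matrix("./.", nrow(d), ncol(d))
  gtStr[!is.na(d) & d == 0L] <- "0/0"
  gtStr[!is.na(d) & d == 1L] <- "0/1"
  gtStr[!is.na(d) & d == 2L] <- "1/1"
  dp <- readDepth(gm); ad <- alleleDepth(gm)
  hasDepth <- !is.null(dp) && !is.null(ad)
  if (hasDepth) {
    cells <- matrix(paste0(gtStr, ":", dp, ":", ad$ref, ",", ad$alt),
                    nrow(d), ncol(d))
    fmt <- "GT:DP:AD"
  } else {
    cells <- gtStr
    fmt <- "GT"
  }
  chrom <- as.character(GenomicRanges::seqnames(gm))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popGSI",
    paste0("##contig=<ID=", unique(chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (hasDepth) c(
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
             "Description=\"Allelic depths\">")),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(gm)), collapse = "\t"))
  body <- cbind(chrom, GenomicRanges::start(gm), lociIds(gm),
                gr$ref, gr$alt, ".", "PASS", ".", fmt, cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
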