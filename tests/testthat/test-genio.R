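writeMiniVcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

miniVcfLines <- function(gtBlock,
                         samples = c("s1", "s2"),
                         fixed = c("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT",
                                   "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    paste(fixed, gtBlock, sep = "\t"))
}

test_that("VCF reading maps genotypes, missing calls and metadata", {
  pm <- data.frame(sampleId = c("s1", "s2"),
                   population = c("POP1", "POP2"))
  path <- writeMiniVcf(miniVcfLines(c("0/0\t0/1", "1/1\t./.")))
  gm <- readVcfGenotypes(path, pm)
  expect_identical(unname(dosage(gm)),
                   matrix(c(0L, 2L, 1L, NA), 2, 2))
  expect_identical(as.character(popGroups(gm)), c("POP1", "POP2"))

  # multiallelic and indel records are rejected with the locus named
  bad <- writeMiniVcf(miniVcfLines(
    c("0/0\t0/1", "1/1\t0/0"),
    fixed = c("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT",
              "chr1\t200\t.\tC\tT,A\t.\tPASS\t.\tGT")))
  expect_error(readVcfGenotypes(bad, pm), "chr1:200")

  # samples missing from the popmap are named
  expect_error(readVcfGenotypes(path, pm[1, , drop = FALSE]), "s2")
})

test_that("genotype depth filtering masks exactly the shallow calls", {
  d <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L, 0L, 2L, 2L, 1L), 4, 3)
  dp <- matrix(c(5L, 9L, 3L, 4L, 2L, 8L, 3L, 3L, 10L, 1L, 3L, 2L), 4, 3)
  gm <- gmFromMatrix(d, depth = dp)
  out <- genotypeDepthFilter(gm, 3)
  expect_identical(unname(is.na(dosage(out))), dp < 3)  # hand mask
  # all-deep matrix passes unchanged
  deep <- genotypeDepthFilter(gmFromMatrix(d, depth = dp + 10L), 3)
  expect_identical(dosage(deep), dosage(gm))
  # a single shallow cell yields exactly one new missing call
  dp1 <- dp * 0L + 5L; dp1[2, 2] <- 2L
  one <- genotypeDepthFilter(gmFromMatrix(d, depth = dp1), 3)
  expect_identical(sum(is.na(dosage(one))), 1L)
  # absent depth is an explicit error, never a silent pass
  expect_error(genotypeDepthFilter(gmFromMatrix(d), 3), "depth")
})

test_that("locus filtering enforces group missingness and carrier counts", {
  grp <- rep(c("A", "B"), each = 4)
  # locus 1: 50% missing in group A -> dropped at 0.40
  # locus 2: minor allele carried by exactly 3 samples -> kept at k = 3
  d <- rbind(c(NA, NA, 0L, 1L, 0L, 1L, 2L, 0L),
             c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L))
  gm <- gmFromMatrix(d, group = grp)
  out <- locusFilter(gm, maxGroupMissing = 0.40,
                     minRareAlleleSamples = 3)
  expect_identical(lociIds(out), lociIds(gm)[2])

  # 6-locus toy agrees with an exhaustive check
  set.seed(1)
  d6 <- matrix(sample(c(0:2, NA), 48, TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)), 6, 8)
  gm6 <- gmFromMatrix(d6, group = grp)
  out6 <- locusFilter(gm6, 0.40, 3)
  expected <- vapply(seq_len(6), function(l) {
    x <- d6[l, ]
    okMiss <- all(tapply(is.na(x), grp, mean) <= 0.40)
    called <- x[!is.na(x)]
    pAlt <- sum(called) / (2 * length(called))
    carriers <- if (is.nan(pAlt)) 0
    else if (pAlt <= 0.5) sum(called >= 1) else sum(called <= 1)
    okMiss && carriers >= 3
  }, logical(1))
  expect_identical(lociIds(out6), lociIds(gm6)[expected])
})

test_that("sample missingness removal is strictly greater than 5%", {
  d <- matrix(1L, 20, 3)
  d[1, 2] <- NA          # exactly 5% missing -> kept
  d[1:3, 3] <- NA        # 15% missing -> removed
  gm <- gmFromMatrix(d)
  out <- sampleMissingnessFilter(gm, 0.05)
  expect_identical(colnames(out), c("s001", "s002"))
  rep <- filterReport(out)
  expect_identical(rep@removed[["sample_missingness"]], "s003")
})

test_that("Yang relatedness flags duplicates and centres on zero", {
  ref <- simulateReference(twoPopConfig(21, 0.01, nLoci = 2000L,
                                        n = 30L))
  A <- relatednessYang(ref$gm)
  offdiag <- A[upper.tri(A)]
  expect_lt(abs(mean(offdiag)), 0.05)       # unrelated samples

  # a duplicated sample scores >= 0.9 and the kin filter removes one;
  # as in the QC cascade, rare-allele loci (with their unstable
  # frequency estimates at this sample size) are filtered out first
  d <- dosage(ref$gm)[, popGroups(ref$gm) == "A"]
  n0 <- ncol(d)
  d <- cbind(d, d[, 1])
  gm <- gmFromMatrix(d, group = rep("P", n0 + 1))
  gm <- locusFilter(gm, 1, 5)
  A2 <- relatednessYang(gm)
  expect_gt(A2[1, n0 + 1], 0.9)
  out <- kinFilter(gm, 0.9)
  expect_identical(ncol(out), n0)

  # a pair sharing no called loci is an error
  dd <- rbind(c(1L, NA), c(NA, 1L), c(0L, NA))
  expect_error(relatednessYang(gmFromMatrix(dd)), "no called")
})

test_that("oracle equality for Yang relatedness holds under missingness", {
  set.seed(5)
  d <- matrix(sample(c(0:2, NA), 300, TRUE,
                     prob = c(0.35, 0.3, 0.25, 0.1)), 30, 10)
  gm <- gmFromMatrix(d)
  expect_equal(relatednessYang(gm), oracleYang(d),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("heterozygosity ceiling keeps the boundary and drops extremes", {
  d <- cbind(rep(1L, 10),                      # Ho = 1 -> removed
             c(rep(1L, 3), rep(0L, 7)),        # Ho = 0.3 -> kept
             c(rep(1L, 2), rep(2L, 8)))        # Ho = 0.2 -> kept
  gm <- gmFromMatrix(d)
  out <- heterozygosityFilter(gm, 0.3)
  expect_identical(colnames(out), c("s002", "s003"))
})

test_that("HDplot matches hand values and flags planted paralogs", {
  # hand-built 5-sample AD table at 2 loci
  d <- rbind(c(1L, 1L, 0L, 2L, 1L),
             c(0L, 0L, 2L, 0L, 0L))
  refd <- rbind(c(6L, 3L, 9L, 0L, 5L), c(9L, 8L, 0L, 7L, 9L))
  altd <- rbind(c(4L, 7L, 0L, 8L, 5L), c(0L, 0L, 8L, 0L, 0L))
  gm <- gmFromMatrix(d, refDepth = refd, altDepth = altd)
  hd <- hdplot(gm)
  o <- oracleHdplot(d, refd, altd)
  expect_equal(hd$H, o$H)
  expect_equal(hd$D, o$D)
  # by hand: hets at locus 1 are samples 1,2,5 -> ref 14, alt 16
  expect_equal(hd$H[1], 3 / 5)
  expect_equal(hd$D[1], (14 - 16) / sqrt(30))
  # locus without heterozygotes is defined as (0, 0)
  expect_equal(hd$H[2], 0)
  expect_equal(hd$D[2], 0)
  # AD-less input errors
  expect_error(hdplot(gmFromMatrix(d)), "AD")
})

test_that("LD pruning keeps the first of linked loci within the window", {
  set.seed(3)
  base <- sample(0:2, 12, TRUE)
  # locus 2 duplicates locus 1 at 500 bp -> dropped
  # locus 3 duplicates locus 1 at 100,001 bp -> kept (outside window)
  d <- rbind(base, base, base)
  gm <- gmFromMatrix(d, pos = c(1000L, 1500L, 101001L))
  out <- ldPrune(gm, 0.5, 100000)
  expect_identical(unname(GenomicRanges::start(out)),
                   c(1000L, 101001L))

  # 8-locus toy equals the brute-force forward scan
  set.seed(4)
  d8 <- matrix(sample(c(0:2, NA), 160, TRUE,
                      prob = c(0.35, 0.3, 0.25, 0.1)), 8, 20)
  pos8 <- cumsum(sample(2e4:6e4, 8))
  gm8 <- gmFromMatrix(d8, pos = as.integer(pos8))
  out8 <- ldPrune(gm8, 0.5, 100000)
  keep <- oracleLdPrune(d8, rep("chr1", 8), pos8)
  expect_identical(lociIds(out8), lociIds(gm8)[keep])
})

test_that("identity-by-missingness finds batch structure only when planted", {
  set.seed(6)
  # uniform random missingness: no clusters
  d <- matrix(sample(0:2, 3000, TRUE), 100, 30)
  d[sample(length(d), 300)] <- NA
  expect_lt(ibmCheck(gmFromMatrix(d))$silhouette, 0.5)

  # block missingness by batch: clear clusters
  d2 <- matrix(sample(0:2, 3000, TRUE), 100, 30)
  d2[1:40, 1:15][sample(600, 350)] <- NA
  d2[61:100, 16:30][sample(600, 350)] <- NA
  expect_gt(ibmCheck(gmFromMatrix(d2))$silhouette, 0.5)

  # no missingness at all is reported as degenerate
  expect_identical(ibmCheck(gmFromMatrix(matrix(1L, 10, 5)))$status,
                   "no variation")
})

test_that("filters are idempotent and reports telescope", {
  cfg <- twoPopConfig(31, 0.03, nLoci = 600L, n = 40L,
                      kinPairs = 2L, dupLoci = 10L)
  ref <- simulateReference(cfg)
  art <- injectArtifacts(ref$gm, cfg, ref$truth)
  gm <- art$gm

  once <- list(
    depth = genotypeDepthFilter(gm, 3),
    locus = locusFilter(gm, 0.4, 3),
    miss = sampleMissingnessFilter(gm, 0.05),
    het = heterozygosityFilter(gm, 0.3),
    kin = kinFilter(gm, 0.9),
    hd = hdplotFilter(gm, 0.6, 7),
    ld = ldPrune(gm, 0.5, 1e5))
  repeats <- list(
    depth = genotypeDepthFilter(once$depth, 3),
    locus = locusFilter(once$locus, 0.4, 3),
    miss = sampleMissingnessFilter(once$miss, 0.05),
    het = heterozygosityFilter(once$het, 0.3),
    kin = kinFilter(once$kin, 0.9),
    hd = hdplotFilter(once$hd, 0.6, 7),
    ld = ldPrune(once$ld, 0.5, 1e5))
  for (nm in names(once)) {
    expect_identical(dim(repeats[[nm]]), dim(once[[nm]]),
                     label = paste("idempotent:", nm))
    expect_identical(dosage(repeats[[nm]]), dosage(once[[nm]]),
                     label = paste("idempotent dosage:", nm))
  }

  # full cascade: counts telescope and removed + survivors = input
  flt <- standardFilterCascade(gm)
  rep <- filterReport(flt)
  expect_true(validObject(rep))
  s <- rep@steps
  expect_identical(s$samplesIn[-1], s$samplesOut[-nrow(s)])
  expect_identical(s$lociIn[-1], s$lociOut[-nrow(s)])
  removedSamples <- unlist(rep@removed[
    s$step[s$samplesOut < s$samplesIn]])
  expect_setequal(c(colnames(flt), removedSamples), colnames(gm))
})
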