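#' Per-individual diversity and inbreeding
#'
#' For each sample computes observed heterozygosity Ho (fraction of its
#' called genotypes that are heterozygous), expected heterozygosity He
#' (mean of 2p(1-p) over its called loci, with p the alternate-allele
#' frequency of the sample's own group), and F = 1 - Ho/He; then group
#' means and standard deviations of each. Groups of size one get He and
#' F flagged `NA`.
#'
#' @param gm a `GenotypeExperiment` with group labels.
#' @return list with `perSample` and `perGroup` data.frames.
#' @export
diversity <- function(gm) {
  d <- dosage(gm)
  grp <- popGroups(gm)
  af <- alleleFreqs(gm)
  called <- !is.na(d)
  ho <- colSums(d == 1L, na.rm = TRUE) / colSums(called)
  he <- rep(NA_real_, ncol(d))
  sizes <- table(grp)
  for (j in seq_len(ncol(d))) {
    if (sizes[[grp[j]]] < 2) next
    p <- af@freq[, grp[j]]
    hexp <- 2 * p * (1 - p)
    he[j] <- mean(hexp[called[, j]], na.rm = TRUE)
  }
  fis <- 1 - ho / he
  per <- data.frame(sampleId = colnames(d), group = as.character(grp),
                    Ho = ho, He = he, F = fis,
                    flagged = is.na(he), stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(per, per$group), function(s)
    data.frame(group = s$group[1], n = nrow(s),
               HoMean = mean(s$Ho), HoSD = sd(s$Ho),
               HeMean = mean(s$He), HeSD = sd(s$He),
               FMean = mean(s$F), FSD = sd(s$F),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(perSample = per, perGroup = agg)
}

#' NeEstimate: linkage-disequilibrium effective population size
#'
#' @slot group population label.
#' @slot ne point estimate (may be `Inf` when the drift signal is <= 0).
#' @slot ci length-2 numeric (low, high).
#' @slot nComparisons locus pairs used.
#' @slot meanR2 mean squared correlation across pairs.
#' @slot expectedR2 sampling expectation E[r2 | S].
#' @slot harmonicS harmonic-mean pairwise sample size.
#' @aliases NeEstimate-class
#' @export NeEstimate
#' @exportClass NeEstimate
NeEstimate <- setClass("NeEstimate", slots = c(
  group = "character", ne = "numeric", ci = "numeric",
  nComparisons = "integer", meanR2 = "numeric", expectedR2 = "numeric",
  harmonicS = "numeric"))

setValidity("NeEstimate", function(object) {
  if (!is.infinite(object@ne) && object@ne <= 0)
    return("Ne must be positive or infinite")
  TRUE
})

setMethod("show", "NeEstimate", function(object) {
  cat(sprintf("NeEstimate [%s]: Ne = %.1f (%.1f-%.1f), %d pairs\n",
              object@group, object@ne, object@ci[1], object@ci[2],
              object@nComparisons))
})

# Waples (2006) expectation of r2 under sampling S diploids, and the
# random-mating inversion of the drift signal to Ne
expectedSamplingR2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2
  else 0.0018 + 0.907 / S + 4.44 / S^2
}

neFromR2Drift <- function(r2d) {
  if (r2d <= 0) return(Inf)
  disc <- max(1 / 9 - 2.76 * r2d, 0)
  (1 / 3 + sqrt(disc)) / (2 * r2d)
}

#' LD-method effective population size
#'
#' Burrows-composite linkage disequilibrium among physically unlinked
#' loci: r2 is the squared Pearson correlation of dosages
#' (pairwise-complete) over locus pairs on *different* chromosomes, the
#' sampling expectation E[r2|S] (Waples 2006, harmonic-mean S across
#' pairs) is subtracted, and the residual drift signal is inverted to Ne
#' under random mating. Only loci with in-group minor allele frequency
#' strictly above `maf` enter. The confidence interval is a
#' chromosome-block (delete-one) jackknife on the drift signal.
#'
#' @param gm a `GenotypeExperiment`.
#' @param group population to estimate (default: all samples together).
#' @param maf minor-allele-frequency floor (exclusive).
#' @param crossChromosomeOnly restrict to cross-chromosome pairs
#'   (requires >= 2 chromosomes).
#' @param maxLoci cap on loci used (evenly thinned, deterministic) to
#'   bound the pair count.
#' @return an [NeEstimate-class].
#' @export
ldNe <- function(gm, group = NULL, maf = 0.05,
                 crossChromosomeOnly = TRUE, maxLoci = 2000L) {
  if (!is.null(group)) gm <- gm[, popGroups(gm) == group]
  else group <- "all"
  d <- dosage(gm)
  S0 <- ncol(d)
  if (S0 < 10) stop("LD-Ne needs at least 10 samples")
  n <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(n, 1L))
  mafv <- pmin(p, 1 - p)
  keep <- n >= 2 & mafv > maf
  gm2 <- gm[keep, ]
  d <- dosage(gm2)
  if (nrow(d) > maxLoci) {
    idx <- unique(round(seq(1, nrow(d), length.out = maxLoci)))
    gm2 <- gm2[idx, ]; d <- dosage(gm2)
  }
  chrom <- as.character(GenomicRanges::seqnames(gm2))
  if (crossChromosomeOnly && length(unique(chrom)) < 2)
    stop("cross-chromosome LD-Ne needs at least two chromosomes")
  r <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))
  obs <- crossprod(!is.na(t(d)) * 1)   # pairwise sample sizes
  ut <- upper.tri(r)
  use <- ut & !is.na(r)
  if (crossChromosomeOnly)
    use <- use & outer(chrom, chrom, "!=")
  Spair <- obs[use]
  # Burrows composite r2: Pearson r2 with the S/(S-1) covariance factor
  r2 <- r[use]^2 * (Spair / (Spair - 1))^2
  if (!length(r2)) stop("no usable locus pairs")
  harmS <- length(Spair) / sum(1 / Spair)
  er2 <- expectedSamplingR2(harmS)
  r2d <- mean(r2) - er2
  ne <- neFromR2Drift(r2d)
  if (is.infinite(ne))
    warning("drift signal <= 0; Ne reported as infinite")
  # delete-one-chromosome jackknife on the drift signal
  pairChrom <- outer(chrom, chrom, function(a, b) a)[use]
  pairChromB <- outer(chrom, chrom, function(a, b) b)[use]
  chroms <- unique(chrom)
  thetas <- vapply(chroms, function(ch) {
    sel <- pairChrom != ch & pairChromB != ch
    if (!any(sel)) return(NA_real_)
    mean(r2[sel]) - er2
  }, numeric(1))
  thetas <- thetas[!is.na(thetas)]
  if (length(thetas) >= 2) {
    g <- length(thetas)
    jkMean <- mean(thetas)
    se <- sqrt((g - 1) / g * sum((thetas - jkMean)^2))
    lo <- r2d + 1.96 * se   # larger r2 -> smaller Ne
    hi <- r2d - 1.96 * se
    ci <- c(neFromR2Drift(lo), neFromR2Drift(hi))
  } else ci <- c(NA_real_, NA_real_)
  NeEstimate(group = group, ne = ne, ci = ci,
             nComparisons = length(r2), meanR2 = mean(r2),
             expectedR2 = er2, harmonicS = harmS)
}
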