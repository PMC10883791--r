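#' Weir-Cockerham variance components per locus
#'
#' Computes the WC-84 among-population (a), among-individual (b) and
#' within-individual (c) variance components at every locus for an
#' arbitrary grouping. The multilocus estimator is the ratio of sums,
#' theta = sum(a) / sum(a + b + c). Loci where any group has no called
#' genotype are dropped; loci monomorphic across all groups contribute
#' zero to both sums.
#'
#' @param gm a `GenotypeExperiment`.
#' @param labels per-sample grouping (default: population groups).
#' @return data.frame (locus, a, b, c) of per-locus components.
#' @export
wcComponents <- function(gm, labels = NULL) {
  if (is.null(labels)) labels <- popGroups(gm)
  labels <- as.character(labels)
  d <- dosage(gm)
  groups <- sort(unique(labels))
  r <- length(groups)
  if (r < 2) stop("WC components need at least two groups")
  nmat <- pmat <- hmat <- matrix(0, nrow(d), r,
                                 dimnames = list(NULL, groups))
  for (g in groups) {
    idx <- which(labels == g)
    sub <- d[, idx, drop = FALSE]
    nmat[, g] <- rowSums(!is.na(sub))
    pmat[, g] <- rowSums(sub, na.rm = TRUE) / (2 * pmax(nmat[, g], 1))
    hmat[, g] <- rowSums(sub == 1L, na.rm = TRUE) / pmax(nmat[, g], 1)
  }
  ok <- rowSums(nmat > 0) == r & rowSums(nmat) > r  # every group called
  nsum <- rowSums(nmat)
  nbar <- nsum / r
  nc <- (nsum - rowSums(nmat^2) / nsum) / (r - 1)
  pbar <- rowSums(nmat * pmat) / nsum
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * hmat) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  data.frame(locus = lociIds(gm), a = a, b = b, c = cc,
             stringsAsFactors = FALSE)
}

#' Multilocus Weir-Cockerham theta
#'
#' @param gm a `GenotypeExperiment`.
#' @param labels per-sample grouping (default: population groups).
#' @param loci optional locus-id subset.
#' @return theta = sum(a) / sum(a+b+c) over usable loci.
#' @export
multilocusFst <- function(gm, labels = NULL, loci = NULL) {
  if (!is.null(loci)) {
    sel <- lociIds(gm) %in% loci
    if (!any(sel)) stop("no requested loci present")
    gm <- gm[sel, ]
  }
  comp <- wcComponents(gm, labels)
  ok <- !is.na(comp$a)
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

#' FstMatrix: pairwise differentiation with bootstrap support
#'
#' @slot groups population labels.
#' @slot theta symmetric matrix of multilocus WC-84 point estimates.
#' @slot ciLow,ciHigh percentile bootstrap bounds per pair.
#' @slot pValue one-sided bootstrap p (fraction of resampled theta <= 0).
#' @slot nLoci loci used per pair.
#' @aliases FstMatrix-class
#' @export FstMatrix
#' @exportClass FstMatrix
FstMatrix <- setClass("FstMatrix", slots = c(
  groups = "character", theta = "matrix", ciLow = "matrix",
  ciHigh = "matrix", pValue = "matrix", nLoci = "matrix"))

setValidity("FstMatrix", function(object) {
  th <- object@theta
  if (any(abs(th - t(th)) > 1e-12, na.rm = TRUE))
    return("theta must be symmetric")
  if (any(abs(diag(th)) > 1e-12)) return("diagonal must be zero")
  TRUE
})

setMethod("show", "FstMatrix", function(object) {
  cat("FstMatrix over", length(object@groups), "groups; theta range",
      sprintf("%.4g-%.4g",
              min(object@theta[upper.tri(object@theta)]),
              max(object@theta[upper.tri(object@theta)])), "\n")
})

#' Pairwise Weir-Cockerham FST with locus bootstrap
#'
#' For every pair of population groups computes multilocus theta
#' (ratio-of-sums over per-locus WC-84 components) together with a
#' percentile 95% confidence interval and a one-sided p-value from
#' `nBoot` bootstrap resamples of loci.
#'
#' @param gm a `GenotypeExperiment` (each group needs >= 2 samples).
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return an [FstMatrix-class].
#' @export
pairwiseFst <- function(gm, nBoot = 1000, seed = 1L) {
  grp <- popGroups(gm)
  groups <- sort(unique(as.character(grp)))
  if (any(table(grp)[groups] < 2))
    stop("every group needs at least two samples")
  k <- length(groups)
  theta <- lo <- hi <- pv <- nl <-
    matrix(0, k, k, dimnames = list(groups, groups))
  set.seed(seed)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    sub <- gm[, grp %in% c(groups[i], groups[j])]
    comp <- wcComponents(sub)
    ok <- which(!is.na(comp$a))
    av <- comp$a[ok]; tot <- av + comp$b[ok] + comp$c[ok]
    th <- sum(av) / sum(tot)
    bs <- vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(length(av), replace = TRUE)
      sum(av[idx]) / sum(tot[idx])
    }, numeric(1))
    q <- quantile(bs, c(0.025, 0.975), names = FALSE)
    theta[i, j] <- theta[j, i] <- th
    lo[i, j] <- lo[j, i] <- min(q[1], th)
    hi[i, j] <- hi[j, i] <- max(q[2], th)
    pv[i, j] <- pv[j, i] <- mean(bs <= 0)
    nl[i, j] <- nl[j, i] <- length(av)
  }
  FstMatrix(groups = groups, theta = theta, ciLow = lo, ciHigh = hi,
            pValue = pv, nLoci = nl)
}
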