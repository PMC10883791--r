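#' OutlierScan: PCA-based outlier scan results
#'
#' @slot K principal components used.
#' @slot z loci x K matrix of per-locus regression z-scores.
#' @slot d2 Mahalanobis distance of each locus' z-vector.
#' @slot lambda genomic inflation factor.
#' @slot p,q per-locus p-values and Storey q-values.
#' @slot significant logical flags at the q threshold used.
#' @slot qThreshold the threshold applied.
#' @slot loci locus ids (constant loci excluded).
#' @aliases OutlierScan-class
#' @export OutlierScan
#' @exportClass OutlierScan
OutlierScan <- setClass("OutlierScan", slots = c(
  K = "integer", z = "matrix", d2 = "numeric", lambda = "numeric",
  p = "numeric", q = "numeric", significant = "logical",
  qThreshold = "numeric", loci = "character"))

setValidity("OutlierScan", function(object) {
  if (any(object@p <= 0 | object@p > 1)) return("p must lie in (0, 1]")
  if (object@lambda <= 0) return("lambda must be positive")
  o <- order(object@p)
  if (is.unsorted(object@q[o], strictly = FALSE))
    return("q must be nondecreasing in p")
  TRUE
})

setMethod("show", "OutlierScan", function(object) {
  cat(sprintf(
    "OutlierScan: K=%d, lambda=%.3f, %d/%d loci significant at q<%g\n",
    object@K, object@lambda, sum(object@significant),
    length(object@p), object@qThreshold))
})

#' Scree-based choice of K
#'
#' Automates the visual scree method: eigenvalues of the genotype PCA
#' are examined up to `kMax` (clipped to samples - 1) and K is the
#' position of the largest second difference (the elbow). A scree table
#' is attached for manual override; a warning is raised when K = 1
#' (little or no structure beyond noise).
#'
#' @param gm a `GenotypeExperiment`.
#' @param kMax largest K considered (default 20).
#' @return integer K with attribute `"scree"` (data.frame of
#'   eigenvalues).
#' @export
screeSelectK <- function(gm, kMax = 20) {
  kMax <- min(kMax, ncol(gm) - 1)
  ev <- pcaGenotypes(gm, nAxes = 1)$eigenvalues
  ev <- ev[seq_len(min(kMax + 2, length(ev)))]
  d2 <- ev[seq_len(length(ev) - 2)] - 2 * ev[seq_len(length(ev) - 2) + 1] +
    ev[seq_len(length(ev) - 2) + 2]
  K <- as.integer(which.max(d2[seq_len(min(kMax, length(d2)))]))
  if (K == 1)
    warning("scree elbow at K = 1: little structure beyond the first axis")
  attr(K, "scree") <- data.frame(axis = seq_along(ev), eigenvalue = ev)
  K
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the lambda grid 0.05, 0.10,
#' ..., 0.90 with a cubic smoothing-spline extrapolation towards
#' lambda = 1, then computes q_i = min over t >= p_i of
#' pi0 * m * t / #\{p <= t\}.
#'
#' @param p vector of p-values in (0, 1].
#' @param pi0 optional fixed null proportion (overrides estimation).
#' @return vector of q-values in the order of `p`, with attribute
#'   `"pi0"`.
#' @export
qvalueStorey <- function(p, pi0 = NULL) {
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    lam <- seq(0.05, 0.90, by = 0.05)
    pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- tryCatch(
      predict(smooth.spline(lam, pi0l, df = 3), x = 1)$y,
      error = function(e) min(pi0l[length(pi0l)], 1))
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  rank <- m - seq_len(m) + 1   # rank of each sorted-descending p
  q <- pi0 * m * p[o] / rank
  q <- cummin(pmin(q, 1))
  out <- q[ro]
  attr(out, "pi0") <- pi0
  out
}

# deterministic outlier-resistant Mahalanobis distance: the location and
# covariance of the z-vectors are re-estimated a few times on the loci
# whose current distance is below the chi-squared 97.5% quantile, so a
# modest fraction of true outliers cannot inflate the null covariance
robustMahalanobis <- function(z, iter = 3) {
  K <- ncol(z)
  # first pass from median/MAD marginals, which a minority outlier
  # cluster cannot drag; later passes use mean/cov of the kept loci
  mu <- apply(z, 2, median)
  S <- diag(apply(z, 2, stats::mad)^2, nrow = K)
  for (i in seq_len(iter + 1)) {
    d2 <- mahalanobis(z, mu, S)
    if (i > iter) break
    lam <- median(d2) / qchisq(0.5, df = K)
    keep <- d2 / lam <= qchisq(0.975, df = K)
    mu <- colMeans(z[keep, , drop = FALSE])
    S <- cov(z[keep, , drop = FALSE])
  }
  d2
}

#' PCA-based outlier scan
#'
#' Regresses every locus' (scaled, mean-imputed) dosages on the first K
#' principal-component score vectors; the resulting K-vector of
#' t-statistics per locus is summarised by its Mahalanobis distance
#' under the standard covariance estimate, rescaled by the genomic
#' inflation factor lambda = median(D2)/median(chi2_K), and converted to
#' upper-tail chi-squared p-values and Storey q-values. Constant loci
#' are excluded up front.
#'
#' @param gm a `GenotypeExperiment`.
#' @param K number of principal components (>= 1, < samples - 1).
#' @param qThreshold significance threshold on q (default 0.01).
#' @param sampleMask optional logical/index vector choosing the samples
#'   that enter the scan (e.g. rivers pooled for a tactic contrast).
#' @return an [OutlierScan-class].
#' @export
pcadaptScan <- function(gm, K, qThreshold = 0.01, sampleMask = NULL) {
  if (!is.null(sampleMask)) gm <- gm[, sampleMask]
  n <- ncol(gm)
  if (K < 1) stop("K must be >= 1")
  if (K >= n - 1) stop("K must be smaller than samples - 1")
  x <- imputedDosage(gm, scale = TRUE)       # samples x loci
  keptLoci <- attr(x, "keptLoci")
  sv <- svd(x, nu = K, nv = 0)
  U <- sv$u                                  # orthonormal scores
  B <- crossprod(U, x)                       # K x L coefficients
  rss <- pmax(colSums(x^2) - colSums(B^2), 0)
  s2 <- rss / (n - K - 1)
  z <- t(B) / sqrt(pmax(s2, .Machine$double.eps))
  d2 <- robustMahalanobis(z)
  lambda <- median(d2) / qchisq(0.5, df = K)
  p <- pchisq(d2 / lambda, df = K, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  q <- qvalueStorey(p)
  OutlierScan(K = as.integer(K), z = z, d2 = d2, lambda = lambda,
              p = p, q = as.numeric(q), significant = q < qThreshold,
              qThreshold = qThreshold, loci = lociIds(gm)[keptLoci])
}

#' FST contrast between life-history tactics
#'
#' Multilocus Weir-Cockerham theta between tactic groups computed once
#' over all loci and once over a flagged outlier set, with their ratio:
#' the enrichment of tactic-associated differentiation in the outliers.
#'
#' @param gm a `GenotypeExperiment` whose samples carry tactic labels.
#' @param outlierSet character vector of locus ids ("chrom:pos").
#' @return list (thetaAll, thetaOutliers, ratio).
#' @export
tacticFstContrast <- function(gm, outlierSet) {
  if (!length(outlierSet)) stop("outlier set is empty")
  tac <- tactics(gm)
  keep <- !is.na(tac)
  gm <- gm[, keep]
  thetaAll <- multilocusFst(gm, labels = tactics(gm))
  thetaOut <- multilocusFst(gm, labels = tactics(gm), loci = outlierSet)
  list(thetaAll = thetaAll, thetaOutliers = thetaOut,
       ratio = thetaOut / thetaAll)
}
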