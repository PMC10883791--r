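#' Yang relatedness statistic
#'
#' Computes the unadjusted Yang et al. genomic relationship for every
#' sample pair: A_jk = (1/L) * sum_i (x_ij - 2p_i)(x_ik - 2p_i) /
#' (2 p_i (1 - p_i)), over polymorphic loci (0 < p < 1, p the overall
#' alternate-allele frequency) where both samples are called
#' (pairwise-complete). Duplicated or full-sib-like samples score near
#' 1 + F; unrelated pairs near 0.
#'
#' @param gm a `GenotypeExperiment` with at least two samples.
#' @return symmetric samples x samples matrix.
#' @export
relatednessYang <- function(gm) {
  d <- dosage(gm)
  if (ncol(d) < 2) stop("relatedness needs at least two samples")
  n <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(n, 1L))
  poly <- n > 0 & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci for relatedness")
  d <- d[poly, , drop = FALSE]; p <- p[poly]
  s <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(s)
  s[!obs] <- 0
  L <- crossprod(obs)           # pairwise-complete locus counts
  if (any(L[upper.tri(L)] == 0))
    stop("a sample pair shares no called polymorphic loci")
  A <- crossprod(s) / L
  dimnames(A) <- list(colnames(d), colnames(d))
  A
}

#' Kin filter
#'
#' Flags, for every pair with Yang relatedness above `threshold`, the
#' member with more missing data (ties broken by lexicographic sample
#' id) and removes flagged samples so that one representative of each
#' kin cluster is retained.
#'
#' @param gm a `GenotypeExperiment`.
#' @param threshold relatedness above which a pair is treated as kin.
#' @return filtered `GenotypeExperiment`.
#' @export
kinFilter <- function(gm, threshold = 0.9) {
  A <- relatednessYang(gm)
  miss <- colMeans(is.na(dosage(gm)))
  ids <- colnames(gm)
  alive <- setNames(rep(TRUE, length(ids)), ids)
  repeat {
    Asub <- A[alive, alive, drop = FALSE]
    Asub[lower.tri(Asub, diag = TRUE)] <- -Inf
    hit <- which(Asub > threshold, arr.ind = TRUE)
    if (!nrow(hit)) break
    i <- rownames(Asub)[hit[1, 1]]; j <- colnames(Asub)[hit[1, 2]]
    victim <- if (miss[i] > miss[j]) i
              else if (miss[j] > miss[i]) j
              else max(i, j)
    alive[victim] <- FALSE
  }
  out <- gm[, alive]
  recordStep(gm, out, "kin", ids[!alive])
}

#' HDplot paralog diagnostics
#'
#' For every locus computes H, the fraction of called samples that are
#' heterozygous, and D, the read-ratio deviation over heterozygous
#' calls: (sum ref reads - sum alt reads) / sqrt(sum total reads)
#' (0 when a locus has no heterozygotes). Merged paralogs show excess H
#' and/or |D|.
#'
#' @param gm a `GenotypeExperiment` with ref/alt allele-depth assays.
#' @return data.frame (locus, H, D, nHet).
#' @export
hdplot <- function(gm) {
  ad <- alleleDepth(gm)
  if (is.null(ad))
    stop("hdplot requires allele-depth (AD) assays; none present")
  d <- dosage(gm)
  het <- !is.na(d) & d == 1L
  H <- rowSums(het) / pmax(rowSums(!is.na(d)), 1L)
  refSum <- rowSums(ad$ref * het, na.rm = TRUE)
  altSum <- rowSums(ad$alt * het, na.rm = TRUE)
  tot <- refSum + altSum
  D <- ifelse(tot > 0, (refSum - altSum) / sqrt(tot), 0)
  data.frame(locus = lociIds(gm), H = H, D = D,
             nHet = rowSums(het), stringsAsFactors = FALSE)
}

#' HDplot filter
#'
#' Removes loci classified as non-singleton (putative merged paralogs):
#' H strictly above `hThreshold` or |D| strictly above `dThreshold`.
#'
#' @param gm a `GenotypeExperiment` with AD assays.
#' @param hThreshold heterozygote-fraction threshold.
#' @param dThreshold absolute read-ratio-deviation threshold.
#' @return filtered `GenotypeExperiment`.
#' @export
hdplotFilter <- function(gm, hThreshold = 0.6, dThreshold = 7) {
  hd <- hdplot(gm)
  keep <- hd$H <= hThreshold & abs(hd$D) <= dThreshold
  out <- gm[keep, ]
  recordStep(gm, out, "hdplot", lociIds(gm)[!keep])
}

#' Identity-by-missingness check
#'
#' PCA of the binary missingness-indicator matrix followed by 2-means on
#' the first two axes and a mean silhouette score: values above ~0.5
#' indicate batch-like clustering of missing data.
#'
#' @param gm a `GenotypeExperiment`.
#' @return list with `scores` (samples x 2), `silhouette` (mean width),
#'   `clusters`, and `status` ("ok" or "no variation").
#' @export
ibmCheck <- function(gm) {
  ind <- is.na(dosage(gm)) * 1
  keep <- apply(ind, 1, var) > 0
  if (!any(keep))
    return(list(scores = NULL, silhouette = NA_real_, clusters = NULL,
                status = "no variation"))
  pc <- prcomp(t(ind[keep, , drop = FALSE]), center = TRUE,
               scale. = FALSE)
  sc <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  km <- kmeans(sc, centers = 2, nstart = 5)
  sil <- cluster::silhouette(km$cluster, dist(sc))
  list(scores = sc, silhouette = mean(sil[, "sil_width"]),
       clusters = km$cluster, status = "ok")
}
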