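# shared helper: samples x loci matrix, per-locus mean imputation of
# missing dosages, optional unit scaling, zero-variance loci dropped
imputedDosage <- function(gm, scale = TRUE) {
  d <- t(dosage(gm))            # samples x loci
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu)) stop("locus with all genotypes missing")
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  v <- apply(d, 2, var)
  keep <- v > 0
  d <- d[, keep, drop = FALSE]
  d <- scale(d, center = TRUE, scale = scale)
  attr(d, "keptLoci") <- which(keep)
  d
}

#' PCA of genotype dosages
#'
#' Missing dosages are mean-imputed per locus, loci are centred and
#' unit-scaled (zero-variance loci dropped), and the principal axes are
#' extracted by singular value decomposition.
#'
#' @param gm a `GenotypeExperiment` with >= 2 samples.
#' @param nAxes number of axes to return (clipped to what exists).
#' @return list with `scores` (samples x axes), `loadings`,
#'   `explained` (variance fractions, all axes), `eigenvalues`.
#' @export
pcaGenotypes <- function(gm, nAxes = 10) {
  if (ncol(gm) < 2) stop("PCA needs at least two samples")
  x <- imputedDosage(gm, scale = TRUE)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  nAxes <- min(nAxes, ncol(pc$x))
  list(scores = pc$x[, seq_len(nAxes), drop = FALSE],
       loadings = pc$rotation[, seq_len(nAxes), drop = FALSE],
       explained = ev / sum(ev), eigenvalues = ev)
}

#' IbdFit: one isolation-by-distance model fit
#'
#' @slot model `"linear"`, `"null"` or `"intercept"`.
#' @slot nPairs population pairs used.
#' @slot coefficients named numeric (possibly empty for the null model).
#' @slot rss residual sum of squares.
#' @slot adjR2 adjusted R-squared (`NA` for parameter-free models).
#' @slot pSlope p-value of the distance slope (`NA` otherwise).
#' @slot aicc small-sample-corrected AIC.
#' @aliases IbdFit-class
#' @export IbdFit
#' @exportClass IbdFit
IbdFit <- setClass("IbdFit", slots = c(
  model = "character", nPairs = "integer", coefficients = "numeric",
  rss = "numeric", adjR2 = "numeric", pSlope = "numeric",
  aicc = "numeric"))

setMethod("show", "IbdFit", function(object) {
  cat(sprintf("IbdFit[%s]: n=%d AICc=%.3f adjR2=%s p=%s\n",
              object@model, object@nPairs, object@aicc,
              format(object@adjR2), format(object@pSlope)))
})

# AICc with k counting all estimated parameters incl. residual variance
aiccFromRss <- function(n, rss, k) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Isolation-by-distance model selection
#'
#' Regresses linearised differentiation, theta/(1-theta), on pairwise
#' geographic distance and ranks candidate models by AICc: the linear
#' model (slope + intercept + variance, k = 3), a zero-parameter null
#' (response residuals as-is, k = 1 for the variance), and optionally an
#' intercept-only model (k = 2). Populations in `exclude` are dropped
#' before forming pairs.
#'
#' @param fst an [FstMatrix-class].
#' @param dist square symmetric distance matrix (km) with population
#'   dimnames aligned to `fst@groups`.
#' @param exclude character vector of populations to leave out.
#' @param includeIntercept also fit the intercept-only model.
#' @return list of [IbdFit-class] sorted by ascending AICc.
#' @export
ibdFit <- function(fst, dist, exclude = character(),
                   includeIntercept = FALSE) {
  groups <- setdiff(fst@groups, exclude)
  if (!all(groups %in% rownames(dist)))
    stop("distance matrix does not cover all populations")
  pairs <- t(combn(groups, 2))
  th <- fst@theta[pairs]
  if (any(th >= 1))
    stop("a pair has theta = 1; linearised FST is infinite")
  y <- th / (1 - th)
  x <- dist[pairs]
  n <- length(y)
  fits <- list()
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fits$linear <- IbdFit(
    model = "linear", nPairs = as.integer(n),
    coefficients = coef(fit),
    rss = sum(fit$residuals^2), adjR2 = sm$adj.r.squared,
    pSlope = sm$coefficients["x", "Pr(>|t|)"],
    aicc = aiccFromRss(n, sum(fit$residuals^2), 3))
  fits$null <- IbdFit(
    model = "null", nPairs = as.integer(n),
    coefficients = setNames(numeric(), character()),
    rss = sum(y^2), adjR2 = NA_real_, pSlope = NA_real_,
    aicc = aiccFromRss(n, sum(y^2), 1))
  if (includeIntercept) {
    r <- y - mean(y)
    fits$intercept <- IbdFit(
      model = "intercept", nPairs = as.integer(n),
      coefficients = c(intercept = mean(y)),
      rss = sum(r^2), adjR2 = NA_real_, pSlope = NA_real_,
      aicc = aiccFromRss(n, sum(r^2), 2))
  }
  fits[order(vapply(fits, function(f) f@aicc, numeric(1)))]
}

#' AmovaResult: two-level nested analysis of molecular variance
#'
#' @slot table data.frame with one row per stratum (between primary,
#'   between secondary within primary, within secondary): df, SS,
#'   variance component, percentage of variation, permutation p-value.
#' @aliases AmovaResult-class
#' @export AmovaResult
#' @exportClass AmovaResult
AmovaResult <- setClass("AmovaResult", slots = c(table = "data.frame"))

setValidity("AmovaResult", function(object) {
  t <- object@table
  if (abs(sum(t$percent) - 100) > 0.01)
    return("percentages must sum to 100")
  TRUE
})

setMethod("show", "AmovaResult", function(object) {
  print(object@table, row.names = FALSE)
})

# nested sums of squares from a squared-distance matrix:
# SS(set) = sum_{i<j in set} d2_ij / |set|
ssFromD2 <- function(D2, sets) {
  sum(vapply(sets, function(s)
    sum(D2[s, s, drop = FALSE]) / (2 * length(s)), numeric(1)))
}

amovaComponents <- function(D2, primary, secondary) {
  N <- nrow(D2)
  secKey <- paste(primary, secondary, sep = "\r")
  priSets <- split(seq_len(N), primary)
  secSets <- split(seq_len(N), secKey)
  ssTotal <- sum(D2) / (2 * N)
  ssWithinSec <- ssFromD2(D2, secSets)
  ssWithinPri <- ssFromD2(D2, priSets)
  ssAP <- ssWithinPri - ssWithinSec   # among secondary within primary
  ssAG <- ssTotal - ssWithinPri       # among primary
  a <- length(priSets)
  bTot <- length(secSets)
  dfAG <- a - 1
  dfAP <- bTot - a
  dfWP <- N - bTot
  nSec <- lengths(secSets)
  nPri <- lengths(priSets)
  secPri <- vapply(strsplit(names(secSets), "\r"), `[`, character(1), 1)
  sumSq_g <- vapply(names(priSets), function(g)
    sum(nSec[secPri == g]^2) / nPri[[g]], numeric(1))
  n1 <- (N - sum(sumSq_g)) / dfAP
  n2 <- (sum(sumSq_g) - sum(nSec^2) / N) / dfAG
  n3 <- (N - sum(nPri^2) / N) / dfAG
  msWP <- ssWithinSec / dfWP
  msAP <- ssAP / dfAP
  msAG <- ssAG / dfAG
  sigC <- msWP
  sigB <- (msAP - sigC) / n1
  sigA <- (msAG - sigC - n2 * sigB) / n3
  list(ss = c(ssAG, ssAP, ssWithinSec), df = c(dfAG, dfAP, dfWP),
       sigma = c(sigA, sigB, sigC))
}

#' Two-level nested AMOVA on genotype distances
#'
#' Partitions squared-Euclidean distances between mean-imputed dosage
#' vectors into among-primary, among-secondary-within-primary and
#' within-secondary variance components using the standard nested
#' coefficients for unbalanced designs; percentage of variation is each
#' component over their sum. Permutation p-values: the primary component
#' permutes whole secondary groups across primary labels; the secondary
#' component permutes samples across secondary groups within each
#' primary group; the within component permutes samples freely (small
#' observed within-variance being the signal).
#'
#' @param gm a `GenotypeExperiment`.
#' @param primary,secondary names of colData columns (e.g. `"group"`,
#'   `"tactic"`) or per-sample label vectors.
#' @param nPerm permutation count.
#' @param seed RNG seed.
#' @return an [AmovaResult-class].
#' @export
amovaTwoLevel <- function(gm, primary = "group", secondary = "tactic",
                          nPerm = 1000, seed = 1L) {
  cd <- SummarizedExperiment::colData(gm)
  pri <- if (length(primary) == 1 && primary %in% colnames(cd))
    as.character(cd[[primary]]) else as.character(primary)
  sec <- if (length(secondary) == 1 && secondary %in% colnames(cd))
    as.character(cd[[secondary]]) else as.character(secondary)
  if (anyNA(pri) || anyNA(sec))
    stop("every sample must be labelled for both factors")
  x <- imputedDosage(gm, scale = FALSE)
  D2 <- as.matrix(dist(x))^2
  obs <- amovaComponents(D2, pri, sec)
  set.seed(seed)
  secKey <- paste(pri, sec, sep = "\r")
  permA <- permB <- permC <- numeric(nPerm)
  uKey <- unique(secKey)
  keyPri <- pri[match(uKey, secKey)]
  for (b in seq_len(nPerm)) {
    # whole secondary groups across primary labels; cells stay distinct
    # so the nesting never degenerates under relabelling
    newPri <- sample(keyPri)[match(secKey, uKey)]
    permA[b] <- amovaComponents(D2, newPri, secKey)$sigma[1]
    # samples across secondary groups within primary
    secP <- sec
    for (g in unique(pri)) {
      idx <- which(pri == g)
      secP[idx] <- sec[sample(idx)]
    }
    permB[b] <- amovaComponents(D2, pri, secP)$sigma[2]
    # free permutation of samples
    sh <- sample.int(nrow(D2))
    permC[b] <- amovaComponents(D2, pri[sh], sec[sh])$sigma[3]
  }
  pA <- (sum(permA >= obs$sigma[1]) + 1) / (nPerm + 1)
  pB <- (sum(permB >= obs$sigma[2]) + 1) / (nPerm + 1)
  pC <- (sum(permC <= obs$sigma[3]) + 1) / (nPerm + 1)
  pct <- 100 * obs$sigma / sum(obs$sigma)
  AmovaResult(table = data.frame(
    stratum = c("between_primary", "between_secondary_within_primary",
                "within_secondary"),
    df = obs$df, SS = obs$ss, sigma = obs$sigma, percent = pct,
    p = c(pA, pB, pC), stringsAsFactors = FALSE))
}

#' MigrationGraph: directional relative migration
#'
#' @slot m directed matrix, row = source, column = sink, scaled so the
#'   largest entry is 1; diagonal 0.
#' @slot statistic differentiation statistic used.
#' @slot nBoot bootstrap iterations.
#' @slot ciLow,ciHigh bootstrap bounds on the normalised rates.
#' @aliases MigrationGraph-class
#' @export MigrationGraph
#' @exportClass MigrationGraph
MigrationGraph <- setClass("MigrationGraph", slots = c(
  m = "matrix", statistic = "character", nBoot = "integer",
  ciLow = "matrix", ciHigh = "matrix"))

setValidity("MigrationGraph", function(object) {
  if (abs(max(object@m) - 1) > 1e-9)
    return("normalised matrix must have maximum 1")
  if (any(diag(object@m) != 0)) return("diagonal must be 0")
  TRUE
})

setMethod("show", "MigrationGraph", function(object) {
  cat("MigrationGraph (", object@statistic, ") over",
      nrow(object@m), "populations\n")
  print(round(object@m, 3))
})

# Nei GST (ratio of sums across loci) between two frequency vectors,
# treating each as one population of the pair
gstPair <- function(p1, p2) {
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pb <- (p1 + p2) / 2
  ht <- 2 * pb * (1 - pb)
  if (sum(ht) == 0) return(0)
  sum(ht - hs) / sum(ht)
}

#' Directional relative migration from a migrant pool
#'
#' For every ordered population pair, a hypothetical migrant pool is
#' formed as the unweighted arithmetic mean of the two populations'
#' allele frequencies; Nei's GST (ratio of sums across loci) between the
#' pool and each member measures how far each population sits from the
#' pool, and the member closer to the pool is treated as the origin.
#' Raw directional flow a -> b is ((1/g_a) - 1)/4 with g_a the
#' pool-to-a differentiation; the matrix is normalised by its maximum.
#' Non-positive g are capped at `cap` before normalisation. Locus
#' bootstrap gives per-edge intervals.
#'
#' @param gm a `GenotypeExperiment` with >= 2 groups.
#' @param nBoot bootstrap iterations over loci.
#' @param cap raw-flow cap used when differentiation is <= 0.
#' @param seed RNG seed.
#' @return a [MigrationGraph-class].
#' @export
divMigrate <- function(gm, nBoot = 1000, cap = 1e4, seed = 1L) {
  af <- alleleFreqs(gm)
  pops <- colnames(af@freq)
  if (length(pops) < 2) stop("divMigrate needs at least two groups")
  k <- length(pops)
  rawFlow <- function(freqIdx) {
    raw <- matrix(0, k, k, dimnames = list(pops, pops))
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      pa <- af@freq[freqIdx, pops[i]]; pb <- af@freq[freqIdx, pops[j]]
      ok <- !is.na(pa) & !is.na(pb)
      pool <- (pa[ok] + pb[ok]) / 2
      ga <- gstPair(pa[ok], pool)
      gb <- gstPair(pb[ok], pool)
      fa <- if (ga <= 0) cap else min((1 / ga - 1) / 4, cap)
      fb <- if (gb <= 0) cap else min((1 / gb - 1) / 4, cap)
      raw[pops[i], pops[j]] <- fa
      raw[pops[j], pops[i]] <- fb
    }
    raw
  }
  L <- nrow(af@freq)
  raw <- rawFlow(seq_len(L))
  m <- raw / max(raw)
  set.seed(seed)
  boots <- array(NA_real_, c(k, k, nBoot))
  for (b in seq_len(nBoot)) {
    idx <- sample.int(L, replace = TRUE)
    rb <- rawFlow(idx)
    boots[, , b] <- rb / max(rb)
  }
  lo <- apply(boots, c(1, 2), quantile, 0.025)
  hi <- apply(boots, c(1, 2), quantile, 0.975)
  dimnames(lo) <- dimnames(hi) <- dimnames(m)
  MigrationGraph(m = m, statistic = "GST", nBoot = as.integer(nBoot),
                 ciLow = lo, ciHigh = hi)
}
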