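#' MixtureResult: Bayesian mixture composition of a mixed-stock sample
#'
#' @slot posterior individuals x populations posterior origin
#'   probabilities (rows sum to 1).
#' @slot kept logical odds-filter verdict per individual (all `TRUE`
#'   until [oddsFilter()] is applied).
#' @slot mixingProps data.frame: year, population, posterior mean and SD
#'   of the mixing proportion.
#' @slot year per-individual year label.
#' @slot allMissing individuals with no called panel genotype (reported
#'   with a uniform posterior and flagged).
#' @slot nSweeps,burnIn MCMC bookkeeping.
#' @aliases MixtureResult-class
#' @export MixtureResult
#' @exportClass MixtureResult
MixtureResult <- setClass("MixtureResult", slots = c(
  posterior = "matrix", kept = "logical", mixingProps = "data.frame",
  year = "character", allMissing = "logical", nSweeps = "integer",
  burnIn = "integer"))

setValidity("MixtureResult", function(object) {
  rs <- rowSums(object@posterior)
  if (any(abs(rs - 1) > 1e-9))
    return("posterior rows must sum to 1")
  ok <- vapply(split(object@mixingProps$mean,
                     object@mixingProps$year),
               function(v) abs(sum(v) - 1) < 1e-6, logical(1))
  if (!all(ok)) return("mixing proportions must sum to 1 per year")
  TRUE
})

setMethod("show", "MixtureResult", function(object) {
  cat("MixtureResult:", nrow(object@posterior), "individuals,",
      ncol(object@posterior), "candidate populations;",
      sum(object@kept), "kept by the odds filter\n")
})

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Bayesian mixture composition by Gibbs sampling
#'
#' Conditional genetic stock identification: reference allele
#' frequencies are fixed at their posterior means under a per-allele
#' Dirichlet(1/2) prior, each mixture fish's origin indicator z is
#' Gibbs-sampled proportional to pi_i times its HWE genotype likelihood
#' over the panel loci (missing genotypes skipped), and the mixing
#' vector pi is drawn from Dirichlet(1 + counts). Sweeps after burn-in
#' give the per-individual posterior origin probabilities (mean of z
#' indicators) and the posterior mean mixing proportions. Years are
#' estimated independently. Fish with no called panel genotype are
#' flagged and reported with a uniform posterior.
#'
#' @param ref reference `GenotypeExperiment`.
#' @param mix mixture `GenotypeExperiment` (year labels used if
#'   present).
#' @param panel locus-id vector or [PanelSpec-class]; must be present in
#'   both matrices.
#' @param nSweeps total Gibbs sweeps (default 2000).
#' @param burnIn sweeps discarded (default 100).
#' @param seed RNG seed.
#' @return a [MixtureResult-class].
#' @export
mixtureEstimate <- function(ref, mix, panel = NULL, nSweeps = 2000,
                            burnIn = 100, seed = 1L) {
  if (nSweeps <= burnIn) stop("chain length must exceed burn-in")
  if (!is.null(panel)) {
    if (is(panel, "PanelSpec")) panel <- panel@union
    refSel <- lociIds(ref) %in% panel
    mixSel <- lociIds(mix) %in% panel
    if (!any(refSel) || !any(mixSel))
      stop("panel loci missing from reference or mixture")
    ref <- ref[refSel, ]; mix <- mix[mixSel, ]
  }
  common <- intersect(lociIds(ref), lociIds(mix))
  if (!length(common))
    stop("reference and mixture share no loci")
  ref <- ref[lociIds(ref) %in% common, ]
  mix <- mix[lociIds(mix) %in% common, ]
  dRef <- dosage(ref); dMix <- dosage(mix)
  grp <- as.character(popGroups(ref))
  groups <- sort(unique(grp))
  # posterior-mean reference frequencies under Dirichlet(1/2) per allele
  p <- matrix(NA_real_, nrow(dRef), length(groups),
              dimnames = list(rownames(dRef), groups))
  for (g in groups) {
    sub <- dRef[, grp == g, drop = FALSE]
    n <- rowSums(!is.na(sub))
    p[, g] <- (rowSums(sub, na.rm = TRUE) + 0.5) / (2 * n + 1)
  }
  ll <- hweLogLik(dMix, p)
  allMissing <- colSums(!is.na(dMix)) == 0
  lik <- exp(ll - apply(ll, 1, max))
  year <- sampleYears(mix)
  year[is.na(year)] <- "all"
  set.seed(seed)
  K <- length(groups)
  posterior <- matrix(0, ncol(dMix), K,
                      dimnames = list(colnames(dMix), groups))
  props <- list()
  for (yr in unique(year)) {
    idx <- which(year == yr)
    likY <- lik[idx, , drop = FALSE]
    pi <- rep(1 / K, K)
    zAcc <- matrix(0, length(idx), K)
    piAcc <- matrix(0, nSweeps - burnIn, K)
    for (s in seq_len(nSweeps)) {
      w <- likY * rep(pi, each = length(idx))
      w <- w / rowSums(w)
      z <- apply(w, 1, function(r) sample.int(K, 1, prob = r))
      counts <- tabulate(z, nbins = K)
      pi <- rdirichlet1(1 + counts)
      if (s > burnIn) {
        zAcc[cbind(seq_along(z), z)] <- zAcc[cbind(seq_along(z), z)] + 1
        piAcc[s - burnIn, ] <- pi
      }
    }
    posterior[idx, ] <- zAcc / (nSweeps - burnIn)
    props[[yr]] <- data.frame(
      year = yr, population = groups,
      mean = colMeans(piAcc), sd = apply(piAcc, 2, sd),
      stringsAsFactors = FALSE)
  }
  posterior[allMissing, ] <- 1 / K
  MixtureResult(posterior = posterior,
                kept = rep(TRUE, nrow(posterior)),
                mixingProps = do.call(rbind, props),
                year = unname(year), allMissing = unname(allMissing),
                nSweeps = as.integer(nSweeps),
                burnIn = as.integer(burnIn))
}

#' Posterior-odds filter
#'
#' Keeps an individual only when its largest posterior origin
#' probability is at least `ratio` times the second largest (inclusive
#' at exactly `ratio`).
#'
#' @param mr a [MixtureResult-class].
#' @param ratio the required odds (default 10).
#' @return the `MixtureResult` with its `kept` slot updated.
#' @export
oddsFilter <- function(mr, ratio = 10) {
  post <- mr@posterior
  top2 <- t(apply(post, 1, function(r) sort(r, decreasing = TRUE)[1:2]))
  # inclusive boundary, robust to floating-point representation of the
  # posterior means
  mr@kept <- top2[, 1] >= ratio * top2[, 2] * (1 - 1e-12)
  mr
}

#' Contribution summaries and inter-annual homogeneity tests
#'
#' Per-year contribution percentages of (i) assigned river of origin
#' among odds-filter-kept individuals and (ii) life-history tactic among
#' tactic-identified fish (tactic `marine` or `estuarine`; `mixed` and
#' missing are excluded), plus chi-squared homogeneity tests of the
#' year x category count tables (no continuity correction).
#'
#' @param mr a [MixtureResult-class] (after [oddsFilter()]).
#' @param tacticTable data.frame (sampleId, tactic, year) covering the
#'   mixture individuals.
#' @return list: `riverCounts`, `riverPercent`, `riverTest`,
#'   `tacticCounts`, `tacticPercent`, `tacticTest`.
#' @export
contributionSummary <- function(mr, tacticTable = NULL) {
  keptIds <- rownames(mr@posterior)[mr@kept]
  if (!length(keptIds)) stop("no individuals kept")
  years <- mr@year[mr@kept]
  if (any(table(years) == 0) || !length(years))
    stop("a year has zero kept individuals")
  assigned <- colnames(mr@posterior)[max.col(
    mr@posterior[mr@kept, , drop = FALSE], ties.method = "first")]
  riverCounts <- table(year = years, river = assigned)
  riverPercent <- 100 * prop.table(riverCounts, 1)
  riverTest <- if (nrow(riverCounts) > 1)
    suppressWarnings(chisq.test(
      riverCounts[, colSums(riverCounts) > 0, drop = FALSE],
      correct = FALSE))
  else NULL
  tacticCounts <- tacticPercent <- tacticTest <- NULL
  if (!is.null(tacticTable)) {
    m <- match(keptIds, tacticTable$sampleId)
    tac <- tacticTable$tactic[m]
    yr <- as.character(tacticTable$year[m])
    yr[is.na(yr)] <- years[is.na(yr)]
    sel <- tac %in% c("marine", "estuarine")
    tacticCounts <- table(year = yr[sel], tactic = tac[sel])
    tacticPercent <- 100 * prop.table(tacticCounts, 1)
    tacticTest <- if (nrow(tacticCounts) > 1)
      suppressWarnings(chisq.test(tacticCounts, correct = FALSE))
    else NULL
  }
  list(riverCounts = riverCounts, riverPercent = riverPercent,
       riverTest = riverTest, tacticCounts = tacticCounts,
       tacticPercent = tacticPercent, tacticTest = tacticTest)
}
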