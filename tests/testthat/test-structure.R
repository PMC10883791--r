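test_that("genotype PCA separates fixed-difference populations", {
  set.seed(2)
  # two populations fixed for opposite alleles at every locus, plus a
  # sprinkle of noise loci so variances are positive
  n <- 20; L <- 50
  d <- cbind(matrix(0L, L, n / 2), matrix(2L, L, n / 2))
  noise <- matrix(sample(0:2, 10 * n, TRUE), 10, n)
  gm <- gmFromMatrix(rbind(d, noise),
                     group = rep(c("A", "B"), each = n / 2))
  pc <- pcaGenotypes(gm, 2)
  grp <- as.numeric(factor(popGroups(gm)))
  fit <- summary(lm(pc$scores[, 1] ~ grp))
  expect_gt(fit$r.squared, 0.99)

  # duplicated rows get identical scores
  dd <- dosage(gm)[, c(1, 1, 5, 9, 12, 15)]
  gm2 <- gmFromMatrix(dd, group = rep("P", 6))
  pc2 <- pcaGenotypes(gm2, 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], ignore_attr = TRUE)

  # 4-sample hand matrix: scores equal the eigen-decomposition route
  dH <- rbind(c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 1L), c(0L, 0L, 2L, 2L))
  gmH <- gmFromMatrix(dH)
  pcH <- pcaGenotypes(gmH, 3)
  x <- scale(t(dH))
  ev <- eigen(cov(x))
  scoresByHand <- x %*% ev$vectors
  for (k in seq_len(ncol(pcH$scores)))
    expect_equal(abs(pcH$scores[, k]), abs(scoresByHand[, k]),
                 ignore_attr = TRUE, tolerance = 1e-8)
  # an all-missing locus cannot be imputed
  dBad <- dH; dBad[1, ] <- NA
  expect_error(pcaGenotypes(gmFromMatrix(dBad)), "all genotypes missing")
})

test_that("pairwise WC-84 theta matches the oracle and its bounds", {
  # two-population toy: exact equality with the brute-force oracle
  set.seed(8)
  d <- matrix(sample(c(0:2, NA), 240, TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), 20, 12)
  grp <- rep(c("A", "B"), each = 6)
  gm <- gmFromMatrix(d, group = grp)
  fst <- pairwiseFst(gm, nBoot = 100, seed = 1)
  expect_equal(fst@theta["A", "B"], oracleWcTheta(d, grp),
               tolerance = 1e-9)

  # a random split of one panmictic population: theta ~ 0, CI covers 0
  ref <- simulateReference(twoPopConfig(41, 1e-6, nLoci = 1500L,
                                        n = 40L))
  f0 <- pairwiseFst(ref$gm, nBoot = 200, seed = 2)
  expect_lt(abs(f0@theta["A", "B"]), 0.01)
  expect_lte(f0@ciLow["A", "B"], 0)
  expect_gte(f0@ciHigh["A", "B"], 0)

  # fixed difference, equal n, no missingness: theta = 1 exactly
  dFix <- cbind(matrix(0L, 30, 8), matrix(2L, 30, 8))
  gmF <- gmFromMatrix(dFix, group = rep(c("A", "B"), each = 8))
  fF <- pairwiseFst(gmF, nBoot = 50, seed = 3)
  expect_equal(fF@theta["A", "B"], 1)

  # invariance to locus order and to allele-label swap
  sh <- sample(nrow(d))
  expect_equal(multilocusFst(gmFromMatrix(d[sh, ], group = grp)),
               multilocusFst(gm), tolerance = 1e-12)
  expect_equal(multilocusFst(gmFromMatrix(2L - d, group = grp)),
               multilocusFst(gm), tolerance = 1e-12)
})

test_that("isolation-by-distance model selection behaves", {
  # exactly linear relation: adjusted R2 = 1 and the slope model wins
  groups <- LETTERS[1:6]
  dist <- as.matrix(dist(seq(0, 500, length.out = 6))) * 1
  dimnames(dist) <- list(groups, groups)
  set.seed(7)
  th <- 0.001 + 1e-4 * dist +
    matrix(runif(36, 0, 1e-7), 6, 6)   # essentially exact linearity
  th <- (th + t(th)) / 2
  theta <- th / (1 + th)
  diag(theta) <- 0
  fst <- FstMatrix(groups = groups, theta = theta, ciLow = theta,
                   ciHigh = theta, pValue = theta * 0,
                   nLoci = theta * 0 + 100)
  fits <- ibdFit(fst, dist)
  expect_identical(fits[[1]]@model, "linear")
  expect_gt(fits[[1]]@adjR2, 0.999)

  # AICc approaches plain AIC as n grows (correction term vanishes)
  n <- 1e6; k <- 3; rss <- 123.4
  aic <- n * log(rss / n) + 2 * k
  expect_lt(abs(popGSI:::aiccFromRss(n, rss, k) - aic), 1e-4)

  # a theta = 1 pair makes the linearised response infinite
  thetaBad <- theta; thetaBad["A", "B"] <- thetaBad["B", "A"] <- 1
  fstBad <- FstMatrix(groups = groups, theta = thetaBad,
                      ciLow = thetaBad, ciHigh = thetaBad,
                      pValue = thetaBad * 0, nLoci = thetaBad * 0 + 1)
  expect_error(ibdFit(fstBad, dist), "theta = 1")

  # permuted distances: slope p is not systematically small
  set.seed(9)
  thNoise <- theta + runif(length(theta), 0, 1e-4)
  thNoise <- (thNoise + t(thNoise)) / 2; diag(thNoise) <- 0
  ps <- vapply(1:40, function(i) {
    perm <- sample(groups)
    dPerm <- dist[perm, perm]
    dimnames(dPerm) <- list(groups, groups)
    f <- ibdFit(FstMatrix(groups = groups, theta = thNoise,
                          ciLow = thNoise, ciHigh = thNoise,
                          pValue = thNoise * 0,
                          nLoci = thNoise * 0 + 1), dPerm)
    models <- vapply(f, function(x) x@model, character(1))
    f[[which(models == "linear")]]@pSlope
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("tree distances recover the planted IBD relation", {
  # drift proportional to distance: the slope model must beat the null
  wins <- 0
  for (s in 1:8) {
    cfg <- simpleConfig(200 + s,
                        "((A:0.01,B:0.012):0.01,(C:0.02,D:0.025):0.01);",
                        c(A = 25L, B = 25L, C = 25L, D = 25L),
                        nLoci = 800L)
    ref <- simulateReference(cfg)
    fst <- pairwiseFst(ref$gm, nBoot = 20, seed = s)
    fits <- ibdFit(fst, treeDistancesKm(cfg))
    if (fits[[1]]@model == "linear") wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("two-level AMOVA components, percentages and permutations", {
  # 12-sample toy: sums of squares equal the centroid-identity oracle
  set.seed(12)
  d <- matrix(sample(0:2, 12 * 30, TRUE), 30, 12)
  pri <- rep(c("R1", "R2"), each = 6)
  sec <- rep(c("est", "mar", "est", "mar"), times = c(3, 3, 3, 3))
  gm <- gmFromMatrix(d, group = pri, tactic = sec)
  am <- amovaTwoLevel(gm, "group", "tactic", nPerm = 50, seed = 1)
  o <- oracleAmovaSS(t(d), pri, sec)
  expect_equal(am@table$SS,
               c(o$amongPrimary, o$amongSecondary, o$withinSecondary),
               tolerance = 1e-9)
  expect_equal(sum(am@table$percent), 100, tolerance = 1e-6)
  expect_equal(sum(am@table$df), ncol(gm) - 1)

  # two fixed-difference primary groups: nearly all variation between
  dF <- cbind(matrix(0L, 40, 6), matrix(2L, 40, 6))
  gmF <- gmFromMatrix(dF, group = pri, tactic = sec)
  amF <- amovaTwoLevel(gmF, "group", "tactic", nPerm = 50, seed = 2)
  expect_gt(amF@table$percent[1], 90)

  # random labels: no structure, permutation p mostly insignificant
  sig <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    dr <- matrix(sample(0:2, 16 * 40, TRUE), 40, 16)
    gmr <- gmFromMatrix(dr, group = sample(rep(c("R1", "R2"), 8)),
                        tactic = sample(rep(c("e", "m"), 8)))
    amr <- amovaTwoLevel(gmr, "group", "tactic", nPerm = 60,
                         seed = s)
    if (amr@table$p[1] < 0.05) sig <- sig + 1
  }
  expect_lte(sig, 2)

  # unlabeled samples are rejected
  gmBad <- gmFromMatrix(d, group = pri)
  expect_error(amovaTwoLevel(gmBad, "group", "tactic"), "labelled")
})

test_that("directional migration from a migrant pool", {
  # 3-population toy: full matrix equals a hand evaluation of the
  # pool/GST/flow formulas
  freq <- cbind(A = c(0.1, 0.5, 0.9, 0.3),
                B = c(0.2, 0.4, 0.8, 0.5),
                C = c(0.9, 0.1, 0.2, 0.6))
  nc <- matrix(50L, 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4, width = 1),
                               ref = "A", alt = "G")
  # build genotypes whose group frequencies are exactly freq
  mkPop <- function(p, n = 10) sapply(p, function(pp) {
    nAlt <- round(2 * n * pp)
    g <- c(rep(2L, nAlt %/% 2), rep(1L, nAlt %% 2))
    c(g, rep(0L, n - length(g)))
  })
  d <- t(rbind(mkPop(freq[, "A"]), mkPop(freq[, "B"]),
               mkPop(freq[, "C"])))
  gm <- gmFromMatrix(d, group = rep(c("A", "B", "C"), each = 10))
  mg <- divMigrate(gm, nBoot = 10, seed = 1)

  af <- alleleFreqs(gm)@freq
  raw <- matrix(0, 3, 3, dimnames = dimnames(mg@m))
  for (i in 1:2) for (j in (i + 1):3) {
    pa <- af[, i]; pb <- af[, j]; pool <- (pa + pb) / 2
    g <- function(p1, p2) {
      hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
      ht <- 2 * ((p1 + p2) / 2) * (1 - (p1 + p2) / 2)
      sum(ht - hs) / sum(ht)
    }
    raw[i, j] <- (1 / g(pa, pool) - 1) / 4
    raw[j, i] <- (1 / g(pb, pool) - 1) / 4
  }
  expect_equal(mg@m, raw / max(raw), tolerance = 1e-9)
  # normalisation leaves exactly one entry at 1
  expect_identical(sum(mg@m == 1), 1L)

  # identical populations: flow is symmetric
  dSame <- cbind(d[, 1:10], d[, 1:10])
  gmS <- gmFromMatrix(dSame, group = rep(c("A", "B"), each = 10))
  mgS <- divMigrate(gmS, nBoot = 5, seed = 1)
  expect_equal(mgS@m[1, 2], mgS@m[2, 1])

  # planted one-way flow: composited population receives more
  wins <- 0
  for (s in 1:8) {
    set.seed(400 + s)
    L <- 600
    pa <- runif(L, 0.1, 0.9)
    pb <- plogis(qlogis(pa) + rnorm(L, 0, 0.9))
    pbMix <- 0.8 * pb + 0.2 * pa   # b receives migrants from a
    da <- matrix(rbinom(L * 40, 2, pa), L, 40)
    db <- matrix(rbinom(L * 40, 2, pbMix), L, 40)
    gmM <- gmFromMatrix(cbind(da, db),
                        group = rep(c("A", "B"), each = 40))
    mgM <- divMigrate(gmM, nBoot = 5, seed = s)
    if (mgM@m["A", "B"] > mgM@m["B", "A"]) wins <- wins + 1
  }
  expect_gte(wins, 7)
})
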