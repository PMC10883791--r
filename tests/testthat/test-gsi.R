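freqTable <- function(freq, chrom = NULL, pos = NULL) {
  L <- nrow(freq)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  AlleleFreqTable(
    freq = freq,
    nCalled = matrix(50L, L, ncol(freq),
                     dimnames = dimnames(freq)),
    loci = GenomicRanges::GRanges(
      chrom, IRanges::IRanges(pos, width = 1),
      ref = "A", alt = "G"))
}

test_that("allele frequency differences are plain absolute contrasts", {
  freq <- cbind(A = c(0.2, 0.0, 0.5, 0.9),
                B = c(0.2, 1.0, 0.3, 0.5),
                C = c(0.6, 0.5, 0.5, 0.1))
  rownames(freq) <- paste0("chr1:", 1:4 * 100)
  afd <- afdTable(freqTable(freq))
  expect_equal(afd[1, "A|B"], 0)          # identical frequencies
  expect_equal(afd[2, "A|B"], 1)          # fixed difference
  # 3-population toy: whole table by hand
  expect_equal(unname(afd[, "A|C"]), c(0.4, 0.5, 0.0, 0.8))
  expect_equal(unname(afd[, "B|C"]), c(0.4, 0.5, 0.2, 0.4))
})

test_that("balanced panel construction follows the greedy water-filling", {
  # two populations: the panel is simply the top loci by AFD
  freq2 <- cbind(A = seq(0.05, 0.95, length.out = 10),
                 B = rep(0.5, 10))
  rownames(freq2) <- paste0("chr1:", 1:10 * 100)
  ps2 <- buildBalancedPanel(freqTable(freq2), 4)
  afd2 <- abs(freq2[, "A"] - freq2[, "B"])
  topIds <- rownames(freq2)[order(-afd2)][1:4]
  expect_setequal(ps2@union, topIds)

  # 3-population 10-locus toy equals the independently re-derived trace
  set.seed(17)
  freq3 <- matrix(round(runif(30), 2), 10, 3,
                  dimnames = list(paste0("chr1:", 1:10 * 100),
                                  c("A", "B", "C")))
  ft <- freqTable(freq3)
  ps3 <- buildBalancedPanel(ft, 7)
  o <- oracleGreedyPanel(freq3,
                         data.frame(chrom = rep("chr1", 10),
                                    pos = 1:10 * 100), 7)
  expect_identical(ps3@union, rownames(freq3)[o$union])
  expect_equal(ps3@pairSums, o$sums[names(ps3@pairSums)])

  # pair-sum balance: spread bounded by the largest appended AFD^2
  maxAfd2 <- max(afdTable(ft)^2)
  expect_lte(max(ps3@pairSums) - min(ps3@pairSums), maxAfd2)

  # weakly differentiated pairs get longer lists
  ref <- simulateReference(simpleConfig(
    19, "(A:0.01,B:0.01,(C:0.1,D:0.1):0.02);",
    c(A = 40L, B = 40L, C = 40L, D = 40L), nLoci = 1500L))
  af <- alleleFreqs(ref$gm)
  ps <- buildBalancedPanel(af, 400)
  expect_gt(length(ps@pairLists[["A|B"]]),
            length(ps@pairLists[["C|D"]]))

  # determinism under shuffled input locus order
  sh <- sample(nrow(freq3))
  ftSh <- freqTable(freq3[sh, ], pos = (1:10 * 100L)[sh])
  psSh <- buildBalancedPanel(ftSh, 7)
  expect_setequal(psSh@union, ps3@union)

  # over-large targets are rejected
  expect_error(buildBalancedPanel(ft, 99), "exceeds")
})

test_that("self-assignment accuracy tracks differentiation", {
  # strong structure: near-perfect assignment
  ref <- simulateReference(twoPopConfig(23, 0.15, nLoci = 1000L,
                                        n = 50L))
  cv <- selfAssignCv(ref$gm, nIter = 20, seed = 1)
  expect_gt(mean(colMeans(cv@accuracy)), 0.95)
  expect_true(validObject(cv))
  # confusion matrix is diagonal-dominant under strong structure
  expect_gt(sum(diag(cv@confusion)) / sum(cv@confusion), 0.95)

  # panmictic split: chance-level accuracy
  ref0 <- simulateReference(twoPopConfig(24, 1e-6, nLoci = 800L,
                                         n = 40L))
  cv0 <- selfAssignCv(ref0$gm, trainProps = 0.7, lociProps = 1,
                      nIter = 20, seed = 2)
  expect_lt(abs(mean(colMeans(cv0@accuracy)) - 0.5), 0.15)

  # a twin whose double sits in the training set is assigned home
  d <- dosage(ref$gm)
  dTwin <- cbind(d, d[, 1])
  gmT <- gmFromMatrix(dTwin, group = c(as.character(popGroups(ref$gm)),
                                       "A"))
  p <- popGSI:::smoothedFreqs(d, as.character(popGroups(ref$gm)))
  ll <- popGSI:::hweLogLik(dTwin[, ncol(dTwin), drop = FALSE], p)
  expect_identical(colnames(p)[which.max(ll)], "A")

  # accuracy is monotone nondecreasing in FST across the study's range
  accs <- vapply(c(0.01, 0.05, 0.15), function(f) {
    r <- simulateReference(twoPopConfig(25, f, nLoci = 150L, n = 40L))
    mean(colMeans(selfAssignCv(r$gm, trainProps = 0.7, lociProps = 1,
                               nIter = 10, seed = 3)@accuracy))
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})

test_that("panel-size choice is lexicographic on min accuracy then SD", {
  mkCv <- function(accA, accB, sd = 0.01, seed = 1) {
    set.seed(seed)
    acc <- cbind(A = rnorm(50, accA, sd), B = rnorm(50, accB, sd))
    acc[] <- pmin(pmax(acc, 0), 1)
    AssignmentCv(trainProp = 0.7, lociProp = 1, nIter = 50L,
                 accuracy = acc, byCell = list(cell = acc),
                 confusion = matrix(0L, 2, 2))
  }
  # a dominating panel wins outright
  res <- list(`500` = mkCv(0.80, 0.85), `1000` = mkCv(0.95, 0.96))
  expect_identical(as.integer(pickPanel(res)), 1000L)
  # min-accuracy tie: the lower-SD panel wins
  res2 <- list(`500` = mkCv(0.90, 0.98, sd = 0.002, seed = 2),
               `1000` = mkCv(0.90, 0.98, sd = 0.05, seed = 3))
  pick2 <- pickPanel(res2)
  expect_identical(as.integer(pick2), 500L)
  # synthetic sweep with a mid-size optimum is recovered
  res3 <- list(`500` = mkCv(0.85, 0.9, seed = 4),
               `2000` = mkCv(0.97, 0.97, seed = 5),
               `8000` = mkCv(0.93, 0.95, seed = 6))
  expect_identical(as.integer(pickPanel(res3)), 2000L)
})

test_that("the Gibbs sampler concentrates on the true origin mix", {
  cfg <- simpleConfig(29, "(A:0.1,B:0.1);", c(A = 50L, B = 50L),
                      nLoci = 800L,
                      mixture = list(list(
                        year = "2020", n = 80L,
                        origin = c(A = 1, B = 0),
                        estuarineProb = c(A = 0.5, B = 0.5))))
  ref <- simulateReference(cfg)
  mix <- simulateMixture(cfg, truthFreqTable(ref))
  mr <- mixtureEstimate(ref$gm, mix$gm, nSweeps = 800, burnIn = 100,
                        seed = 4)
  est <- setNames(mr@mixingProps$mean, mr@mixingProps$population)
  expect_gt(est[["A"]], 0.95)
  expect_true(validObject(mr))
  # posterior rows sum to one
  expect_lt(max(abs(rowSums(mr@posterior) - 1)), 1e-9)

  # an individual with no called genotype is flagged and uniform
  dMix <- dosage(mix$gm)
  dMix[, 1] <- NA
  gmM <- gmFromMatrix(dMix, chrom = as.character(
    GenomicRanges::seqnames(mix$gm)),
    pos = GenomicRanges::start(mix$gm),
    group = rep("KOK", ncol(dMix)))
  mr2 <- mixtureEstimate(ref$gm, gmM, nSweeps = 300, burnIn = 50,
                         seed = 5)
  expect_true(mr2@allMissing[1])
  expect_equal(unname(mr2@posterior[1, ]), c(0.5, 0.5))

  # guard rails
  expect_error(mixtureEstimate(ref$gm, mix$gm, nSweeps = 50,
                               burnIn = 100), "burn-in")
  off <- gmFromMatrix(dMix[1:5, ], chrom = rep("chrZ", 5),
                      pos = 1:5 * 7L, group = rep("KOK", ncol(dMix)))
  expect_error(mixtureEstimate(ref$gm, off, nSweeps = 200,
                               burnIn = 10), "no loci|share no loci")
})

test_that("posterior-odds filtering is inclusive at exactly tenfold", {
  post <- rbind(c(0.91, 0.09),          # 10.1x -> kept
                c(10 / 11, 1 / 11),     # exactly 10x -> kept
                c(0.8, 0.2),            # 4x -> dropped
                c(0.9, 0.1))            # 9x -> dropped
  colnames(post) <- c("A", "B")
  rownames(post) <- paste0("f", 1:4)
  mr <- MixtureResult(
    posterior = post, kept = rep(TRUE, 4),
    mixingProps = data.frame(year = "2020", population = c("A", "B"),
                             mean = c(0.5, 0.5), sd = c(0, 0)),
    year = rep("2020", 4), allMissing = rep(FALSE, 4),
    nSweeps = 10L, burnIn = 1L)
  out <- oddsFilter(mr, 10)
  expect_identical(unname(out@kept), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("contribution summaries reproduce worked percentages", {
  # 2020 mixed-stock tactic counts: 37 marine, 104 estuarine plus
  # 8 mixed and 3 unscored fish that stay out of the percentages
  n <- 152
  ids <- sprintf("k%03d", seq_len(n))
  post <- matrix(rep(c(0.99, 0.01), each = n), n, 2,
                 dimnames = list(ids, c("DEL", "GUE")))
  tac <- c(rep("marine", 37), rep("estuarine", 104),
           rep("mixed", 8), rep(NA, 3))
  mr <- MixtureResult(
    posterior = post, kept = rep(TRUE, n),
    mixingProps = data.frame(year = "2020",
                             population = c("DEL", "GUE"),
                             mean = c(0.99, 0.01), sd = c(0, 0)),
    year = rep("2020", n), allMissing = rep(FALSE, n),
    nSweeps = 10L, burnIn = 1L)
  contrib <- contributionSummary(
    mr, data.frame(sampleId = ids, tactic = tac, year = "2020"))
  pct <- contrib$tacticPercent
  expect_equal(round(pct["2020", "estuarine"], 1), 73.8)
  expect_equal(round(pct["2020", "marine"], 1), 26.2)

  # identical composition in both years: chi-squared 0, p = 1
  ids2 <- sprintf("m%03d", 1:80)
  post2 <- matrix(rep(c(0.95, 0.05), each = 80), 80, 2,
                  dimnames = list(ids2, c("A", "B")))
  mr2 <- MixtureResult(
    posterior = post2, kept = rep(TRUE, 80),
    mixingProps = data.frame(year = rep(c("Y1", "Y2"), each = 2),
                             population = c("A", "B", "A", "B"),
                             mean = c(0.95, 0.05, 0.95, 0.05),
                             sd = rep(0, 4)),
    year = rep(c("Y1", "Y2"), each = 40),
    allMissing = rep(FALSE, 80), nSweeps = 10L, burnIn = 1L)
  tac2 <- rep(rep(c("marine", "estuarine"), each = 20), 2)
  c2 <- contributionSummary(
    mr2, data.frame(sampleId = ids2, tactic = tac2,
                    year = rep(c("Y1", "Y2"), each = 40)))
  expect_equal(unname(c2$tacticTest$statistic), 0)
  expect_equal(c2$tacticTest$p.value, 1)

  # 2x2 toy equals the hand chi-squared formula
  tab <- matrix(c(30, 10, 20, 25), 2, 2)
  expect_equal(unname(suppressWarnings(
    chisq.test(tab, correct = FALSE))$statistic), oracleChisq(tab))
})

test_that("panel informativeness drives posterior recovery", {
  # matched mixtures, one resolved with an informative panel and one
  # with the least informative loci: the informative panel must give
  # a smaller proportion error
  cfg <- simpleConfig(33, "(A:0.06,B:0.06);", c(A = 50L, B = 50L),
                      nLoci = 1200L,
                      mixture = list(list(
                        year = "2020", n = 100L,
                        origin = c(A = 0.7, B = 0.3),
                        estuarineProb = c(A = 0.5, B = 0.5))))
  ref <- simulateReference(cfg)
  mix <- simulateMixture(cfg, truthFreqTable(ref))
  af <- alleleFreqs(ref$gm)
  afd <- afdTable(af)[, "A|B"]
  top <- names(sort(afd, decreasing = TRUE))[1:200]
  bottom <- names(sort(afd))[1:200]
  err <- function(panel) {
    mr <- mixtureEstimate(ref$gm, mix$gm, panel = panel,
                          nSweeps = 600, burnIn = 100, seed = 6)
    est <- setNames(mr@mixingProps$mean, mr@mixingProps$population)
    abs(est[["A"]] - 0.7)
  }
  expect_lt(err(top), err(bottom))
})
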