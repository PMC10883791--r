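# independent brute-force oracles; deliberately scalar, loop-based
# implementations kept free of the package's vectorised code paths

# single-locus WC-84 components accumulated by explicit loops
oracleWcTheta <- function(d, labels) {
  groups <- sort(unique(labels))
  r <- length(groups)
  sumA <- 0; sumAll <- 0
  for (l in seq_len(nrow(d))) {
    n <- p <- h <- numeric(r)
    for (k in seq_len(r)) {
      x <- d[l, labels == groups[k]]
      x <- x[!is.na(x)]
      n[k] <- length(x)
      if (n[k] == 0) break
      p[k] <- sum(x) / (2 * n[k])
      h[k] <- sum(x == 1) / n[k]
    }
    if (any(n == 0) || sum(n) <= r) next
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
         (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    sumA <- sumA + a
    sumAll <- sumAll + a + b + cc
  }
  sumA / sumAll
}

# AMOVA sums of squares through the centroid identity
# sum_{i<j in g} d2_ij / n_g == sum_i ||x_i - centroid_g||^2
oracleAmovaSS <- function(x, pri, sec) {
  ssDev <- function(rows) {
    ctr <- colMeans(x[rows, , drop = FALSE])
    s <- 0
    for (i in rows) s <- s + sum((x[i, ] - ctr)^2)
    s
  }
  total <- ssDev(seq_len(nrow(x)))
  wSec <- 0
  for (g in unique(paste(pri, sec))) {
    rows <- which(paste(pri, sec) == g)
    wSec <- wSec + ssDev(rows)
  }
  wPri <- 0
  for (g in unique(pri)) wPri <- wPri + ssDev(which(pri == g))
  list(amongPrimary = total - wPri,
       amongSecondary = wPri - wSec,
       withinSecondary = wSec)
}

oracleChisq <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

oracleHdplot <- function(d, refd, altd) {
  H <- D <- numeric(nrow(d))
  for (l in seq_len(nrow(d))) {
    called <- which(!is.na(d[l, ]))
    hets <- called[d[l, called] == 1]
    H[l] <- length(hets) / length(called)
    if (length(hets)) {
      r <- sum(refd[l, hets]); a <- sum(altd[l, hets])
      D[l] <- if (r + a > 0) (r - a) / sqrt(r + a) else 0
    }
  }
  list(H = H, D = D)
}

oracleYang <- function(d) {
  n <- ncol(d)
  p <- numeric(nrow(d))
  for (l in seq_len(nrow(d))) {
    x <- d[l, ][!is.na(d[l, ])]
    p[l] <- sum(x) / (2 * length(x))
  }
  A <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0; L <- 0
    for (l in seq_len(nrow(d))) {
      if (p[l] <= 0 || p[l] >= 1) next
      if (is.na(d[l, j]) || is.na(d[l, k])) next
      s <- s + (d[l, j] - 2 * p[l]) * (d[l, k] - 2 * p[l]) /
        (2 * p[l] * (1 - p[l]))
      L <- L + 1
    }
    A[j, k] <- s / L
  }
  A
}

# forward-scan LD pruning by explicit loops
oracleLdPrune <- function(d, chrom, pos, r2 = 0.5, win = 1e5) {
  keep <- logical(nrow(d))
  retained <- integer()
  for (i in seq_len(nrow(d))) {
    drop <- FALSE
    for (j in retained) {
      if (chrom[j] != chrom[i]) next
      if (pos[i] - pos[j] > win) next
      r <- suppressWarnings(
        cor(d[i, ], d[j, ], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2) { drop <- TRUE; break }
    }
    if (!drop) { keep[i] <- TRUE; retained <- c(retained, i) }
  }
  keep
}

# greedy AFD water-filling re-derived independently for small toys
oracleGreedyPanel <- function(freq, loci, target) {
  pops <- colnames(freq)
  pairs <- sort(apply(combn(pops, 2), 2, paste, collapse = "|"))
  afd <- sapply(pairs, function(pr) {
    ab <- strsplit(pr, "|", fixed = TRUE)[[1]]
    abs(freq[, ab[1]] - freq[, ab[2]])
  })
  sums <- setNames(rep(0, length(pairs)), pairs)
  taken <- lapply(pairs, function(p) integer())
  names(taken) <- pairs
  union <- integer()
  repeat {
    if (length(union) >= target) break
    pr <- pairs[which.min(sums)]
    avail <- setdiff(order(-afd[, pr], loci$chrom, loci$pos),
                     taken[[pr]])
    if (!length(avail)) break
    locus <- avail[1]
    taken[[pr]] <- c(taken[[pr]], locus)
    sums[pr] <- sums[pr] + afd[locus, pr]^2
    if (!locus %in% union) union <- c(union, locus)
  }
  list(union = union, sums = sums, lists = taken)
}
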