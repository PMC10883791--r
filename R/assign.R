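#' AssignmentCv: Monte-Carlo cross-validated self-assignment
#'
#' @slot trainProp,lociProp the proportions behind each sweep cell.
#' @slot nIter iterations per cell.
#' @slot accuracy iterations x populations matrix of per-iteration
#'   per-population accuracies, averaged over sweep cells.
#' @slot byCell named list (cell label -> iterations x populations
#'   accuracy matrix).
#' @slot confusion true x assigned count matrix accumulated over all
#'   cells and iterations.
#' @aliases AssignmentCv-class
#' @export AssignmentCv
#' @exportClass AssignmentCv
AssignmentCv <- setClass("AssignmentCv", slots = c(
  trainProp = "numeric", lociProp = "numeric", nIter = "integer",
  accuracy = "matrix", byCell = "list", confusion = "matrix"))

setValidity("AssignmentCv", function(object) {
  a <- object@accuracy[!is.na(object@accuracy)]
  if (length(a) && (any(a < 0) || any(a > 1)))
    return("accuracies must lie in [0, 1]")
  TRUE
})

setMethod("show", "AssignmentCv", function(object) {
  cat("AssignmentCv:", object@nIter, "iterations; mean accuracy by",
      "population:\n")
  print(round(colMeans(object@accuracy, na.rm = TRUE), 3))
})

# smoothed training frequencies: +0.5 on each allele count
smoothedFreqs <- function(d, labels) {
  groups <- sort(unique(labels))
  p <- matrix(NA_real_, nrow(d), length(groups),
              dimnames = list(rownames(d), groups))
  for (g in groups) {
    sub <- d[, labels == g, drop = FALSE]
    n <- rowSums(!is.na(sub))
    p[, g] <- (rowSums(sub, na.rm = TRUE) + 0.5) / (2 * n + 1)
  }
  p
}

# HWE genotype log-likelihood of each column of d under each column of p;
# missing genotypes skipped
hweLogLik <- function(d, p) {
  A0 <- (!is.na(d) & d == 0L) * 1
  A1 <- (!is.na(d) & d == 1L) * 1
  A2 <- (!is.na(d) & d == 2L) * 1
  ll <- matrix(0, ncol(d), ncol(p),
               dimnames = list(colnames(d), colnames(p)))
  for (g in colnames(p)) {
    pg <- p[, g]; qg <- 1 - pg
    ll[, g] <- crossprod(A0, 2 * log(qg)) +
      crossprod(A1, log(2 * pg * qg)) +
      crossprod(A2, 2 * log(pg))
  }
  ll
}

#' Monte-Carlo cross-validated self-assignment
#'
#' For each combination of training proportion and locus proportion and
#' each iteration: a stratified random training set is drawn within
#' every population, training allele frequencies are estimated with
#' +0.5-per-allele smoothing, and every held-out individual is assigned
#' to the population maximising its HWE genotype log-likelihood.
#' Accuracies and the confusion matrix are accumulated.
#'
#' @param gm reference `GenotypeExperiment` (>= 2 populations with >= 3
#'   samples each).
#' @param panel optional locus-id subset (e.g. a [PanelSpec-class]
#'   union) applied before the locus subsampling.
#' @param trainProps training-set proportions to sweep.
#' @param lociProps locus proportions to sweep.
#' @param nIter iterations per cell.
#' @param seed RNG seed.
#' @return an [AssignmentCv-class].
#' @export
selfAssignCv <- function(gm, panel = NULL,
                         trainProps = c(0.7, 0.9),
                         lociProps = c(0.5, 1.0),
                         nIter = 100, seed = 1L) {
  if (!is.null(panel)) {
    if (is(panel, "PanelSpec")) panel <- panel@union
    gm <- gm[lociIds(gm) %in% panel, ]
  }
  d <- dosage(gm)
  grp <- as.character(popGroups(gm))
  groups <- sort(unique(grp))
  if (length(groups) < 2 || any(table(grp) < 3))
    stop("need >= 2 populations with >= 3 samples each")
  set.seed(seed)
  confusion <- matrix(0L, length(groups), length(groups),
                      dimnames = list(true = groups, assigned = groups))
  byCell <- list()
  for (tp in trainProps) for (lp in lociProps) {
    acc <- matrix(NA_real_, nIter, length(groups),
                  dimnames = list(NULL, groups))
    for (it in seq_len(nIter)) {
      train <- unlist(lapply(groups, function(g) {
        idx <- which(grp == g)
        nTrain <- max(1L, round(tp * length(idx)))
        if (nTrain >= length(idx)) nTrain <- length(idx) - 1L
        sample(idx, nTrain)
      }))
      if (!length(train)) stop("training set collapsed to 0 samples")
      test <- setdiff(seq_len(ncol(d)), train)
      lsel <- if (lp < 1)
        sample.int(nrow(d), max(1L, round(lp * nrow(d))))
      else seq_len(nrow(d))
      p <- smoothedFreqs(d[lsel, train, drop = FALSE], grp[train])
      ll <- hweLogLik(d[lsel, test, drop = FALSE], p)
      assigned <- groups[max.col(ll, ties.method = "first")]
      for (g in groups) {
        sel <- grp[test] == g
        if (any(sel)) acc[it, g] <- mean(assigned[sel] == g)
      }
      tt <- table(factor(grp[test], groups),
                  factor(assigned, groups))
      confusion <- confusion + matrix(tt, length(groups),
                                      length(groups))
    }
    byCell[[sprintf("train%g_loci%g", tp, lp)]] <- acc
  }
  arr <- array(unlist(byCell), dim = c(nIter, length(groups),
                                       length(byCell)))
  accuracy <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  dimnames(accuracy) <- list(NULL, groups)
  AssignmentCv(trainProp = trainProps, lociProp = lociProps,
               nIter = as.integer(nIter), accuracy = accuracy,
               byCell = byCell, confusion = confusion)
}
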