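#' Per-pair allele frequency differences
#'
#' AFD = |p_a - p_b| on the alternate allele, for every locus and every
#' unordered population pair.
#'
#' @param freqs an [AlleleFreqTable-class].
#' @return loci x pairs matrix; pair columns named `"A|B"` with A < B.
#' @export
afdTable <- function(freqs) {
  pops <- colnames(freqs@freq)
  pairs <- combn(pops, 2)
  out <- apply(pairs, 2, function(pr)
    abs(freqs@freq[, pr[1]] - freqs@freq[, pr[2]]))
  colnames(out) <- apply(pairs, 2, paste, collapse = "|")
  rownames(out) <- rownames(freqs@freq)
  out
}

#' PanelSpec: an AFD-balanced assignment panel
#'
#' @slot targetSize requested union size.
#' @slot pairLists named list of per-pair ordered locus-id vectors.
#' @slot pairSums named numeric of per-pair sums of squared AFD.
#' @slot union deduplicated union locus list, in deterministic order of
#'   first inclusion.
#' @slot frozen pairs that exhausted their loci before the stop.
#' @aliases PanelSpec-class
#' @export PanelSpec
#' @exportClass PanelSpec
PanelSpec <- setClass("PanelSpec", slots = c(
  targetSize = "integer", pairLists = "list", pairSums = "numeric",
  union = "character", frozen = "character"))

setValidity("PanelSpec", function(object) {
  if (length(object@union) > object@targetSize)
    return("union may not exceed the target size")
  if (!all(object@union %in% unlist(object@pairLists)))
    return("every union locus must appear in at least one pair list")
  TRUE
})

setMethod("show", "PanelSpec", function(object) {
  cat(sprintf(
    "PanelSpec: union %d/%d loci over %d pairs; pair sums %.3f-%.3f\n",
    length(object@union), object@targetSize, length(object@pairLists),
    min(object@pairSums), max(object@pairSums)))
})

#' Build an AFD-balanced assignment panel
#'
#' Greedy water-filling: repeatedly pick the population pair whose
#' running sum of squared AFDs is smallest (ties broken by lexicographic
#' pair order) and append that pair's next-highest-AFD locus not yet in
#' its own list (AFD ties broken by chromosome, position); stop when the
#' deduplicated union reaches `targetSize` or loci are exhausted. Pairs
#' that run out of loci are frozen with a warning. The procedure is
#' fully deterministic, and because the smallest sum is always topped
#' up, weakly differentiated pairs end with longer lists.
#'
#' @param freqs an [AlleleFreqTable-class].
#' @param targetSize union panel size (<= available loci).
#' @return a [PanelSpec-class].
#' @export
buildBalancedPanel <- function(freqs, targetSize) {
  afd <- afdTable(freqs)
  afd[is.na(afd)] <- 0   # uncallable cells carry no information
  L <- nrow(afd)
  if (targetSize > L) stop("targetSize exceeds available loci")
  gr <- freqs@loci
  tieOrder <- order(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr))
  pairs <- sort(colnames(afd))
  # per-pair locus ranking: AFD descending, ties by (chrom, pos)
  rank <- lapply(pairs, function(pr) {
    key <- afd[, pr]
    tieOrder[order(-key[tieOrder])]
  })
  names(rank) <- pairs
  ptr <- setNames(rep(1L, length(pairs)), pairs)
  sums <- setNames(rep(0, length(pairs)), pairs)
  lists <- setNames(vector("list", length(pairs)), pairs)
  inUnion <- logical(L)
  unionIdx <- integer()
  frozen <- setNames(rep(FALSE, length(pairs)), pairs)
  ids <- rownames(afd)
  while (length(unionIdx) < targetSize && !all(frozen)) {
    active <- names(which(!frozen))
    pr <- active[which.min(sums[active])]   # ties: lexicographic order
    if (ptr[pr] > L) { frozen[pr] <- TRUE; next }
    locus <- rank[[pr]][ptr[pr]]
    ptr[pr] <- ptr[pr] + 1L
    lists[[pr]] <- c(lists[[pr]], locus)
    sums[pr] <- sums[pr] + afd[locus, pr]^2
    if (!inUnion[locus]) {
      inUnion[locus] <- TRUE
      unionIdx <- c(unionIdx, locus)
    }
    if (ptr[pr] > L) frozen[pr] <- TRUE
  }
  if (any(frozen) && length(unionIdx) < targetSize)
    warning("pair(s) exhausted their loci: ",
            paste(names(which(frozen)), collapse = ", "))
  PanelSpec(targetSize = as.integer(targetSize),
            pairLists = lapply(lists, function(ix) ids[ix]),
            pairSums = sums, union = ids[unionIdx],
            frozen = names(which(frozen)))
}

#' Choose a panel size from cross-validation sweeps
#'
#' Lexicographic criterion over candidate panels: maximise the minimum
#' per-population mean assignment accuracy; break ties by the smaller
#' mean across-iteration standard deviation; then by the smaller panel.
#'
#' @param cvResults named list (names = panel sizes) of
#'   [AssignmentCv-class] objects.
#' @return the chosen size (integer) with attribute `"summary"`.
#' @export
pickPanel <- function(cvResults) {
  sizes <- as.integer(names(cvResults))
  summ <- do.call(rbind, lapply(names(cvResults), function(nm) {
    cv <- cvResults[[nm]]
    accByPop <- colMeans(cv@accuracy)
    sdByPop <- apply(cv@accuracy, 2, sd)
    data.frame(size = as.integer(nm), minAcc = min(accByPop),
               meanSD = mean(sdByPop), stringsAsFactors = FALSE)
  }))
  o <- order(-summ$minAcc, summ$meanSD, summ$size)
  chosen <- summ$size[o[1]]
  attr(chosen, "summary") <- summ
  chosen
}
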