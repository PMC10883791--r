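#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
#' @importMethodsFrom SummarizedExperiment assay "assay<-" assayNames
#'   colData rowRanges
#' @importMethodsFrom S4Vectors metadata "metadata<-"
#' @importMethodsFrom BiocGenerics start
#' @importFrom stats as.dist dist cor cov kmeans lm mahalanobis median pchisq
#'   predict prcomp qchisq quantile rbeta rbinom rgamma rmultinom rnbinom
#'   runif sd setNames smooth.spline var complete.cases chisq.test coef
#'   anova p.adjust
#' @importFrom utils head read.table write.table combn packageVersion
NULL

#' @rdname dosage
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname dosage
#' @export
setGeneric("alleleDepth", function(x) standardGeneric("alleleDepth"))

#' @rdname dosage
#' @export
setGeneric("popGroups", function(x) standardGeneric("popGroups"))

#' @rdname dosage
#' @export
setGeneric("tactics", function(x) standardGeneric("tactics"))

#' @rdname dosage
#' @export
setGeneric("sampleYears", function(x) standardGeneric("sampleYears"))

#' @rdname dosage
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))

#' @rdname filterReport
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))
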