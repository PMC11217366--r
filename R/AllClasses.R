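#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

## Fixed, case-sensitive subtype vocabulary; the first four define the
## LumA-LumB-HER2-E-BL adjacency used by the switching audit, NL is optional.
.SUBTYPES <- c("LumA", "LumB", "HER2-E", "BL", "NL")

.SCALES <- c("counts", "log2cpm", "logfpkm", "log_generic", "centered")

#' Gene-by-sample expression container
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding a single
#' numeric assay (genes in rows, samples in columns) plus a scale tag
#' (\code{"counts"}, \code{"log2cpm"}, \code{"logfpkm"}, \code{"log_generic"}
#' or \code{"centered"}) recording what the values mean. Sample annotations
#' (cohort, ER+/HER2- subgroup membership, and for synthetic data the true
#' subtype) live in \code{colData}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; the scale tag is stored in
#'   \code{metadata(x)$scale}.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(SummarizedExperiment::assays(object)) != 1L)
    msg <- c(msg, "exactly one assay expected")
  v <- SummarizedExperiment::assay(object)
  if (!is.numeric(v)) msg <- c(msg, "assay must be numeric")
  g <- rownames(object); s <- colnames(object)
  if (is.null(g) || anyDuplicated(g))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(s) || anyDuplicated(s))
    msg <- c(msg, "sample ids must be present and unique")
  sc <- metadata(object)$scale
  if (is.null(sc) || length(sc) != 1L || !sc %in% .SCALES)
    msg <- c(msg, sprintf("scale tag must be one of: %s",
                          paste(.SCALES, collapse = ", ")))
  else {
    if (any(!is.finite(v))) msg <- c(msg, "all expression values must be finite")
    if (identical(sc, "counts") && any(v < 0))
      msg <- c(msg, "scale 'counts' requires non-negative values")
  }
  if (length(msg)) msg else TRUE
})

#' Subtype centroid profiles
#'
#' Prototype (centroid) expression profiles, one column per intrinsic
#' subtype, together with the correlation method they were trained for.
#'
#' @slot values numeric matrix, genes x subtypes.
#' @slot method \code{"spearman"} or \code{"pearson"}.
#' @export
setClass("CentroidSet",
  representation(values = "matrix", method = "character"))

setValidity("CentroidSet", function(object) {
  msg <- character()
  v <- object@values
  labs <- colnames(v)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "centroid gene ids must be present and unique")
  if (is.null(labs) || anyDuplicated(labs))
    msg <- c(msg, "subtype labels must be present and distinct")
  else {
    if (!length(labs) %in% 4:5)
      msg <- c(msg, "4 or 5 subtype labels expected")
    bad <- setdiff(labs, .SUBTYPES)
    if (length(bad))
      msg <- c(msg, sprintf("unknown subtype label(s): %s",
                            paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(v))) msg <- c(msg, "centroid values must be finite")
  if (!identical(length(object@method), 1L) ||
      !object@method %in% c("spearman", "pearson"))
    msg <- c(msg, "method must be 'spearman' or 'pearson'")
  if (length(msg)) msg else TRUE
})

#' Per-sample subtype calls with score profiles
#'
#' One row per sample: the call, the full score vector against every class
#' (centroid correlations for nearest-centroid classifiers, normalized
#' posteriors for the rule-based classifier), the top-two margin
#' delta = score(1) - score(2), a tie flag and a switched flag (set by the
#' second-centroid switching experiment, in which case the call is the
#' second-best class).
#'
#' @slot scores numeric matrix, samples x classes.
#' @slot scoreType \code{"correlation"} or \code{"posterior"}.
#' @export
setClass("SubtypeCalls",
  representation(sampleIds = "character", call = "character",
                 scores = "matrix", scoreType = "character",
                 margin = "numeric", tie = "logical", switched = "logical",
                 metadata = "list"))

setValidity("SubtypeCalls", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicate sample ids")
  if (length(object@call) != n || nrow(object@scores) != n ||
      length(object@margin) != n || length(object@tie) != n ||
      length(object@switched) != n)
    msg <- c(msg, "all per-sample slots must have one entry per sample")
  if (is.null(colnames(object@scores)))
    msg <- c(msg, "score matrix must have class labels as colnames")
  if (!object@scoreType %in% c("correlation", "posterior"))
    msg <- c(msg, "scoreType must be 'correlation' or 'posterior'")
  if (any(object@margin < -1e-12)) msg <- c(msg, "margins must be >= 0")
  if (identical(object@scoreType, "correlation") &&
      any(abs(object@scores) > 1 + 1e-9))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (n && !length(msg)) {
    best <- object@scores[cbind(seq_len(n), match(object@call, colnames(object@scores)))]
    ok <- object@switched | (abs(best - apply(object@scores, 1L, max)) <= 1e-9)
    if (any(!ok))
      msg <- c(msg, "call must be a maximal-score class unless switched")
  }
  if (length(msg)) msg else TRUE
})

#' Subgroup-specific percentile centering reference
#'
#' Per-gene summary of an external reference cohort: the full-cohort
#' (global) median, the median of its ER+/HER2--like subgroup, and the
#' percentile of the subgroup's empirical distribution at which the global
#' median sits (the quantity sgPct centering transfers to a new cohort).
#'
#' @export
setClass("NormalizationReference",
  representation(geneIds = "character", globalMedian = "numeric",
                 subgroupMedian = "numeric", percentile = "numeric",
                 source = "character"))

setValidity("NormalizationReference", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicate gene ids")
  if (length(object@globalMedian) != n || length(object@subgroupMedian) != n ||
      length(object@percentile) != n)
    msg <- c(msg, "per-gene slots must match gene ids in length")
  if (any(!is.finite(object@percentile)) ||
      any(object@percentile < 0) || any(object@percentile > 100))
    msg <- c(msg, "percentiles must lie in [0, 100]")
  if (any(!is.finite(object@globalMedian)) || any(!is.finite(object@subgroupMedian)))
    msg <- c(msg, "medians must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-gene affine technical calibration factors
#'
#' Cross-platform correction on the log scale: calibrated = scale * x + shift,
#' gene by gene (e.g. mapping RNA-seq log expression onto the microarray
#' scale a centroid set was trained on).
#'
#' @export
setClass("CalibrationFactors",
  representation(geneIds = "character", scale = "numeric", shift = "numeric"))

setValidity("CalibrationFactors", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicate gene ids")
  if (length(object@scale) != n || length(object@shift) != n)
    msg <- c(msg, "scale/shift must match gene ids in length")
  if (any(!is.finite(object@scale)) || any(!is.finite(object@shift)))
    msg <- c(msg, "factors must be finite")
  if (any(object@scale <= 0)) msg <- c(msg, "scale factors must be positive")
  if (length(msg)) msg else TRUE
})

#' Binary gene-pair rule set with naive-Bayes parameters
#'
#' Ordered rules (gene_low, gene_high), each true within a sample iff
#' expression(gene_low) < expression(gene_high); per-rule per-class
#' conditional probabilities that the rule is true, and class priors.
#'
#' @slot condProb numeric matrix, rules x classes, entries strictly in (0,1).
#' @export
setClass("RuleSet",
  representation(geneLow = "character", geneHigh = "character",
                 condProb = "matrix", priors = "numeric"))

setValidity("RuleSet", function(object) {
  msg <- character()
  r <- length(object@geneLow)
  if (length(object@geneHigh) != r || nrow(object@condProb) != r)
    msg <- c(msg, "rule slots must agree in length")
  if (any(object@geneLow == object@geneHigh))
    msg <- c(msg, "gene_low must differ from gene_high within a rule")
  if (is.null(colnames(object@condProb)))
    msg <- c(msg, "condProb must have class labels as colnames")
  if (any(object@condProb <= 0) || any(object@condProb >= 1))
    msg <- c(msg, "conditional probabilities must lie strictly in (0, 1)")
  pr <- object@priors
  if (!identical(sort(names(pr)), sort(colnames(object@condProb))))
    msg <- c(msg, "priors must be named by the condProb classes")
  if (any(pr <= 0) || any(pr >= 1) || abs(sum(pr) - 1) > 1e-9)
    msg <- c(msg, "priors must lie in (0,1) and sum to 1 within 1e-9")
  if (length(msg)) msg else TRUE
})

#' Cross-method contingency table
#'
#' Integer counts of samples by (method A label, method B label); rows are
#' method A, columns method B.
#'
#' @export
setClass("ContingencyTable",
  representation(counts = "matrix", methodA = "character", methodB = "character"))

setValidity("ContingencyTable", function(object) {
  msg <- character()
  cnt <- object@counts
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    msg <- c(msg, "counts must carry row/column labels")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Concordance report between two subtyping methods
#'
#' Bundles the contingency table, overall agreement, Cohen's kappa (after an
#' optional label merge such as NL -> LumA), axis-conditional misassignment
#' rates, per-method subtype distributions and the clear-defined/discord
#' sample partition.
#'
#' @export
setClass("ConcordanceReport",
  representation(table = "ContingencyTable", mergeMap = "character",
                 agreement = "list", kappa = "list",
                 conditionalRates = "list", distributions = "list",
                 clearDefined = "character", discord = "character"))

setValidity("ConcordanceReport", function(object) {
  n <- sum(object@table@counts)
  if (length(object@clearDefined) + length(object@discord) != n)
    "clear-defined and discord samples must partition the cohort" else TRUE
})
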