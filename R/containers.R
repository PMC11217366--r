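#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param scale what the values are: \code{"counts"}, \code{"log2cpm"},
#'   \code{"logfpkm"}, \code{"log_generic"} or \code{"centered"}.
#' @param annotation optional \code{data.frame} with a \code{sample_id} column
#'   and any of \code{cohort}, \code{in_subgroup}, \code{true_subtype}; rows
#'   are matched to samples by id.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' x <- ExpressionMatrix(m, scale = "log_generic")
#' exprScale(x)
#' @export
ExpressionMatrix <- function(values,
                             scale = c("counts", "log2cpm", "logfpkm",
                                       "log_generic", "centered"),
                             annotation = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(annotation)) {
    if (!"sample_id" %in% colnames(annotation))
      stop("annotation must have a 'sample_id' column")
    if (anyDuplicated(annotation$sample_id))
      stop("duplicate sample_id in annotation")
    idx <- match(colnames(values), annotation$sample_id)
    if (anyNA(idx))
      stop("annotation missing sample(s): ",
           paste(colnames(values)[is.na(idx)], collapse = ", "))
    ann <- annotation[idx, setdiff(colnames(annotation), "sample_id"),
                      drop = FALSE]
    cd <- S4Vectors::DataFrame(ann, row.names = colnames(values))
  }
  se <- SummarizedExperiment(assays = list(expr = values), colData = cd)
  metadata(se)$scale <- scale
  new("ExpressionMatrix", se)
}

#' @rdname ExpressionMatrix
#' @param x an object.
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "expr"))

#' @rdname ExpressionMatrix
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) metadata(x)$scale)

#' @rdname ExpressionMatrix
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname ExpressionMatrix
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname ExpressionMatrix
#' @export
setMethod("geneIds", "CentroidSet", function(x) rownames(x@values))

#' @rdname ExpressionMatrix
#' @export
setMethod("geneIds", "NormalizationReference", function(x) x@geneIds)

#' @rdname ExpressionMatrix
#' @export
setMethod("geneIds", "CalibrationFactors", function(x) x@geneIds)

## Replace the assay while keeping sample annotations; retag the scale.
.replaceValues <- function(x, values, scale) {
  se <- SummarizedExperiment(assays = list(expr = values), colData = colData(x))
  metadata(se)$scale <- scale
  new("ExpressionMatrix", se)
}

#' Sample annotations of an ExpressionMatrix as a data.frame
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return \code{data.frame} with \code{sample_id} plus any annotation columns.
#' @export
sampleAnnotation <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  cbind(data.frame(sample_id = colnames(x), stringsAsFactors = FALSE),
        as.data.frame(colData(x)))
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(object), ncol(object), exprScale(object)))
  if (ncol(colData(object)))
    cat("  annotations:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

#' Construct a CentroidSet
#'
#' @param values numeric matrix, genes x subtypes; colnames must be drawn from
#'   \code{LumA, LumB, HER2-E, BL, NL} (4 or 5 of them, NL optional).
#' @param method correlation method the centroids were trained for.
#' @return A \linkS4class{CentroidSet}.
#' @export
CentroidSet <- function(values, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("CentroidSet", values = values, method = method)
}

#' @rdname CentroidSet
#' @param x a \code{CentroidSet}.
#' @export
setMethod("subtypeLabels", "CentroidSet", function(x) colnames(x@values))

#' @rdname CentroidSet
#' @export
centroidValues <- function(x) {
  stopifnot(is(x, "CentroidSet"))
  x@values
}

#' @rdname CentroidSet
#' @export
centroidMethod <- function(x) {
  stopifnot(is(x, "CentroidSet"))
  x@method
}

setMethod("show", "CentroidSet", function(object) {
  cat(sprintf("CentroidSet: %d genes, subtypes %s [%s]\n",
              nrow(object@values),
              paste(colnames(object@values), collapse = ", "),
              object@method))
})

#' Construct a SubtypeCalls object
#'
#' Usually produced by \code{\link{classify}} or \code{\link{nbClassify}};
#' the constructor is exported for round-tripping through files.
#'
#' @param sampleIds character vector of unique sample ids.
#' @param call subtype call per sample.
#' @param scores samples x classes score matrix (correlations or posteriors).
#' @param scoreType \code{"correlation"} or \code{"posterior"}.
#' @param margin top-two score gap per sample; computed from \code{scores}
#'   when \code{NULL}.
#' @param tie,switched logical flags per sample.
#' @param metadata free-form list (e.g. switch-experiment summary).
#' @return A \linkS4class{SubtypeCalls}.
#' @export
SubtypeCalls <- function(sampleIds, call, scores,
                         scoreType = c("correlation", "posterior"),
                         margin = NULL, tie = NULL, switched = NULL,
                         metadata = list()) {
  scoreType <- match.arg(scoreType)
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  rownames(scores) <- sampleIds
  if (is.null(margin)) {
    srt <- apply(scores, 1L, function(r) sort(r, decreasing = TRUE)[1:2])
    margin <- srt[1L, ] - srt[2L, ]
  }
  if (is.null(tie)) tie <- margin <= 1e-12
  if (is.null(switched)) switched <- rep(FALSE, length(sampleIds))
  new("SubtypeCalls", sampleIds = as.character(sampleIds),
      call = as.character(call), scores = scores, scoreType = scoreType,
      margin = as.numeric(margin), tie = as.logical(tie),
      switched = as.logical(switched), metadata = metadata)
}

#' @rdname SubtypeCalls
#' @param x a \code{SubtypeCalls} object.
#' @export
setMethod("calls", "SubtypeCalls", function(x) {
  stats::setNames(x@call, x@sampleIds)
})

#' @rdname SubtypeCalls
#' @export
setMethod("scores", "SubtypeCalls", function(x) x@scores)

#' @rdname SubtypeCalls
#' @export
setMethod("margins", "SubtypeCalls", function(x) {
  stats::setNames(x@margin, x@sampleIds)
})

#' @rdname SubtypeCalls
#' @export
setMethod("tieFlags", "SubtypeCalls", function(x) {
  stats::setNames(x@tie, x@sampleIds)
})

#' @rdname SubtypeCalls
#' @export
setMethod("switchedFlags", "SubtypeCalls", function(x) {
  stats::setNames(x@switched, x@sampleIds)
})

#' @rdname SubtypeCalls
#' @export
setMethod("sampleIds", "SubtypeCalls", function(x) x@sampleIds)

#' Coerce SubtypeCalls to the flat calls table
#'
#' @param x a \linkS4class{SubtypeCalls}.
#' @param ... unused.
#' @return \code{data.frame} with \code{sample_id}, \code{call}, one
#'   \code{rho_<class>} column per class, \code{margin}, \code{tie},
#'   \code{switched}.
#' @export
as.data.frame.SubtypeCalls <- function(x, ...) {
  sc <- x@scores
  colnames(sc) <- paste0("rho_", colnames(sc))
  data.frame(sample_id = x@sampleIds, call = x@call, sc,
             margin = x@margin, tie = x@tie, switched = x@switched,
             row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

setMethod("show", "SubtypeCalls", function(object) {
  cat(sprintf("SubtypeCalls: %d samples, classes %s [%s scores]\n",
              length(object@sampleIds),
              paste(colnames(object@scores), collapse = ", "),
              object@scoreType))
  tab <- table(factor(object@call, levels = colnames(object@scores)))
  cat("  calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (any(object@switched))
    cat(sprintf("  switched: %d\n", sum(object@switched)))
})

#' @rdname NormalizationReference-class
#' @param geneIds,globalMedian,subgroupMedian,percentile,source slots; see
#'   class description.
#' @export
NormalizationReference <- function(geneIds, globalMedian, subgroupMedian,
                                   percentile, source = "unspecified") {
  new("NormalizationReference", geneIds = as.character(geneIds),
      globalMedian = as.numeric(globalMedian),
      subgroupMedian = as.numeric(subgroupMedian),
      percentile = as.numeric(percentile), source = source)
}

setMethod("show", "NormalizationReference", function(object) {
  cat(sprintf("NormalizationReference: %d genes (source: %s)\n",
              length(object@geneIds), object@source))
})

#' @rdname CalibrationFactors-class
#' @param geneIds,scale,shift per-gene factors: calibrated = scale * x + shift.
#' @export
CalibrationFactors <- function(geneIds, scale, shift) {
  new("CalibrationFactors", geneIds = as.character(geneIds),
      scale = as.numeric(scale), shift = as.numeric(shift))
}

setMethod("show", "CalibrationFactors", function(object) {
  cat(sprintf("CalibrationFactors: %d genes\n", length(object@geneIds)))
})

#' Construct a RuleSet
#'
#' @param geneLow,geneHigh gene ids; rule r is true within a sample iff
#'   expression(geneLow[r]) < expression(geneHigh[r]) (strict; equality is
#'   false).
#' @param condProb rules x classes matrix of P(rule true | class), strictly
#'   inside (0,1) (use smoothing when estimating).
#' @param priors named class priors summing to 1.
#' @return A \linkS4class{RuleSet}.
#' @export
RuleSet <- function(geneLow, geneHigh, condProb, priors) {
  condProb <- as.matrix(condProb)
  storage.mode(condProb) <- "double"
  new("RuleSet", geneLow = as.character(geneLow),
      geneHigh = as.character(geneHigh), condProb = condProb,
      priors = priors)
}

#' Number of rules in a RuleSet
#' @param x a \linkS4class{RuleSet}.
#' @export
nRules <- function(x) {
  stopifnot(is(x, "RuleSet"))
  length(x@geneLow)
}

#' Genes referenced by a RuleSet
#' @param x a \linkS4class{RuleSet}.
#' @export
ruleGenes <- function(x) {
  stopifnot(is(x, "RuleSet"))
  unique(c(x@geneLow, x@geneHigh))
}

setMethod("show", "RuleSet", function(object) {
  cat(sprintf("RuleSet: %d rules over %d genes, classes %s\n",
              length(object@geneLow), length(ruleGenes(object)),
              paste(colnames(object@condProb), collapse = ", ")))
})

#' Construct a ContingencyTable
#'
#' @param counts integer matrix of cross-method counts; rows = method A,
#'   columns = method B, with subtype labels as dimnames.
#' @param methodA,methodB display names for the two methods.
#' @return A \linkS4class{ContingencyTable}.
#' @export
ContingencyTable <- function(counts, methodA = "method_a", methodB = "method_b") {
  counts <- as.matrix(counts)
  new("ContingencyTable", counts = counts, methodA = methodA, methodB = methodB)
}

#' @rdname ContingencyTable
#' @param x a \code{ContingencyTable}.
#' @export
setMethod("tableCounts", "ContingencyTable", function(x) x@counts)

#' Total sample count of a ContingencyTable
#' @param x a \linkS4class{ContingencyTable}.
#' @export
tableN <- function(x) {
  stopifnot(is(x, "ContingencyTable"))
  sum(x@counts)
}

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable: %s (rows) vs %s (columns), n = %d\n",
              object@methodA, object@methodB, sum(object@counts)))
  print(object@counts)
})

setMethod("show", "ConcordanceReport", function(object) {
  cat(sprintf("ConcordanceReport: %s vs %s, n = %d\n",
              object@table@methodA, object@table@methodB,
              sum(object@table@counts)))
  cat(sprintf("  agreement: %d/%d = %s%%\n", object@agreement$numerator,
              object@agreement$denominator, object@agreement$percent))
  cat(sprintf("  kappa%s: %.2f\n",
              if (length(object@mergeMap))
                sprintf(" (merge %s)", paste(names(object@mergeMap),
                                             object@mergeMap, sep = "->",
                                             collapse = ", ")) else "",
              object@kappa$kappa))
  cat(sprintf("  clear-defined: %d, discord: %d\n",
              length(object@clearDefined), length(object@discord)))
})
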