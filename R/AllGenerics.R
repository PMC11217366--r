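#' @rdname ExpressionMatrix
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname ExpressionMatrix
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SubtypeCalls
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname SubtypeCalls
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname SubtypeCalls
#' @export
setGeneric("margins", function(x) standardGeneric("margins"))

#' @rdname SubtypeCalls
#' @export
setGeneric("tieFlags", function(x) standardGeneric("tieFlags"))

#' @rdname SubtypeCalls
#' @export
setGeneric("switchedFlags", function(x) standardGeneric("switchedFlags"))

#' @rdname CentroidSet
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' @rdname ContingencyTable
#' @export
setGeneric("tableCounts", function(x) standardGeneric("tableCounts"))
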