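#' Accessors
#'
#' `exprs()` returns the log2 expression matrix of a cohort;
#' `clinicalData()` its clinical table (with `sample_id` restored as a
#' column); `riskScores()`, `subtypeCalls()` and
#' `centroidCorrelationMatrices()` read the components of a
#' [ScoreTable-class]; `scoreStatus()` the per-signature scoring status.
#'
#' @param object a [SignatureCohort-class] or [ScoreTable-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' @rdname accessors
#' @export
setMethod("exprs", "SignatureCohort", function(object)
  SummarizedExperiment::assay(object, "exprs"))

#' @rdname accessors
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))

#' @rdname accessors
#' @export
setMethod("clinicalData", "SignatureCohort", function(object) {
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  cbind(sample_id = colnames(object), cd, row.names = NULL,
        stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("riskScores", function(object) standardGeneric("riskScores"))

#' @rdname accessors
#' @export
setMethod("riskScores", "ScoreTable", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("subtypeCalls", function(object) standardGeneric("subtypeCalls"))

#' @rdname accessors
#' @export
setMethod("subtypeCalls", "ScoreTable", function(object) object@calls)

#' @rdname accessors
#' @export
setGeneric("centroidCorrelationMatrices",
           function(object) standardGeneric("centroidCorrelationMatrices"))

#' @rdname accessors
#' @export
setMethod("centroidCorrelationMatrices", "ScoreTable",
          function(object) object@correlations)

#' @rdname accessors
#' @export
setGeneric("scoreStatus", function(object) standardGeneric("scoreStatus"))

#' @rdname accessors
#' @export
setMethod("scoreStatus", "ScoreTable", function(object) object@status)
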