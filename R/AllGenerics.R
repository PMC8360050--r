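#' @rdname CountMatrix
#' @param x a `CountMatrix` (or other object, see methods).
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname CountMatrix
#' @export
setGeneric("taxonPrevalence", function(x) standardGeneric("taxonPrevalence"))

#' @rdname CountMatrix
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))

#' @rdname zeroFraction
#' @export
setGeneric("zeroFraction", function(x) standardGeneric("zeroFraction"))

#' @rdname prevalenceFilter
#' @export
setGeneric("prevalenceFilter",
    function(x, minPrevalence = 5L, minMeanAbundance = 0)
        standardGeneric("prevalenceFilter"))

#' @rdname CenteredLogMatrix
#' @param x a `CenteredLogMatrix`.
#' @export
setGeneric("centeredMatrix", function(x) standardGeneric("centeredMatrix"))

#' @rdname CenteredLogMatrix
#' @export
setGeneric("logRowMeans", function(x) standardGeneric("logRowMeans"))

#' @rdname CenteredLogMatrix
#' @export
setGeneric("logColMeans", function(x) standardGeneric("logColMeans"))

#' @rdname CenteredLogMatrix
#' @export
setGeneric("grandMean", function(x) standardGeneric("grandMean"))

#' @rdname OrdinationResult
#' @param x an `OrdinationResult`.
#' @export
setGeneric("sampleScores", function(x) standardGeneric("sampleScores"))

#' @rdname OrdinationResult
#' @export
setGeneric("taxonLoadings", function(x) standardGeneric("taxonLoadings"))

#' @rdname OrdinationResult
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname OrdinationResult
#' @export
setGeneric("explainedFraction", function(x) standardGeneric("explainedFraction"))

#' @rdname RdaTestResult
#' @param x an `RdaTestResult`.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname RdaTestResult
#' @export
setGeneric("constrainedFraction", function(x) standardGeneric("constrainedFraction"))

#' @rdname RdaTestResult
#' @export
setGeneric("permStats", function(x) standardGeneric("permStats"))
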