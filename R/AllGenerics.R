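#' @rdname asScore
#' @export
setGeneric("asScore", function(x, ...) standardGeneric("asScore"))

#' @rdname acsScore
#' @export
setGeneric("acsScore", function(x, category = NULL, ...)
  standardGeneric("acsScore"))

#' @rdname summarizeGroups
#' @export
setGeneric("summarizeGroups", function(x, ...)
  standardGeneric("summarizeGroups"))

#' @rdname orderCases
#' @export
setGeneric("orderCases", function(x, ...) standardGeneric("orderCases"))

#' @rdname deriveFindingsFlags
#' @export
setGeneric("deriveFindingsFlags", function(x, ...)
  standardGeneric("deriveFindingsFlags"))

#' Accessor: case-level metadata table
#' @param x a \linkS4class{CapillaryCohort}.
#' @return data.frame of case metadata.
#' @export
setGeneric("caseData", function(x) standardGeneric("caseData"))

#' Accessor: per-capillary score table
#' @param x a \linkS4class{CapillaryCohort}.
#' @return data.frame of per-capillary category scores.
#' @export
setGeneric("capillaryScores", function(x) standardGeneric("capillaryScores"))
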