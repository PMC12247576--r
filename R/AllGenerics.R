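#' @rdname poolEstimates
#' @export
setGeneric("poolEstimates", function(x, scheme, ...)
  standardGeneric("poolEstimates"))

#' @rdname schemeErrors
#' @export
setGeneric("schemeErrors", function(x, scheme, ...)
  standardGeneric("schemeErrors"))

#' @rdname simulateStudy
#' @export
setGeneric("simulateStudy", function(model, design, seed = NULL, ...)
  standardGeneric("simulateStudy"))

#' @rdname impliedRho
#' @export
setGeneric("impliedRho", function(model, sameBlock = TRUE)
  standardGeneric("impliedRho"))

#' @rdname estimateRho
#' @export
setGeneric("estimateRho", function(x, ...) standardGeneric("estimateRho"))

#' @rdname longTable
#' @export
setGeneric("longTable", function(x, ...) standardGeneric("longTable"))

#' @rdname measureKeys
#' @export
setGeneric("measureKeys", function(x) standardGeneric("measureKeys"))

#' @rdname scanInfo
#' @export
setGeneric("scanInfo", function(x) standardGeneric("scanInfo"))

#' @rdname schemeDuration
#' @export
setGeneric("schemeDuration", function(scheme, ...)
  standardGeneric("schemeDuration"))
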