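#' @rdname gridSpec
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname rasterValues
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname layerNames
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname getLayer
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' Extent of a gridded or polygonal object
#'
#' @param x a GridSpec, RasterLayer, CovariateStack or AdminUnits object.
#' @return named numeric (xmin, xmax, ymin, ymax) in km.
#' @export
setGeneric("extentOf", function(x) standardGeneric("extentOf"))

#' @rdname asfr
#' @export
setGeneric("asfr", function(x) standardGeneric("asfr"))

#' @rdname tfr
#' @export
setGeneric("tfr", function(x) standardGeneric("tfr"))

#' @rdname posteriorSummary
#' @export
setGeneric("posteriorSummary", function(x, ...) standardGeneric("posteriorSummary"))
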