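#' @rdname DailySeries-accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname DailySeries-accessors
#' @export
setGeneric("seriesDates", function(x) standardGeneric("seriesDates"))

#' @rdname DailySeries-accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname DailySeries-accessors
#' @export
setGeneric("seriesMask", function(x) standardGeneric("seriesMask"))

#' @rdname DailySeries-accessors
#' @export
setGeneric("longitude", function(x) standardGeneric("longitude"))

#' @rdname DailySeries-accessors
#' @export
setGeneric("latitude", function(x) standardGeneric("latitude"))

#' @rdname slicePeriod
#' @export
setGeneric("slicePeriod", function(x, period) standardGeneric("slicePeriod"))

#' @rdname seasonalSubset
#' @export
setGeneric("seasonalSubset",
  function(x, season, spec = seasonMap()) standardGeneric("seasonalSubset"))

#' @rdname meanSST
#' @export
setGeneric("meanSST", function(x, ...) standardGeneric("meanSST"))
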