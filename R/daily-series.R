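#' Construct a DailySeries
#'
#' @param values numeric SST in degrees C; `NA` marks masked days.
#' @param dates `Date` vector (or coercible), strictly increasing.
#' @param siteId site identifier; defaults to `"lon_lat"`.
#' @param lon,lat cell-centre coordinates in decimal degrees.
#' @return a [DailySeries-class] object.
#' @examples
#' d <- DailySeries(rnorm(10, 15), seq(as.Date("2000-01-01"), by = 1,
#'                  length.out = 10), lon = -8, lat = 43.5)
#' meanSST(d)
#' @export
DailySeries <- function(values, dates, siteId = NULL, lon = NA_real_,
                        lat = NA_real_) {
  dates <- as.Date(dates)
  if (is.null(siteId)) siteId <- sprintf("%g_%g", lon, lat)
  new("DailySeries", siteId = as.character(siteId), lon = as.numeric(lon),
      lat = as.numeric(lat), dates = dates, values = as.numeric(values))
}

#' Accessors for DailySeries
#'
#' @param x a [DailySeries-class].
#' @name DailySeries-accessors
NULL

#' @rdname DailySeries-accessors
#' @export
setMethod("siteId", "DailySeries", function(x) x@siteId)

#' @rdname DailySeries-accessors
#' @export
setMethod("seriesDates", "DailySeries", function(x) x@dates)

#' @rdname DailySeries-accessors
#' @export
setMethod("seriesValues", "DailySeries", function(x) x@values)

#' @rdname DailySeries-accessors
#' @export
setMethod("seriesMask", "DailySeries", function(x) is.na(x@values))

#' @rdname DailySeries-accessors
#' @export
setMethod("longitude", "DailySeries", function(x) x@lon)

#' @rdname DailySeries-accessors
#' @export
setMethod("latitude", "DailySeries", function(x) x@lat)

#' @describeIn DailySeries-class number of days
#' @export
setMethod("length", "DailySeries", function(x) length(x@values))

#' @describeIn DailySeries-class compact display
#' @param object a `DailySeries`
#' @export
setMethod("show", "DailySeries", function(object) {
  n <- length(object)
  cat(sprintf("DailySeries '%s' (%.3f, %.3f): %d days %s..%s, %d masked\n",
              object@siteId, object@lon, object@lat, n,
              if (n) format(min(object@dates)) else "-",
              if (n) format(max(object@dates)) else "-",
              sum(is.na(object@values))))
})

#' Is a series contiguous at daily step?
#'
#' @param x a [DailySeries-class].
#' @return logical scalar.
#' @export
isContiguous <- function(x) {
  d <- as.integer(seriesDates(x))
  length(d) <= 1L || all(diff(d) == 1L)
}

#' Restrict a daily series to an analysis period
#'
#' @param x a [DailySeries-class].
#' @param period a [PeriodSpec-class].
#' @return the sub-series falling inside the period (site metadata kept).
#' @export
setMethod("slicePeriod", "DailySeries", function(x, period) {
  keep <- x@dates >= period@start & x@dates <= period@end
  if (!any(keep)) stop("period slice is empty for site ", x@siteId)
  DailySeries(x@values[keep], x@dates[keep], x@siteId, x@lon, x@lat)
})

#' Seasonal subset of a daily series
#'
#' Keeps the days whose calendar month maps to the requested season. The
#' result is legitimately non-contiguous (e.g. all summers of a period).
#'
#' @param x a [DailySeries-class].
#' @param season one of `"winter"`, `"spring"`, `"summer"`, `"autumn"`.
#' @param spec season map as returned by [seasonMap()].
#' @return a [DailySeries-class].
#' @export
setMethod("seasonalSubset", "DailySeries", function(x, season,
                                                    spec = seasonMap()) {
  if (!season %in% unique(spec)) stop("unknown season label: ", season)
  m <- as.integer(format(x@dates, "%m"))
  keep <- seasonOf(m, spec) == season
  DailySeries(x@values[keep], x@dates[keep], x@siteId, x@lon, x@lat)
})

#' Mean SST of a series
#'
#' Arithmetic mean over unmasked days.
#'
#' @param x a [DailySeries-class].
#' @param ... unused.
#' @return numeric scalar, degrees C.
#' @export
setMethod("meanSST", "DailySeries", function(x, ...) {
  v <- x@values[!is.na(x@values)]
  if (length(v) == 0L) stop("mean of an all-masked series is undefined")
  mean(v)
})
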