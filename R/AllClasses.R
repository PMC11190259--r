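#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var sd cor quantile approx fft glm.fit binomial gaussian
#'   pt rnorm runif rbinom plogis lm lm.fit coef resid hclust dist as.dist
#'   cophenetic wilcox.test complete.cases setNames median
#' @importFrom utils head tail read.csv write.csv
NULL

#' DailySeries: one grid cell's daily SST record
#'
#' Container for a single site's daily sea-surface-temperature series with
#' calendar metadata. Missing days are encoded as `NA` in `values`; the mask
#' accessor derives from them. Dates must be strictly increasing; most metrics
#' additionally require a contiguous daily span (see [isContiguous()]), but
#' seasonal subsets are legitimately non-contiguous.
#'
#' @slot siteId character scalar, conventionally `"lon_lat"`.
#' @slot lon,lat numeric scalars, decimal degrees (lon in \[-180, 180)).
#' @slot dates `Date` vector, strictly increasing.
#' @slot values numeric vector of SST in degrees C, same length as `dates`;
#'   `NA` marks masked days.
#'
#' @export
setClass("DailySeries",
  representation(
    siteId = "character",
    lon = "numeric",
    lat = "numeric",
    dates = "Date",
    values = "numeric"
  )
)

setValidity("DailySeries", function(object) {
  msg <- NULL
  if (length(object@siteId) != 1L) msg <- c(msg, "siteId must be a scalar")
  if (length(object@dates) != length(object@values))
    msg <- c(msg, "dates and values must have equal length")
  if (length(object@dates) > 1L && any(diff(as.integer(object@dates)) <= 0L))
    msg <- c(msg, "dates must be strictly increasing")
  v <- object@values
  if (any(!is.na(v) & !is.finite(v)))
    msg <- c(msg, "unmasked values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' PeriodSpec: a named analysis window
#'
#' @slot name character, e.g. `"baseline"` or `"resurvey"`.
#' @slot start,end `Date` scalars, inclusive.
#' @export
setClass("PeriodSpec",
  representation(name = "character", start = "Date", end = "Date")
)

setValidity("PeriodSpec", function(object) {
  if (object@end < object@start) "end must be >= start" else TRUE
})

#' Climatology: day-of-year baseline mean and percentile thresholds
#'
#' Per day-of-year (1..366, Feb 29 = 60) climatological mean, upper (90th
#' percentile) and lower (10th percentile) threshold curves, pooled over a
#' fixed multi-year baseline within an 11-day window and smoothed by a 31-day
#' circular moving average.
#'
#' @slot doy integer 1:366.
#' @slot mean,upper,lower numeric length-366 curves, degrees C.
#' @slot windowHalfwidth,smooth integers: pooling half-window and smoothing
#'   width in days.
#' @slot span `Date` length-2: first and last day of the climatology period.
#' @slot unstable logical: `TRUE` when built from fewer than 10 years.
#' @export
setClass("Climatology",
  representation(
    doy = "integer",
    mean = "numeric",
    upper = "numeric",
    lower = "numeric",
    windowHalfwidth = "integer",
    smooth = "integer",
    span = "Date",
    unstable = "logical"
  )
)

setValidity("Climatology", function(object) {
  msg <- NULL
  if (length(object@doy) != 366L) msg <- c(msg, "doy grid must have 366 entries")
  for (s in c("mean", "upper", "lower"))
    if (length(slot(object, s)) != 366L)
      msg <- c(msg, sprintf("%s curve must have 366 entries", s))
  ok <- is.finite(object@lower) & is.finite(object@mean) & is.finite(object@upper)
  if (any(object@lower[ok] > object@mean[ok] + 1e-9) ||
      any(object@mean[ok] > object@upper[ok] + 1e-9))
    msg <- c(msg, "curves must satisfy lower <= mean <= upper")
  if (is.null(msg)) TRUE else msg
})

#' SSTGrid: gridded daily SST as a SummarizedExperiment
#'
#' Rows are sites (rowData: `site_id`, `lon`, `lat`), columns are consecutive
#' calendar days (colData: `date`), and the single assay `sst` holds daily SST
#' in degrees C with `NA` for masked cells.
#'
#' @export
setClass("SSTGrid", contains = "SummarizedExperiment")

setValidity("SSTGrid", function(object) {
  msg <- NULL
  if (!"sst" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'sst' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("site_id", "lon", "lat") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain site_id, lon, lat")
  cd <- SummarizedExperiment::colData(object)
  if (!"date" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain date")
  } else {
    d <- as.Date(cd$date)
    if (length(d) > 1L && any(diff(as.integer(d)) != 1L))
      msg <- c(msg, "dates must be contiguous at daily step")
  }
  if (is.null(msg)) TRUE else msg
})

#' HPResult: hierarchical-partitioning decomposition of goodness-of-fit
#'
#' @slot table data.frame with one row per variable: `variable`, `I`
#'   (independent contribution), `J` (joint contribution), `I_percent`,
#'   and, when a randomization test has been run, `Z` and `significant`.
#' @slot gofFull numeric: full-model goodness-of-fit (equals `sum(I)`).
#' @slot measure character: goodness-of-fit measure name.
#' @slot n,k integers: rows and variables used.
#' @export
setClass("HPResult",
  representation(
    table = "data.frame",
    gofFull = "numeric",
    measure = "character",
    n = "integer",
    k = "integer"
  )
)

setValidity("HPResult", function(object) {
  msg <- NULL
  if (!all(c("variable", "I", "J", "I_percent") %in% colnames(object@table)))
    msg <- c(msg, "table must have variable, I, J, I_percent columns")
  if (object@k > 12L) msg <- c(msg, "at most 12 variables per partition")
  if (abs(sum(object@table$I) - object@gofFull) > 1e-6)
    msg <- c(msg, "sum of independent contributions must equal full-model gof")
  if (is.null(msg)) TRUE else msg
})

#' OrdinationResult: two-dimensional NMDS of records in anomaly space
#'
#' @slot scores numeric matrix (records x 2), centred, principal-axis rotated.
#' @slot stress numeric: Kruskal stress-1 in \[0, 1\].
#' @slot vectors data.frame of fitted environmental vectors (one row per
#'   variable: direction cosines `dx`, `dy`, `r2`, permutation `p`), possibly
#'   empty until [fitVectors()] is called.
#' @slot nStarts integer: number of random starts used.
#' @export
setClass("OrdinationResult",
  representation(
    scores = "matrix",
    stress = "numeric",
    vectors = "data.frame",
    nStarts = "integer"
  )
)

setValidity("OrdinationResult", function(object) {
  msg <- NULL
  if (ncol(object@scores) != 2L) msg <- c(msg, "scores must be two-dimensional")
  if (object@stress < 0 || object@stress > 1)
    msg <- c(msg, "stress must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @useDynLib sstshift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
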