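# Sites x variables anomaly table: every per-period statistic from the mean,
# event and variability modules, contrasted resurvey minus baseline.

#' Anomaly between two period statistics
#'
#' `difference` is resurvey minus baseline; `percent_change` is
#' 100 (resurvey - baseline) / baseline, so a decrease shows as a negative
#' percentage. Used with `percent_change` for the consecutive disparity
#' index and `difference` for everything else.
#'
#' @param resurvey,baseline numeric period statistics.
#' @param transform `"difference"` or `"percent_change"`.
#' @return numeric anomaly; `NA` when an input is undefined or a percent
#'   change has zero baseline.
#' @export
anomaly <- function(resurvey, baseline,
                    transform = c("difference", "percent_change")) {
  transform <- match.arg(transform)
  if (transform == "difference") return(resurvey - baseline)
  out <- 100 * (resurvey - baseline) / baseline
  out[!is.na(baseline) & baseline == 0] <- NA_real_
  out
}

eventStatNames <- function() {
  c("frequency", "duration_mean", "intensity_max_abs", "intensity_max_mean",
    "intensity_mean", "intensity_cum_mean", "intensity_cum_max")
}

scopeNames <- function() c("annual", "winter", "spring", "summer", "autumn")

#' The anomaly-variable registry
#'
#' Enumerates the core variable universe: 5 mean-SST scopes, 7 event
#' statistics x 5 scopes x 2 event kinds, 5 variability statistics and one
#' thermal-threshold exceedance variable per requested species — 81 columns
#' for a single species. Each entry records the family, scope, statistic and
#' anomaly transform (percent change for the disparity index D, plain
#' difference otherwise).
#'
#' @param species character vector of species for threshold variables, or
#'   `NULL` for the generic single entry.
#' @return data.frame with columns `variable`, `family`, `scope`,
#'   `statistic`, `transform`.
#' @export
variableRegistry <- function(species = NULL) {
  rows <- list()
  for (sc in scopeNames())
    rows[[length(rows) + 1L]] <- data.frame(
      variable = paste0("mean_sst.", sc), family = "mean_sst", scope = sc,
      statistic = "mean", transform = "difference")
  for (kind in c("mhw", "mcs")) for (sc in scopeNames())
    for (st in eventStatNames())
      rows[[length(rows) + 1L]] <- data.frame(
        variable = paste(kind, st, sc, sep = "."), family = kind, scope = sc,
        statistic = st, transform = "difference")
  vstats <- c(seasonality = "difference", noise_beta = "difference",
              cv = "difference", d_index = "percent_change",
              skewness = "difference")
  for (st in names(vstats))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = st, family = "variability", scope = "none", statistic = st,
      transform = vstats[[st]])
  if (is.null(species)) {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "threshold_days", family = "threshold", scope = "none",
      statistic = "threshold_days", transform = "difference")
  } else {
    for (sp in species)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = paste0("threshold_days.", sp), family = "threshold",
        scope = "none", statistic = "threshold_days", transform = "difference")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

periodStats <- function(series, period, events, spec, dOffset) {
  sl <- slicePeriod(series, period)
  out <- list()
  out[["mean_sst.annual"]] <- meanSST(sl)
  for (sc in setdiff(scopeNames(), "annual"))
    out[[paste0("mean_sst.", sc)]] <- meanSST(seasonalSubset(sl, sc, spec))
  for (kind in c("mhw", "mcs")) {
    ev <- events[[kind]]
    for (sc in scopeNames()) {
      sm <- summarizeEvents(ev, period, sc, spec)
      for (st in eventStatNames())
        out[[paste(kind, st, sc, sep = ".")]] <- sm[[st]]
    }
  }
  out[["seasonality"]] <- seasonalityRatio(sl)
  out[["noise_beta"]] <- noiseColour(sl)$beta
  out[["cv"]] <- cvPercent(sl)
  out[["d_index"]] <- dIndex(sl, offset = dOffset)
  out[["skewness"]] <- skewnessCoef(sl)
  out
}

#' Build the sites x variables anomaly table
#'
#' For every site: builds the fixed-baseline climatology on the full span,
#' detects MHWs and MCSs on the whole series, computes every registry
#' statistic per period and scope, and contrasts resurvey against baseline.
#' When one period has zero events its frequency enters the anomaly as 0,
#' but duration/intensity anomalies are left missing rather than fabricated.
#' Species whose thermal limit exceeds the domain-wide maximum SST are
#' excluded (recorded in the `excluded_species` attribute).
#'
#' @param grid a [SSTGrid-class].
#' @param baseline,resurvey [PeriodSpec-class] windows.
#' @param thresholds named numeric vector of species thermal limits (degrees
#'   C), or `NULL` for none.
#' @param spec season map.
#' @param minDuration,maxGap event-detection knobs (see [detectEvents()]).
#' @param windowHalfwidth,smooth climatology knobs (see [buildClimatology()]).
#' @param dOffset additive offset for the disparity index (recorded in the
#'   `d_offset` attribute).
#' @return data.frame with `site_id`, `lon`, `lat` and one column per
#'   registry variable; attributes `registry`, `excluded_species`,
#'   `d_offset`.
#' @export
buildVariableTable <- function(grid,
                               baseline = baselinePeriod(),
                               resurvey = resurveyPeriod(),
                               thresholds = NULL,
                               spec = seasonMap(),
                               minDuration = 5L, maxGap = 2L,
                               windowHalfwidth = 5L, smooth = 31L,
                               dOffset = 0) {
  sites <- gridSites(grid)
  domainMax <- max(SummarizedExperiment::assay(grid, "sst"), na.rm = TRUE)
  excluded <- character()
  if (!is.null(thresholds)) {
    excluded <- names(thresholds)[thresholds > domainMax]
    thresholds <- thresholds[thresholds <= domainMax]
  }
  registry <- variableRegistry(species = if (length(thresholds))
    names(thresholds) else NULL)
  if (!length(thresholds))
    registry <- registry[registry$family != "threshold", ]
  rows <- lapply(sites, function(id) {
    s <- gridSeries(grid, id)
    clim <- suppressWarnings(buildClimatology(s, windowHalfwidth, smooth))
    events <- list(
      mhw = detectEvents(s, clim, "MHW", minDuration, maxGap),
      mcs = detectEvents(s, clim, "MCS", minDuration, maxGap))
    pb <- periodStats(s, baseline, events, spec, dOffset)
    pr <- periodStats(s, resurvey, events, spec, dOffset)
    vals <- vapply(registry$variable, function(vn) {
      entry <- registry[registry$variable == vn, ]
      if (entry$family == "threshold") {
        sp <- sub("^threshold_days\\.", "", vn)
        lim <- thresholds[[sp]]
        b <- thresholdDays(slicePeriod(s, baseline), lim, baseline)
        r <- thresholdDays(slicePeriod(s, resurvey), lim, resurvey)
        return(anomaly(r, b, "difference"))
      }
      anomaly(pr[[vn]], pb[[vn]], entry$transform)
    }, numeric(1L))
    c(list(site_id = id, lon = longitude(s), lat = latitude(s)),
      as.list(vals))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  rownames(tab) <- tab$site_id
  attr(tab, "registry") <- registry
  attr(tab, "excluded_species") <- excluded
  attr(tab, "d_offset") <- dOffset
  tab
}

#' z-score a column over all rows
#'
#' @param x numeric vector.
#' @return `(x - mean) / sd` ignoring `NA`; all-`NA` with a warning when the
#'   standard deviation is zero.
#' @export
zscore <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s < .Machine$double.eps) {
    warning("zero standard deviation; z-scores undefined")
    return(rep(NA_real_, length(x)))
  }
  (x - m) / s
}

#' Group summary of an anomaly column by persistence status
#'
#' @param table a [buildVariableTable()] result (or data.frame with
#'   `site_id`).
#' @param status data.frame with `site_id` and `status` (0 extirpated /
#'   1 persisted).
#' @param column variable name.
#' @param z z-score the column over the joined rows first?
#' @return data.frame with one row per status group: `status`, `n`, `mean`,
#'   `sd`, `se`.
#' @export
groupSummary <- function(table, status, column, z = FALSE) {
  df <- merge(status[, c("site_id", "status")],
              data.frame(site_id = table$site_id, value = table[[column]]),
              by = "site_id")
  if (z) df$value <- zscore(df$value)
  out <- do.call(rbind, lapply(split(df$value, df$status), function(v) {
    v <- v[!is.na(v)]
    data.frame(n = length(v), mean = mean(v), sd = sd(v),
               se = sd(v) / sqrt(length(v)))
  }))
  out <- cbind(status = as.integer(rownames(out)), out)
  rownames(out) <- NULL
  if (any(out$n == 0L)) stop("empty status group for column ", column)
  out
}
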