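# Marine heatwave / cold-spell machinery: fixed-baseline day-of-year
# percentile climatology, run detection with gap joining, standard-scheme
# categories and per-period summaries.

circularSmooth <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, o) ((i + o - 1L) %% n) + 1L)
  rowMeans(matrix(x[idx], nrow = n))
}

#' Build a day-of-year percentile climatology
#'
#' For each day-of-year d (1..366, Feb 29 = 60) the daily values whose
#' day-of-year falls within d +/- `windowHalfwidth` are pooled across all
#' years of the climatology span; the climatological mean is the mean of the
#' pool and the upper/lower thresholds its 90th/10th percentiles. Feb 29 is
#' filled by interpolating its neighbours, then all three curves are smoothed
#' by a `smooth`-day circular moving average.
#'
#' @param series a [DailySeries-class] spanning the climatology period
#'   (default 1982-2015 when the series covers it).
#' @param windowHalfwidth pooling half-window in days (11-day window = 5).
#' @param smooth moving-average width in days (0 or 1 disables smoothing).
#' @param probs upper/lower percentile levels.
#' @return a [Climatology-class].
#' @export
buildClimatology <- function(series, windowHalfwidth = 5L, smooth = 31L,
                             probs = c(lower = 0.10, upper = 0.90)) {
  v <- seriesValues(series)
  d <- seriesDates(series)
  if (mean(is.na(v)) > 0.10)
    stop("more than 10% of days are masked; climatology rejected")
  nYears <- length(unique(format(d, "%Y")))
  unstable <- nYears < 10L
  if (unstable)
    warning("climatology built from fewer than 10 years; treat as unstable")
  doy <- adjustedDayOfYear(d)
  ok <- !is.na(v)
  pools <- split(v[ok], factor(doy[ok], levels = 1:366))
  mu <- up <- lo <- rep(NA_real_, 366L)
  grid <- setdiff(1:366, 60L)
  for (dd in grid) {
    win <- ((dd - 1L + (-windowHalfwidth:windowHalfwidth)) %% 366L) + 1L
    pool <- unlist(pools[win], use.names = FALSE)
    if (length(pool) == 0L) next
    mu[dd] <- mean(pool)
    qq <- quantile(pool, probs = c(probs[["lower"]], probs[["upper"]]),
                   names = FALSE)
    lo[dd] <- qq[1L]
    up[dd] <- qq[2L]
  }
  # Feb 29: interpolate the flanking grid days rather than using its own
  # quarter-sampled pool.
  mu[60L] <- mean(mu[c(59L, 61L)])
  up[60L] <- mean(up[c(59L, 61L)])
  lo[60L] <- mean(lo[c(59L, 61L)])
  if (smooth > 1L) {
    mu <- circularSmooth(mu, smooth)
    up <- circularSmooth(up, smooth)
    lo <- circularSmooth(lo, smooth)
  }
  new("Climatology", doy = 1:366, mean = mu, upper = up, lower = lo,
      windowHalfwidth = as.integer(windowHalfwidth),
      smooth = as.integer(max(smooth, 0L)),
      span = range(d), unstable = unstable)
}

#' @describeIn Climatology-class compact display
#' @param object a `Climatology`
#' @export
setMethod("show", "Climatology", function(object) {
  cat(sprintf(
    "Climatology %s..%s (window %dd, smooth %dd)%s\n  mean %.2f..%.2f degC\n",
    format(object@span[1L]), format(object@span[2L]),
    2L * object@windowHalfwidth + 1L, object@smooth,
    if (object@unstable) " [unstable]" else "",
    min(object@mean, na.rm = TRUE), max(object@mean, na.rm = TRUE)))
})

#' Detect marine heatwaves or cold spells
#'
#' Flags days strictly above the upper threshold (`kind = "MHW"`) or
#' strictly below the lower threshold (`kind = "MCS"`); maximal runs of
#' flagged days of length >= `minDuration` are events, and qualifying events
#' separated by <= `maxGap` non-flagged days are merged (gap days counted in
#' the duration). Daily intensity is SST minus climatological mean for MHWs
#' and climatological mean minus SST for MCSs, so intensities are positive
#' for both kinds.
#'
#' @param series a [DailySeries-class].
#' @param clim a [Climatology-class] built on the declared climatology span.
#' @param kind `"MHW"` or `"MCS"`.
#' @param minDuration minimum run length in days.
#' @param maxGap maximum join gap in days.
#' @return data.frame with one row per event: `kind`, `start`, `end`,
#'   `duration`, `intensity_max`, `intensity_mean`, `intensity_cumulative`,
#'   `peak_date`, `category` (MHW only, `NA` for MCS).
#' @export
detectEvents <- function(series, clim, kind = c("MHW", "MCS"),
                         minDuration = 5L, maxGap = 2L) {
  kind <- match.arg(kind)
  v <- seriesValues(series)
  d <- seriesDates(series)
  doy <- adjustedDayOfYear(d)
  thr <- if (kind == "MHW") clim@upper[doy] else clim@lower[doy]
  mu <- clim@mean[doy]
  flag <- if (kind == "MHW") !is.na(v) & v > thr else !is.na(v) & v < thr
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  qual <- which(runs$values & runs$lengths >= minDuration)
  if (length(qual) == 0L) return(emptyEventFrame())
  ev <- data.frame(start = starts[qual], end = ends[qual])
  # merge qualifying events separated by short gaps
  merged <- ev[1L, , drop = FALSE]
  if (nrow(ev) > 1L) for (i in 2:nrow(ev)) {
    gap <- ev$start[i] - merged$end[nrow(merged)] - 1L
    if (gap <= maxGap) merged$end[nrow(merged)] <- ev$end[i]
    else merged <- rbind(merged, ev[i, ])
  }
  intensity <- if (kind == "MHW") v - mu else mu - v
  nEv <- nrow(merged)
  iMax <- iMean <- iCum <- numeric(nEv)
  peakIdx <- integer(nEv)
  for (i in seq_len(nEv)) {
    idx <- merged$start[i]:merged$end[i]
    ii <- intensity[idx]
    iMax[i] <- max(ii, na.rm = TRUE)
    iMean[i] <- mean(ii, na.rm = TRUE)
    iCum[i] <- sum(ii, na.rm = TRUE)
    peakIdx[i] <- idx[which.max(ii)]
  }
  out <- data.frame(kind = kind, start = d[merged$start], end = d[merged$end],
                    duration = merged$end - merged$start + 1L,
                    intensity_max = iMax, intensity_mean = iMean,
                    intensity_cumulative = iCum, peak_date = d[peakIdx],
                    category = NA_integer_, stringsAsFactors = FALSE)
  if (kind == "MHW") {
    pd <- doy[peakIdx]
    gap <- clim@upper[pd] - clim@mean[pd]
    ok <- is.finite(gap) & gap > 0
    cat4 <- rep(NA_integer_, nEv)
    cat4[ok] <- pmin(4L, pmax(1L, as.integer(
      ceiling(iMax[ok] / gap[ok] - 1 - 1e-12))))
    out$category <- cat4
  }
  out
}

emptyEventFrame <- function() {
  data.frame(kind = character(), start = as.Date(character()),
             end = as.Date(character()), duration = integer(),
             intensity_max = numeric(), intensity_mean = numeric(),
             intensity_cumulative = numeric(),
             peak_date = as.Date(character()), category = integer(),
             stringsAsFactors = FALSE)
}

#' Category of a marine heatwave
#'
#' Multiples of the local climatological (threshold - mean) gap at the peak
#' date, following the standard category scheme: a maximum intensity in
#' (1, 2\] gaps is category I (moderate), (2, 3\] II (strong), (3, 4\] III
#' (severe) and above 4 gaps IV (extreme).
#'
#' @param event one event row as returned by [detectEvents()].
#' @param clim a [Climatology-class].
#' @return integer category 1..4, or `NA` when the gap is zero.
#' @export
categorizeEvent <- function(event, clim) {
  doy <- adjustedDayOfYear(as.Date(event$peak_date))
  gap <- clim@upper[doy] - clim@mean[doy]
  if (!is.finite(gap) || gap <= 0) return(NA_integer_)
  ratio <- event$intensity_max / gap
  min(4L, max(1L, as.integer(ceiling(ratio - 1 - 1e-12))))
}

#' Summarize events for one period and scope
#'
#' Events are assigned to the period containing their start date; for a
#' seasonal scope only events whose start month maps to the season are kept.
#' Frequency is events per year of period length; the remaining statistics
#' are undefined (`NA`) when the period has no events.
#'
#' @param events data.frame from [detectEvents()].
#' @param period a [PeriodSpec-class].
#' @param scope `"annual"` or a season label.
#' @param spec season map.
#' @return one-row data.frame: `n_events`, `frequency` (events/yr),
#'   `duration_mean` (days), `intensity_max_abs`, `intensity_max_mean`,
#'   `intensity_mean`, `intensity_cum_mean`, `intensity_cum_max`.
#' @export
summarizeEvents <- function(events, period, scope = "annual",
                            spec = seasonMap()) {
  keep <- events$start >= period@start & events$start <= period@end
  if (scope != "annual") {
    m <- as.integer(format(as.Date(events$start), "%m"))
    keep <- keep & seasonOf(m, spec) == scope
  }
  ev <- events[keep, , drop = FALSE]
  yrs <- periodYears(period)
  if (nrow(ev) == 0L)
    return(data.frame(n_events = 0L, frequency = 0,
                      duration_mean = NA_real_, intensity_max_abs = NA_real_,
                      intensity_max_mean = NA_real_, intensity_mean = NA_real_,
                      intensity_cum_mean = NA_real_,
                      intensity_cum_max = NA_real_))
  data.frame(n_events = nrow(ev),
             frequency = nrow(ev) / yrs,
             duration_mean = mean(ev$duration),
             intensity_max_abs = max(ev$intensity_max),
             intensity_max_mean = mean(ev$intensity_max),
             intensity_mean = mean(ev$intensity_mean),
             intensity_cum_mean = mean(ev$intensity_cumulative),
             intensity_cum_max = max(ev$intensity_cumulative))
}
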