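# Temporal-variability statistics: trend/season/residual decomposition,
# unbounded seasonality a/b, spectral colour of noise, CV, consecutive
# disparity index D, skewness, and thermal-threshold exceedance.

#' Decompose a daily series into trend, seasonal and residual parts
#'
#' (1) an ordinary-least-squares line on time is removed; (2) the seasonal
#' component is the 12 monthly means of the detrended series, placed at month
#' midpoints and linearly interpolated back to daily resolution, circularly
#' across the Dec-Jan boundary; (3) residuals are the detrended series minus
#' the seasonal component.
#'
#' @param series a [DailySeries-class] covering >= 2 whole years with every
#'   month represented.
#' @return list with numeric vectors `trend`, `seasonal`, `residuals`
#'   (masked days `NA`) aligned with `seriesDates(series)`.
#' @export
decomposeSeries <- function(series) {
  v <- seriesValues(series)
  d <- seriesDates(series)
  if (as.numeric(max(d) - min(d)) < 2 * 365 - 31)
    stop("decomposition needs at least 2 whole years")
  ok <- !is.na(v)
  m <- as.integer(format(d, "%m"))
  if (length(unique(m[ok])) < 12L)
    stop("a month is absent from the series; decomposition undefined")
  tt <- as.numeric(d - d[1L])
  fit <- lm(v ~ tt, subset = ok)
  trend <- as.numeric(coef(fit)[1L] + coef(fit)[2L] * tt)
  det <- v - trend
  monthMean <- tapply(det[ok], m[ok], mean)
  # month midpoints on the phase-continuous day-of-year axis
  midDoy <- c(16, 45.5, 75, 105.5, 136, 166.5, 197, 228, 258.5, 289, 319.5, 350)
  doy <- cycleDayOfYear(d)
  # circular interpolation: extend the 12 anchors by one period on each side
  xs <- c(midDoy[12L] - 365.25, midDoy, midDoy[1L] + 365.25)
  ys <- as.numeric(monthMean[c("12", sprintf("%d", 1:12), "1")])
  seasonal <- approx(xs, ys, xout = doy, rule = 2)$y
  res <- det - seasonal
  list(trend = trend, seasonal = seasonal, residuals = res)
}

#' Unbounded seasonality a/b
#'
#' Ratio between the variance of the interpolated daily seasonal component
#' (`a`) and the variance of the residuals after removing both the linear
#' trend and the seasonal component (`b`). White-noise-only series give a/b
#' near 0; a noiseless seasonal cycle gives the `Inf` sentinel.
#'
#' @param series a [DailySeries-class].
#' @return numeric scalar >= 0, or `Inf` when residual variance is zero.
#' @export
seasonalityRatio <- function(series) {
  dec <- decomposeSeries(series)
  ok <- !is.na(dec$residuals)
  a <- var(dec$seasonal[ok])
  b <- var(dec$residuals[ok])
  if (b < .Machine$double.eps) return(Inf)
  a / b
}

#' Colour of environmental noise
#'
#' Raw (unsmoothed, untapered) periodogram of the detrended, de-seasoned
#' residuals; beta is minus the OLS slope of ln(spectral density) on
#' ln(frequency) over all positive frequencies. Labels follow the standard
#' bins: white 0 <= beta <= 0.5, red 0.5 < beta <= 1.5, brown
#' 1.5 < beta <= 2; values outside \[0, 2\] are labelled out-of-range.
#'
#' @param series a [DailySeries-class].
#' @return list with `beta` (numeric) and `label` (character).
#' @export
noiseColour <- function(series) {
  dec <- decomposeSeries(series)
  r <- dec$residuals[!is.na(dec$residuals)]
  if (sd(r) < .Machine$double.eps) stop("residuals are constant; colour undefined")
  n <- length(r)
  r <- r - mean(r)
  I <- Mod(fft(r))^2 / n
  m <- n %/% 2L
  f <- (1:m) / n
  dens <- I[2:(m + 1L)]
  keep <- dens > 0
  slope <- coef(lm(log(dens[keep]) ~ log(f[keep])))[[2L]]
  beta <- -slope
  label <- if (beta < 0 || beta > 2) "out-of-range"
           else if (beta <= 0.5) "white"
           else if (beta <= 1.5) "red"
           else "brown"
  list(beta = beta, label = label)
}

#' Coefficient of variation (percent)
#'
#' CV = sample standard deviation (n-1 denominator) / mean x 100.
#'
#' @param series a [DailySeries-class] (or numeric vector).
#' @return numeric scalar (percent), `NA` for non-positive mean.
#' @export
cvPercent <- function(series) {
  v <- if (is(series, "DailySeries")) seriesValues(series) else series
  v <- v[!is.na(v)]
  m <- mean(v)
  if (m <= 0) return(NA_real_)
  sd(v) / m * 100
}

#' Consecutive disparity index D
#'
#' D = 1/(n-1) * sum_i |ln(p_{i+1} / p_i)| over consecutive unmasked values:
#' a chronology-aware variability measure that is 0 for constant series and
#' invariant to multiplicative rescaling. All values must be strictly
#' positive; `offset` is added beforehand when supplied (recorded by the
#' caller, not here).
#'
#' @param series a [DailySeries-class] (or numeric vector).
#' @param offset additive offset applied before the log-ratios.
#' @return numeric scalar >= 0.
#' @export
dIndex <- function(series, offset = 0) {
  p <- if (is(series, "DailySeries")) seriesValues(series) else series
  p <- p[!is.na(p)] + offset
  if (any(p <= 0))
    stop("D is undefined for values <= 0; consider the additive offset")
  if (length(p) < 2L) return(0)
  mean(abs(diff(log(p))))
}

#' Skewness (third standardized moment)
#'
#' m3 / m2^(3/2) with population moments (mean of centred k-th powers).
#' Positive skew indicates dominance of values below the mean with a long
#' upper tail.
#'
#' @param series a [DailySeries-class] (or numeric vector).
#' @return numeric scalar, `NA` for zero variance or n < 3.
#' @export
skewnessCoef <- function(series) {
  v <- if (is(series, "DailySeries")) seriesValues(series) else series
  v <- v[!is.na(v)]
  if (length(v) < 3L) return(NA_real_)
  m2 <- mean((v - mean(v))^2)
  if (m2 < .Machine$double.eps) return(NA_real_)
  mean((v - mean(v))^3) / m2^1.5
}

#' Days per year above a species' thermal limit
#'
#' @param series a [DailySeries-class] restricted to the period of interest.
#' @param limit thermal threshold, degrees C.
#' @param period a [PeriodSpec-class] defining the divisor in years; defaults
#'   to the series' own span.
#' @return numeric scalar, mean days/year with SST strictly above `limit`.
#' @export
thresholdDays <- function(series, limit, period = NULL) {
  v <- seriesValues(series)
  yrs <- if (is.null(period)) {
    d <- seriesDates(series)
    as.numeric(max(d) - min(d) + 1) / 365.25
  } else periodYears(period)
  sum(v > limit, na.rm = TRUE) / yrs
}
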