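# Calendar machinery shared by the climatology and seasonal statistics.

#' Leap-aware day-of-year on a 366-day grid
#'
#' Maps each date onto a fixed 1..366 grid in which Feb 29 is day 60 and
#' every date after Feb 28 in a non-leap year is shifted by one, so a given
#' grid day always corresponds to the same calendar day across years.
#'
#' @param dates `Date` vector.
#' @return integer vector in 1..366.
#' @export
adjustedDayOfYear <- function(dates) {
  dates <- as.Date(dates)
  yd <- as.POSIXlt(dates)$yday + 1L
  leap <- isLeapYear(as.integer(format(dates, "%Y")))
  ifelse(!leap & yd >= 60L, yd + 1L, yd)
}

#' @rdname adjustedDayOfYear
#' @param year integer vector of calendar years.
#' @export
isLeapYear <- function(year) {
  (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
}

#' Continuous day-of-year for seasonal-phase computations
#'
#' Like [adjustedDayOfYear()] but returns 59.5 for Feb 29 so the seasonal
#' cycle stays phase-continuous across leap days, and values follow the
#' ordinary 1..365 convention otherwise.
#'
#' @param dates `Date` vector.
#' @return numeric vector.
#' @export
cycleDayOfYear <- function(dates) {
  dates <- as.Date(dates)
  yd <- as.POSIXlt(dates)$yday + 1L
  leap <- isLeapYear(as.integer(format(dates, "%Y")))
  out <- as.numeric(yd)
  feb29 <- leap & yd == 60L
  out[feb29] <- 59.5
  shift <- leap & yd > 60L
  out[shift] <- out[shift] - 1
  out
}

#' Northern-Hemisphere season map
#'
#' Months are mapped to meteorological seasons: winter = Dec-Feb, spring =
#' Mar-May, summer = Jun-Aug, autumn = Sep-Nov. December belongs to the
#' winter labelled by the following January's year, keeping each winter a
#' contiguous block.
#'
#' @return named character vector of length 12 (month number to season).
#' @export
seasonMap <- function() {
  c("1" = "winter", "2" = "winter", "3" = "spring", "4" = "spring",
    "5" = "spring", "6" = "summer", "7" = "summer", "8" = "summer",
    "9" = "autumn", "10" = "autumn", "11" = "autumn", "12" = "winter")
}

#' @rdname seasonMap
#' @param month integer vector in 1..12.
#' @param spec season map as returned by [seasonMap()].
#' @export
seasonOf <- function(month, spec = seasonMap()) {
  if (any(is.na(match(as.character(month), names(spec)))))
    stop("month must be in 1..12")
  unname(spec[as.character(month)])
}

#' @rdname seasonMap
#' @param dates `Date` vector.
#' @return `seasonYear`: the year labelling each date's season (December is
#'   assigned to the following year's winter).
#' @export
seasonYear <- function(dates) {
  dates <- as.Date(dates)
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  ifelse(m == 12L, y + 1L, y)
}

#' Analysis period specifications
#'
#' `periodSpec()` builds an arbitrary window; `baselinePeriod()` and
#' `resurveyPeriod()` return the default study windows (1982-1990 and
#' 1991-2015), which partition the full SST record with the resurvey
#' starting the day after the baseline ends.
#'
#' @param name character scalar.
#' @param start,end inclusive `Date` bounds.
#' @return a [PeriodSpec-class] object.
#' @export
periodSpec <- function(name, start, end) {
  new("PeriodSpec", name = name, start = as.Date(start), end = as.Date(end))
}

#' @rdname periodSpec
#' @export
baselinePeriod <- function() {
  periodSpec("baseline", "1982-01-01", "1990-12-31")
}

#' @rdname periodSpec
#' @export
resurveyPeriod <- function() {
  periodSpec("resurvey", "1991-01-01", "2015-12-31")
}

#' @rdname periodSpec
#' @param period a [PeriodSpec-class].
#' @return `periodYears`: period length in (mean Julian) years.
#' @export
periodYears <- function(period) {
  as.numeric(period@end - period@start + 1L) / 365.25
}

#' @describeIn PeriodSpec-class compact display
#' @param object a `PeriodSpec`
#' @export
setMethod("show", "PeriodSpec", function(object) {
  cat(sprintf("PeriodSpec '%s': %s .. %s (%.2f yr)\n", object@name,
              format(object@start), format(object@end), periodYears(object)))
})
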