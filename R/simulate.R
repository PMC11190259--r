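# Synthetic gridded SST with the statistical structure the analysis assumes:
# west-east gradient in mean and seasonal amplitude, linear warming trend,
# AR(1) or spectrally coloured noise, and injectable discrete warm/cold events.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulation configuration for a synthetic SST grid
#'
#' Per-site parameters may be scalars (recycled) or length-`nSites` vectors.
#' The defaults state a study region resembling a temperate coastal gradient:
#' mean SST rising west to east from 14 to 17 degrees C, a warming trend of
#' 0.2 degrees C per decade, a seasonal amplitude of 2.8 (west) to 3.6 (east)
#' degrees C in the baseline period that increases in the east (+0.4) and
#' slightly decreases in the west (-0.1) at resurvey, and strongly
#' autocorrelated daily noise (`rho` = 0.9, innovation sd 0.4 degrees C).
#'
#' @param nSites number of grid cells, laid out west to east.
#' @param start,end span of the daily record (must cover >= 2 years).
#' @param mu per-site base mean SST (degrees C); default a west-east ramp.
#' @param trend linear warming (degrees C per decade).
#' @param amp1,amp2 seasonal amplitude (degrees C) in the baseline and
#'   resurvey periods; the switch happens at `boundary`.
#' @param phase seasonal phase (radians); the default puts the annual peak
#'   in mid-August.
#' @param rho AR(1) coefficient of the daily noise (|rho| < 1).
#' @param sigma innovation standard deviation (degrees C), > 0.
#' @param beta optional spectral exponent in \[0, 2\]; when non-`NULL` the
#'   noise is 1/f^beta spectrally synthesized instead of AR(1), standardized
#'   to sd `sigma`.
#' @param boundary last day of the baseline period (amplitude switch).
#' @param events list of event injections, each a list with `site` (index),
#'   `start` (date), `duration` (days), `peak` (degrees C) and `sign`
#'   (+1 warm / -1 cold); injected as half-sine bumps.
#' @param lon,lat cell-centre coordinates; defaults span -9 to -2 E at 43.5 N.
#' @param seed RNG seed.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSites = 20L,
                             start = "1982-01-01", end = "2015-12-31",
                             mu = NULL, trend = 0.2,
                             amp1 = NULL, amp2 = NULL,
                             phase = -2.55, rho = 0.9, sigma = 0.4,
                             beta = NULL,
                             boundary = "1990-12-31",
                             events = list(),
                             lon = NULL, lat = 43.5, seed = 1L) {
  nSites <- as.integer(nSites)
  start <- as.Date(start); end <- as.Date(end)
  if (as.numeric(end - start) < 2 * 365)
    stop("span shorter than 2 years: seasonality undefined (config error)")
  ramp <- function(a, b) if (nSites == 1L) (a + b) / 2 else
    seq(a, b, length.out = nSites)
  if (is.null(lon)) lon <- ramp(-9, -2)
  if (is.null(mu)) mu <- ramp(14, 17)
  if (is.null(amp1)) amp1 <- ramp(2.8, 3.6)
  if (is.null(amp2)) amp2 <- amp1 + ramp(-0.1, 0.4)
  rec <- function(x) rep_len(as.numeric(x), nSites)
  cfg <- list(nSites = nSites, start = start, end = end,
              mu = rec(mu), trend = rec(trend), amp1 = rec(amp1),
              amp2 = rec(amp2), phase = rec(phase), rho = rec(rho),
              sigma = rec(sigma), beta = if (is.null(beta)) NULL else rec(beta),
              boundary = as.Date(boundary), events = events,
              lon = rec(lon), lat = rec(lat), seed = as.integer(seed))
  stopifnot(all(cfg$sigma >= 0), all(abs(cfg$rho) < 1))
  if (!is.null(cfg$beta)) stopifnot(all(cfg$beta >= 0), all(cfg$beta <= 2))
  for (ev in cfg$events) stopifnot(ev$duration >= 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Spectrally synthesized coloured noise
#'
#' Inverse-FFT synthesis with amplitude proportional to f^(-beta/2) and
#' independent uniform random phases, standardized to zero mean and unit
#' standard deviation. `beta` = 0 gives white noise, 2 brown noise.
#'
#' @param n series length.
#' @param beta spectral exponent.
#' @param seed optional RNG seed.
#' @return numeric vector of length `n`, sd 1.
#' @export
colouredNoise <- function(n, beta, seed = NULL) {
  withSeed(seed, {
    m <- n %/% 2L
    f <- (1:m) / n
    amp <- f^(-beta / 2)
    ph <- runif(m, 0, 2 * pi)
    spec <- complex(length.out = n)
    spec[2:(m + 1L)] <- amp * exp(1i * ph)
    if (n %% 2L == 0L) {
      spec[m + 1L] <- amp[m] * cos(ph[m])   # Nyquist bin must be real
      if (m > 1L) spec[n:(n - m + 2L)] <- Conj(spec[2:m])
    } else {
      spec[n:(n - m + 1L)] <- Conj(spec[2:(m + 1L)])
    }
    x <- Re(fft(spec, inverse = TRUE))
    as.numeric(scale(x))
  })
}

halfSineBump <- function(n, duration, startIdx, peak) {
  bump <- numeric(n)
  j <- seq_len(duration)
  idx <- startIdx + j - 1L
  ok <- idx >= 1L & idx <= n
  bump[idx[ok]] <- peak * sin(pi * (j[ok] - 0.5) / duration)
  bump
}

#' Simulate one site's daily SST series
#'
#' SST(t) = mu + b t + A(t) sin(2 pi d(t)/365.25 + phase) + eps(t), where
#' A(t) switches from `amp1` to `amp2` after the period boundary, d(t) is the
#' phase-continuous day-of-year ([cycleDayOfYear()]), and eps is AR(1) with
#' innovation sd `sigma` (or 1/f^beta coloured noise standardized to sd
#' `sigma` when `beta` is set). Injected events add half-sine bumps.
#' Deterministic given `cfg$seed` (fanned out per site).
#'
#' @param cfg a [simulationConfig()].
#' @param site site index in 1..`cfg$nSites`.
#' @return a [DailySeries-class].
#' @export
simulateSeries <- function(cfg, site = 1L) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  i <- as.integer(site)
  dates <- seq(cfg$start, cfg$end, by = "day")
  n <- length(dates)
  tDec <- as.numeric(dates - cfg$start) / 3652.5
  doy <- cycleDayOfYear(dates)
  A <- ifelse(dates <= cfg$boundary, cfg$amp1[i], cfg$amp2[i])
  det <- cfg$mu[i] + cfg$trend[i] * tDec +
    A * sin(2 * pi * doy / 365.25 + cfg$phase[i])
  eps <- withSeed(cfg$seed + i, {
    if (!is.null(cfg$beta)) {
      if (cfg$sigma[i] > 0) cfg$sigma[i] * colouredNoise(n, cfg$beta[i])
      else numeric(n)
    } else if (cfg$sigma[i] > 0) {
      as.numeric(stats::filter(rnorm(n, 0, cfg$sigma[i]), cfg$rho[i],
                               method = "recursive"))
    } else numeric(n)
  })
  x <- det + eps
  for (ev in cfg$events) {
    evSite <- if (is.null(ev$site)) 1L else as.integer(ev$site)
    if (evSite != i) next
    startIdx <- as.integer(as.Date(ev$start) - cfg$start) + 1L
    sgn <- if (is.null(ev$sign)) 1 else sign(ev$sign)
    x <- x + halfSineBump(n, as.integer(ev$duration), startIdx,
                          sgn * abs(ev$peak))
  }
  DailySeries(x, dates, lon = cfg$lon[i], lat = cfg$lat[i])
}

#' Simulate a full west-east grid
#'
#' @param cfg a [simulationConfig()]; defaults encode a monotone west-east
#'   gradient in mean SST and in the resurvey-minus-baseline amplitude change.
#' @return a [SSTGrid-class] with `cfg$nSites` sites.
#' @export
simulateGrid <- function(cfg = simulationConfig()) {
  SSTGrid(lapply(seq_len(cfg$nSites), function(i) simulateSeries(cfg, i)))
}

#' Simulate species persistence / extirpation outcomes
#'
#' Status is Bernoulli with success probability
#' logistic(intercept + sum coef_j z_j), where z_j is the z-scored column
#' named by each coefficient. Deterministic given `seed`.
#'
#' @param variables sites x variables table (a [buildVariableTable()] result
#'   or plain data.frame with a `site_id` column).
#' @param coef named numeric vector over columns of `variables`.
#' @param intercept numeric.
#' @param species species name for the output records.
#' @param seed RNG seed.
#' @return data.frame with columns `species`, `site_id`, `status`.
#' @export
simulateSpecies <- function(variables, coef, intercept = 0,
                            species = "synthetic sp.", seed = 1L) {
  tab <- as.data.frame(variables)
  miss <- setdiff(names(coef), colnames(tab))
  if (length(miss)) stop("unknown variable name(s): ", paste(miss, collapse = ", "))
  eta <- rep(intercept, nrow(tab))
  for (nm in names(coef)) {
    z <- zscore(tab[[nm]])
    eta <- eta + coef[[nm]] * z
  }
  status <- withSeed(seed, rbinom(length(eta), 1L, plogis(eta)))
  data.frame(species = species,
             site_id = if ("site_id" %in% colnames(tab)) tab$site_id
                       else rownames(tab),
             status = status, stringsAsFactors = FALSE)
}
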