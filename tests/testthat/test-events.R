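test_that("climatology of a constant series collapses to the constant", {
  d <- seq(as.Date("1982-01-01"), as.Date("1993-12-31"), by = "day")
  s <- DailySeries(rep(15, length(d)), d)
  clim <- buildClimatology(s)
  expect_equal(clim@mean, rep(15, 366))
  expect_equal(clim@upper, rep(15, 366))
  expect_equal(clim@lower, rep(15, 366))
  expect_identical(nrow(detectEvents(s, clim, "MHW")), 0L)
  expect_identical(nrow(detectEvents(s, clim, "MCS")), 0L)
})

test_that("climatological mean tracks a pure sinusoid", {
  s <- sinusoidSeries()                      # 34 yr, A = 4
  clim <- buildClimatology(s)
  doy <- adjustedDayOfYear(seriesDates(s))
  # analytic limit: the 11-day pooling window and 31-day smoothing attenuate
  # a sinusoid of amplitude A by the product of two Dirichlet factors
  att <- function(w) sin(w * pi / 365.25) / (w * sin(pi / 365.25))
  predicted <- 4 * (1 - att(11) * att(31))
  dev <- max(abs(clim@mean[doy] - seriesValues(s)))
  expect_lt(dev, 1.3 * predicted)
  expect_equal(dev, predicted, tolerance = 0.3)
})

test_that("unsmoothed thresholds equal a brute-force percentile on the pools", {
  s <- sinusoidSeries("1982-01-01", "1998-12-31", noiseSd = 1, seed = 8)
  clim <- buildClimatology(s, smooth = 0L)
  pools <- oracleClimPools(s)
  for (dd in c(1, 59, 61, 180, 300, 366)) {
    expect_equal(clim@mean[dd], pools[[dd]][["mean"]], tolerance = 1e-9)
    expect_equal(clim@upper[dd], pools[[dd]][["upper"]], tolerance = 1e-9)
    expect_equal(clim@lower[dd], pools[[dd]][["lower"]], tolerance = 1e-9)
  }
  # white noise around a constant: upper - mean near the normal 90% quantile
  expect_equal(mean(clim@upper - clim@mean, na.rm = TRUE), qnorm(0.9),
               tolerance = 0.05)
})

test_that("short exceedance runs are not events; gap joining merges runs", {
  d <- seq(as.Date("1982-01-01"), as.Date("1993-12-31"), by = "day")
  v <- rep(15, length(d))
  base <- DailySeries(v, d)
  clim <- buildClimatology(base)             # flat at 15
  v4 <- v; v4[200:203] <- 17                 # 4 days: below min duration
  expect_identical(nrow(detectEvents(DailySeries(v4, d), clim, "MHW")), 0L)
  v5 <- v; v5[200:204] <- 17
  ev <- detectEvents(DailySeries(v5, d), clim, "MHW")
  expect_identical(ev$duration, 5L)
  expect_true(is.na(ev$category))   # zero threshold-mean gap: undefined flag
  # two qualifying runs separated by a 2-day gap merge, 3-day gap stays split
  vm <- v; vm[200:205] <- 17; vm[208:213] <- 17
  expect_identical(detectEvents(DailySeries(vm, d), clim, "MHW")$duration, 14L)
  vs <- v; vs[200:205] <- 17; vs[209:214] <- 17
  expect_identical(detectEvents(DailySeries(vs, d), clim, "MHW")$duration,
                   c(6L, 6L))
})

test_that("detector equals the brute-force oracle on random series", {
  for (seed in 1:12) {
    cfg <- simulationConfig(nSites = 1L, start = "1982-01-01",
                            end = "1995-12-31", boundary = "1988-12-31",
                            rho = 0.8, sigma = 0.6, seed = seed)
    s <- simulateSeries(cfg, 1)
    clim <- buildClimatology(s)
    for (kind in c("MHW", "MCS")) {
      got <- detectEvents(s, clim, kind)
      want <- oracleDetect(s, clim, kind)
      expect_identical(nrow(got), nrow(want))
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
      expect_identical(got$duration, want$duration)
    }
  }
})

test_that("raising minDuration or maxGap never increases the event count", {
  cfg <- simulationConfig(nSites = 1L, start = "1982-01-01",
                          end = "1999-12-31", boundary = "1990-12-31",
                          rho = 0.85, sigma = 0.5, seed = 21)
  s <- simulateSeries(cfg, 1)
  clim <- buildClimatology(s)
  counts <- sapply(c(5, 7, 10), function(md)
    nrow(detectEvents(s, clim, "MHW", minDuration = md)))
  expect_true(all(diff(counts) <= 0))
  countsGap <- sapply(c(0, 2, 4), function(g)
    nrow(detectEvents(s, clim, "MHW", maxGap = g)))
  expect_true(all(diff(countsGap) <= 0))
  coverage <- sapply(c(0, 2, 4), function(g)
    sum(detectEvents(s, clim, "MHW", maxGap = g)$duration))
  expect_true(all(diff(coverage) >= 0))
})

test_that("MHW/MCS are symmetric under reflection and never share a day", {
  cfg <- simulationConfig(nSites = 1L, start = "1982-01-01",
                          end = "1999-12-31", boundary = "1990-12-31",
                          rho = 0.8, sigma = 0.5, seed = 9)
  s <- simulateSeries(cfg, 1)
  clim <- buildClimatology(s)
  mhw <- detectEvents(s, clim, "MHW")
  mcs <- detectEvents(s, clim, "MCS")
  # reflect the series around the climatological mean; swap thresholds too
  doy <- adjustedDayOfYear(seriesDates(s))
  refl <- DailySeries(2 * clim@mean[doy] - seriesValues(s), seriesDates(s))
  climR <- new("Climatology", doy = clim@doy, mean = clim@mean,
               upper = 2 * clim@mean - clim@lower,
               lower = 2 * clim@mean - clim@upper,
               windowHalfwidth = clim@windowHalfwidth, smooth = clim@smooth,
               span = clim@span, unstable = clim@unstable)
  mhwR <- detectEvents(refl, climR, "MHW")
  expect_identical(mhwR$start, mcs$start)
  expect_identical(mhwR$duration, mcs$duration)
  expect_equal(mhwR$intensity_cumulative, mcs$intensity_cumulative)
  dayIn <- function(ev) unlist(mapply(seq, as.integer(ev$start),
                                      as.integer(ev$end), SIMPLIFY = FALSE))
  expect_length(intersect(dayIn(mhw), dayIn(mcs)), 0L)
})

test_that("category counts whole threshold-gap multiples, capped at IV", {
  d <- seq(as.Date("1982-01-01"), as.Date("1993-12-31"), by = "day")
  doy <- cycleDayOfYear(d)
  v <- 15 + 2 * sin(2 * pi * doy / 365.25) + rnorm(length(d), 0, 0.3)
  set.seed(2)
  s0 <- DailySeries(v, d)
  clim <- buildClimatology(s0)
  # inject a bump with known peak over the local gap
  idx <- 600:611
  gap <- clim@upper[adjustedDayOfYear(d[idx])] - clim@mean[adjustedDayOfYear(d[idx])]
  v2 <- v; v2[idx] <- clim@mean[adjustedDayOfYear(d[idx])] + 2.5 * max(gap)
  ev <- detectEvents(DailySeries(v2, d), clim, "MHW")
  ev <- ev[ev$start <= d[605] & ev$end >= d[605], ]
  ratio <- ev$intensity_max /
    (clim@upper[adjustedDayOfYear(ev$peak_date)] -
       clim@mean[adjustedDayOfYear(ev$peak_date)])
  expect_identical(ev$category, min(4L, max(1L, as.integer(ceiling(ratio - 1)))))
  expect_gte(ev$category, 2L)    # 2.5x the largest local gap is at least strong
})

test_that("summaries match the event list and handle empty periods", {
  p4 <- periodSpec("p", "1982-01-01", "1985-12-30")  # 4 years to within a day
  ev <- data.frame(kind = "MHW",
                   start = as.Date(c("1982-06-10", "1984-12-05")),
                   end = as.Date(c("1982-06-15", "1984-12-14")),
                   duration = c(6L, 10L),
                   intensity_max = c(2, 3), intensity_mean = c(1.5, 2.5),
                   intensity_cumulative = c(9, 25),
                   peak_date = as.Date(c("1982-06-12", "1984-12-07")),
                   category = c(1L, 2L))
  sm <- summarizeEvents(ev, p4, "annual")
  expect_equal(sm$frequency, 2 / periodYears(p4))
  expect_equal(sm$frequency, 0.5, tolerance = 0.01)
  expect_equal(sm$duration_mean, 8)
  expect_equal(sm$intensity_max_abs, 3)
  expect_equal(sm$intensity_max_mean, 2.5)
  expect_equal(sm$intensity_cum_mean, 17)
  expect_equal(sm$intensity_cum_max, 25)
  # seasonal scope keeps only events whose start month maps to the season
  expect_identical(summarizeEvents(ev, p4, "summer")$n_events, 1L)
  expect_identical(summarizeEvents(ev, p4, "winter")$n_events, 1L)
  expect_identical(summarizeEvents(ev, p4, "spring")$n_events, 0L)
  empty <- summarizeEvents(ev, periodSpec("none", "1990-01-01", "1991-01-01"),
                           "annual")
  expect_equal(empty$frequency, 0)
  expect_true(is.na(empty$duration_mean))
})

test_that("per-period summaries equal a brute-force recomputation", {
  for (seed in 1:5) {
    cfg <- simulationConfig(nSites = 1L, start = "1982-01-01",
                            end = "1997-12-31", boundary = "1989-12-31",
                            rho = 0.8, sigma = 0.5, seed = 100 + seed)
    s <- simulateSeries(cfg, 1)
    clim <- buildClimatology(s)
    ev <- detectEvents(s, clim, "MHW")
    p <- periodSpec("baseline", "1982-01-01", "1989-12-31")
    sm <- summarizeEvents(ev, p, "annual")
    keep <- ev[ev$start >= p@start & ev$start <= p@end, ]
    expect_identical(sm$n_events, nrow(keep))
    expect_equal(sm$frequency, nrow(keep) / (as.numeric(p@end - p@start + 1) / 365.25))
    if (nrow(keep)) {
      expect_equal(sm$duration_mean, sum(keep$duration) / nrow(keep))
      expect_equal(sm$intensity_cum_max, max(keep$intensity_cumulative))
    }
  }
})
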