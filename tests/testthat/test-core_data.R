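test_that("persistence/extirpation coding follows the survey rules", {
  expect_identical(codeStatus(TRUE, TRUE), 1L)
  expect_identical(codeStatus(FALSE, TRUE), 1L)
  expect_identical(codeStatus(TRUE, FALSE), 0L)
  expect_true(is.na(codeStatus(FALSE, FALSE)))
  expect_identical(codeStatus(TRUE, TRUE, override = TRUE), 0L)
  # vectorized with per-row override
  expect_identical(codeStatus(c(1, 1, 0, 0), c(1, 0, 1, 0),
                              c(TRUE, FALSE, FALSE, FALSE)),
                   c(0L, 0L, 1L, NA))
})

test_that("species records reader codes and drops rows as specified", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species,site_id,presence_baseline,presence_resurvey,override_zero",
    "sp,s1,1,0,0", "sp,s2,0,1,0", "sp,s3,0,0,0", "sp,s4,1,1,1"), path)
  rec <- readSpeciesRecords(path)
  expect_identical(nrow(rec), 3L)           # never-observed s3 dropped
  expect_identical(rec$status[rec$site_id == "s1"], 0L)
  expect_identical(rec$status[rec$site_id == "s2"], 1L)
  expect_identical(rec$status[rec$site_id == "s4"], 0L)  # override
})

test_that("thermal-threshold registry holds the published limits", {
  thr <- thermalThresholds()
  expect_equal(thr[["F. serratus"]], 25)
  expect_equal(thr[["H. elongata"]], 18)
  expect_equal(thr[["L. ochroleuca"]], 23)
  expect_equal(thr[["S. polyschides"]], 24)
  expect_equal(thr[["L. hyperborea"]], 20)
  expect_equal(thr[["F. vesiculosus"]], 28)
  expect_error(thermalThreshold("no-such-species"), "unknown species")
})

test_that("period slicing partitions the record with exact calendar lengths", {
  d <- seq(as.Date("1982-01-01"), as.Date("2015-12-31"), by = "day")
  s <- DailySeries(rnorm(length(d), 15), d, lon = -8, lat = 43.5)
  b <- slicePeriod(s, baselinePeriod())
  r <- slicePeriod(s, resurveyPeriod())
  expect_identical(length(b) + length(r), length(s))     # no gap, no overlap
  expect_identical(length(r), 9131L)                     # 1991-2015 incl. leaps
  expect_identical(max(seriesDates(b)) + 1, min(seriesDates(r)))
  expect_identical(slicePeriod(s, periodSpec("all", min(d), max(d)))@values,
                   s@values)                             # full-span identity
  expect_error(slicePeriod(s, periodSpec("out", "2020-01-01", "2020-12-31")),
               "empty")
})

test_that("seasonal subsets have leap-aware sizes and are disjoint", {
  for (year in c(1983, 1984)) {   # non-leap and leap
    d <- seq(as.Date(sprintf("%d-01-01", year)),
             as.Date(sprintf("%d-12-31", year)), by = "day")
    s <- DailySeries(seq_along(d), d)
    sizes <- vapply(c("winter", "spring", "summer", "autumn"),
                    function(x) length(seasonalSubset(s, x)), integer(1L))
    expect_identical(sum(sizes), length(d))
    expect_identical(sizes[["summer"]], 92L)
    expect_identical(sizes[["autumn"]], 91L)
    expect_identical(sizes[["spring"]], if (year == 1984) 92L else 92L)
    expect_identical(sizes[["winter"]],
                     if (year == 1984) 91L else 90L)     # Feb 29
  }
  # winter 1983 = Dec 1982 + Jan/Feb 1983 under the December rule
  d <- seq(as.Date("1982-01-01"), as.Date("1983-12-31"), by = "day")
  s <- DailySeries(seq_along(d), d)
  w <- seasonalSubset(s, "winter")
  wd <- seriesDates(w)[seasonYear(seriesDates(w)) == 1983]
  expect_identical(length(wd), 90L)
  expect_identical(min(wd), as.Date("1982-12-01"))
  expect_identical(max(wd), as.Date("1983-02-28"))
  expect_error(seasonalSubset(s, "monsoon"), "unknown season")
})

test_that("mean SST averages unmasked days only", {
  d <- datesFrom("2000-01-01", 4)
  expect_equal(meanSST(DailySeries(rep(15, 4), d)), 15)
  expect_equal(meanSST(DailySeries(c(10, 20, NA, NA), d)), 15)
  expect_error(meanSST(DailySeries(rep(NA_real_, 4), d)), "all-masked")
  # sinusoid over whole years averages to its offset
  s <- sinusoidSeries("1982-01-01", "1991-12-31", mu = 15, A = 4)
  expect_equal(meanSST(s), 15, tolerance = 1e-3)
})

test_that("grid writer/reader round-trips values, masks and layout", {
  d <- datesFrom("2000-03-01", 10)
  mk <- function(lon, lat, v) DailySeries(v, d, lon = lon, lat = lat)
  vals <- lapply(1:9, function(i) rnorm(10, 15))
  vals[[5]][c(2, 7)] <- NA                       # masked days
  vals[[9]][] <- NA                              # fully masked cell
  series <- mapply(mk, rep(c(-9, -8.75, -8.5), 3),
                   rep(c(43, 43.25, 43.5), each = 3), vals)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSSTGrid(series, path)
  g <- readSSTGrid(path)
  expect_identical(length(gridSites(g)), 9L)
  for (i in 1:9) {
    s2 <- gridSeries(g, siteId(series[[i]]))
    expect_identical(seriesMask(s2), seriesMask(series[[i]]))
    expect_equal(seriesValues(s2), seriesValues(series[[i]]),
                 tolerance = 1e-6)
  }
  # bbox restriction
  g2 <- readSSTGrid(path, bbox = list(lonMin = -9.1, lonMax = -8.6,
                                      latMin = 42, latMax = 44))
  expect_identical(length(gridSites(g2)), 6L)   # two lon columns x three lats
  expect_error(writeSSTGrid(list(), withr::local_tempfile()), "empty")
})

test_that("grid reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,site_id,lon,lat,sst",
               "2000-01-01,a,-9,43,15", "2000-01-03,a,-9,43,15"), path)
  expect_error(readSSTGrid(path), "cadence")
  writeLines(c("date,site_id,lon,sst", "2000-01-01,a,-9,15"), path)
  expect_error(readSSTGrid(path), "format error")
  writeLines(c("date,site_id,lon,lat,sst",
               "2000-01-01,a,-9,43,15", "2000-01-02,a,-9,43,15",
               "2000-01-01,b,-8,43,15"), path)
  expect_error(readSSTGrid(path), "layout")
})

test_that("DailySeries validity catches broken inputs", {
  d <- datesFrom("2000-01-01", 3)
  expect_error(DailySeries(1:2, d), "equal length")
  expect_error(DailySeries(c(1, Inf, 3), d), "finite")
  expect_error(DailySeries(1:3, rev(d)), "increasing")
})
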