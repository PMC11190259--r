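# Independent brute-force oracles. These deliberately re-derive each
# quantity with the plainest possible code path, sharing nothing with the
# package implementation beyond the input data.

datesFrom <- function(start, n) seq(as.Date(start), by = "day", length.out = n)

sinusoidSeries <- function(start = "1982-01-01", end = "2015-12-31",
                           mu = 15, A = 4, noiseSd = 0, seed = 1) {
  d <- seq(as.Date(start), as.Date(end), by = "day")
  doy <- sstshift::cycleDayOfYear(d)
  set.seed(seed)
  v <- mu + A * sin(2 * pi * doy / 365.25) +
    if (noiseSd > 0) rnorm(length(d), 0, noiseSd) else 0
  DailySeries(v, d, lon = -8, lat = 43.5)
}

# --- events ---------------------------------------------------------------

# naive single-pass flag-run detector: one day at a time, no vectorization
oracleDetect <- function(series, clim, kind, minDuration = 5, maxGap = 2) {
  v <- seriesValues(series)
  d <- seriesDates(series)
  doy <- sstshift::adjustedDayOfYear(d)
  flag <- logical(length(v))
  for (i in seq_along(v)) {
    if (is.na(v[i])) next
    flag[i] <- if (kind == "MHW") v[i] > clim@upper[doy[i]]
               else v[i] < clim@lower[doy[i]]
  }
  runs <- list(); startRun <- NA
  for (i in seq_along(flag)) {
    if (flag[i] && is.na(startRun)) startRun <- i
    if ((!flag[i] || i == length(flag)) && !is.na(startRun)) {
      endRun <- if (flag[i]) i else i - 1
      if (endRun - startRun + 1 >= minDuration)
        runs[[length(runs) + 1]] <- c(startRun, endRun)
      startRun <- NA
    }
  }
  if (length(runs) == 0)
    return(data.frame(start = as.Date(character()), end = as.Date(character()),
                      duration = integer()))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= maxGap)
      merged[[length(merged)]] <- c(last[1], r[2])
    else merged[[length(merged) + 1]] <- r
  }
  do.call(rbind, lapply(merged, function(r)
    data.frame(start = d[r[1]], end = d[r[2]],
               duration = as.integer(r[2] - r[1] + 1))))
}

# naive pooled percentile climatology, no smoothing
oracleClimPools <- function(series, halfwidth = 5) {
  v <- seriesValues(series)
  doy <- sstshift::adjustedDayOfYear(seriesDates(series))
  out <- list()
  for (dd in setdiff(1:366, 60)) {
    win <- ((dd - 1 + (-halfwidth:halfwidth)) %% 366) + 1
    pool <- v[doy %in% win & !is.na(v)]
    out[[dd]] <- c(mean = mean(pool),
                   lower = unname(quantile(pool, 0.10)),
                   upper = unname(quantile(pool, 0.90)))
  }
  out
}

# --- variability ----------------------------------------------------------

oracleD <- function(p) {
  p <- p[!is.na(p)]
  s <- 0
  for (i in 1:(length(p) - 1)) s <- s + abs(log(p[i + 1] / p[i]))
  s / (length(p) - 1)
}

oracleCV <- function(v) {
  v <- v[!is.na(v)]
  m <- sum(v) / length(v)
  ss <- sum((v - m)^2) / (length(v) - 1)
  sqrt(ss) / m * 100
}

# --- hierarchical partitioning --------------------------------------------

# average of sequential gof gains over all K! orderings
oracleOrderingsI <- function(status, x, family = "binomial") {
  K <- ncol(x)
  perms <- permutationsOf(K)
  gof <- function(cols) sstshift::gofFit(status, x[, cols, drop = FALSE], family)
  I <- numeric(K)
  for (p in perms) {
    prev <- numeric(0)
    for (k in p) {
      I[k] <- I[k] + gof(c(prev, k)) - gof(prev)
      prev <- c(prev, k)
    }
  }
  I / length(perms)
}

permutationsOf <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permutationsOf(n - 1)) for (pos in 0:(n - 1))
    out[[length(out) + 1]] <- append(p, n, after = pos)
  out
}

# naive O(n^3) complete-linkage agglomeration returning cophenetic distances
oracleCompleteLinkCophenetic <- function(mat) {
  n <- nrow(mat)
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestD <- Inf
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < bestD) { bestD <- dij; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestD; coph[b, a] <- bestD
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}
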