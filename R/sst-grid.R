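#' Construct an SSTGrid from daily series
#'
#' Assembles per-site [DailySeries-class] objects sharing one contiguous
#' daily span into a [SSTGrid-class] (a `SummarizedExperiment` with sites as
#' rows and days as columns).
#'
#' @param series list of [DailySeries-class], all with identical dates.
#' @return a [SSTGrid-class].
#' @export
SSTGrid <- function(series) {
  if (length(series) == 0L) stop("empty series collection")
  dates <- seriesDates(series[[1L]])
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("series must be contiguous at daily step")
  mat <- do.call(rbind, lapply(series, function(s) {
    if (!identical(as.integer(seriesDates(s)), as.integer(dates)))
      stop("all series must share one date axis (non-rectangular site set)")
    seriesValues(s)
  }))
  ids <- vapply(series, siteId, character(1L))
  rownames(mat) <- ids
  colnames(mat) <- format(dates)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(sst = mat),
    rowData = S4Vectors::DataFrame(
      site_id = ids,
      lon = vapply(series, longitude, numeric(1L)),
      lat = vapply(series, latitude, numeric(1L))),
    colData = S4Vectors::DataFrame(date = dates))
  new("SSTGrid", se)
}

#' Extract one site's DailySeries from a grid
#'
#' @param grid a [SSTGrid-class].
#' @param site site id (character) or row index.
#' @return a [DailySeries-class].
#' @export
gridSeries <- function(grid, site) {
  rd <- SummarizedExperiment::rowData(grid)
  i <- if (is.character(site)) match(site, rd$site_id) else as.integer(site)
  if (is.na(i) || i < 1L || i > nrow(grid)) stop("unknown site: ", site)
  DailySeries(SummarizedExperiment::assay(grid, "sst")[i, ],
              SummarizedExperiment::colData(grid)$date,
              rd$site_id[i], rd$lon[i], rd$lat[i])
}

#' @rdname gridSeries
#' @export
gridSites <- function(grid) SummarizedExperiment::rowData(grid)$site_id

#' Read / write a gridded daily SST file
#'
#' The on-disk format is a plain-text long-format CSV with columns
#' `date,site_id,lon,lat,sst` (empty `sst` = masked day), one row per cell
#' and day — a text stand-in for the CF `(time, lat, lon)` convention of the
#' gridded product, chosen so fixtures stay human-readable and portable.
#' `readSSTGrid` checks that the cells form a rectangular site set over a
#' single contiguous daily time axis.
#'
#' @param path file path.
#' @param bbox optional named list/vector with `lonMin`, `lonMax`, `latMin`,
#'   `latMax`; only cells inside the box are read.
#' @return `readSSTGrid`: a [SSTGrid-class]; `writeSSTGrid`: the path,
#'   invisibly.
#' @export
readSSTGrid <- function(path, bbox = NULL) {
  dt <- data.table::fread(path, colClasses = list(character = "site_id"))
  need <- c("date", "site_id", "lon", "lat", "sst")
  if (!all(need %in% names(dt)))
    stop("grid file must have columns ", paste(need, collapse = ","),
         " (format error)")
  dt$date <- as.Date(dt$date)
  if (anyNA(dt$date)) stop("unparseable time axis (format error)")
  if (!is.null(bbox)) {
    bbox <- as.list(bbox)
    dt <- dt[dt$lon >= bbox$lonMin & dt$lon <= bbox$lonMax &
             dt$lat >= bbox$latMin & dt$lat <= bbox$latMax, ]
    if (nrow(dt) == 0L) stop("no cells inside bbox")
  }
  dates <- sort(unique(dt$date))
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("non-daily cadence in time axis (cadence error)")
  ids <- unique(dt$site_id)
  series <- lapply(ids, function(id) {
    sub <- dt[dt$site_id == id, ]
    if (nrow(sub) != length(dates))
      stop("site ", id, " does not cover the full time axis (layout error)")
    sub <- sub[order(sub$date), ]
    DailySeries(sub$sst, sub$date, id, sub$lon[1L], sub$lat[1L])
  })
  SSTGrid(series)
}

#' @rdname readSSTGrid
#' @param grid a [SSTGrid-class] (or list of [DailySeries-class]).
#' @export
writeSSTGrid <- function(grid, path) {
  if (is.list(grid)) grid <- SSTGrid(grid)
  rd <- SummarizedExperiment::rowData(grid)
  dates <- SummarizedExperiment::colData(grid)$date
  mat <- SummarizedExperiment::assay(grid, "sst")
  dt <- data.table::data.table(
    date = rep(format(dates), each = nrow(mat)),
    site_id = rep(rd$site_id, times = ncol(mat)),
    lon = rep(rd$lon, times = ncol(mat)),
    lat = rep(rd$lat, times = ncol(mat)),
    sst = as.vector(mat))
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}
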