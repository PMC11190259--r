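#' Persistence / extirpation coding of a population
#'
#' A population observed in the baseline survey and absent at resurvey is an
#' extirpation (0); one observed in both, or only at resurvey, persisted (1);
#' one never observed yields no record (`NA`). The `override` flag forces 0
#' regardless — it encodes the special case of a species reduced to remnant
#' wave-sheltered stands that the surveys treat as functionally extirpated,
#' and is supplied as a data column, never inferred.
#'
#' @param baseline,resurvey logical (or 0/1) presence in each period.
#' @param override logical; force status 0.
#' @return integer 0/1, or `NA` for never-observed.
#' @examples
#' codeStatus(TRUE, TRUE)    # 1
#' codeStatus(TRUE, FALSE)   # 0
#' codeStatus(TRUE, TRUE, override = TRUE)  # 0
#' @export
codeStatus <- function(baseline, resurvey, override = FALSE) {
  stopifnot(length(baseline) == length(resurvey))
  if (length(override) == 1L) override <- rep(override, length(baseline))
  b <- as.logical(baseline); r <- as.logical(resurvey)
  out <- ifelse(!b & !r, NA_integer_, ifelse(r, 1L, 0L))
  out[as.logical(override) & !is.na(out)] <- 0L
  out
}

#' Read species occurrence records
#'
#' Expects a CSV with columns `species`, `site_id` (or `lon`/`lat`),
#' `presence_baseline`, `presence_resurvey` and optionally `override_zero`.
#' Applies [codeStatus()]; never-observed rows are dropped.
#'
#' @param path CSV path.
#' @return data.frame with columns `species`, `site_id`, `status` (plus
#'   `lon`, `lat` when present in the file).
#' @export
readSpeciesRecords <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "presence_baseline", "presence_resurvey")
  if (!all(need %in% names(df)))
    stop("species records need columns ", paste(need, collapse = ","))
  if (!"site_id" %in% names(df)) {
    if (!all(c("lon", "lat") %in% names(df)))
      stop("species records need site_id or lon/lat")
    df$site_id <- sprintf("%g_%g", df$lon, df$lat)
  }
  ov <- if ("override_zero" %in% names(df)) as.logical(df$override_zero) else FALSE
  df$status <- codeStatus(df$presence_baseline, df$presence_resurvey, ov)
  df <- df[!is.na(df$status), ]
  if (anyDuplicated(df[, c("species", "site_id")]))
    stop("at most one record per (species, site)")
  keep <- intersect(c("species", "site_id", "lon", "lat", "status"), names(df))
  df[, keep]
}

#' Species upper thermal limits
#'
#' Registry of lethal-maximum thermal thresholds (degrees C) from
#' physiological experiments, using the most conservative published value
#' per species.
#'
#' @return named numeric vector, degrees C.
#' @export
thermalThresholds <- function() {
  c("F. serratus" = 25, "H. elongata" = 18, "L. ochroleuca" = 23,
    "S. polyschides" = 24, "L. hyperborea" = 20, "F. vesiculosus" = 28)
}

#' @rdname thermalThresholds
#' @param species character vector of species names.
#' @export
thermalThreshold <- function(species) {
  reg <- thermalThresholds()
  miss <- setdiff(species, names(reg))
  if (length(miss)) stop("unknown species name(s): ", paste(miss, collapse = ", "))
  reg[species]
}
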