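# End-to-end orchestration: simulate -> events/metrics -> anomalies ->
# screen -> hierarchical partitioning -> ordination, with a JSON config, a
# master seed fanned out per stage, and TSV/JSON outputs.

#' Default pipeline configuration
#'
#' A complete demonstration configuration: a 12-site synthetic west-east
#' grid over 1982-2015 and two synthetic species whose extirpation risk
#' loads on the autumn mean-SST anomaly and the seasonality anomaly (the
#' gradient the generator builds into the eastern sites).
#'
#' @return nested list; see [validateConfig()] for the schema.
#' @export
defaultConfig <- function() {
  list(
    simulation = list(nSites = 12L, start = "1982-01-01", end = "2015-12-31",
                      trend = 0.2, rho = 0.9, sigma = 0.4),
    periods = list(baseline = c("1982-01-01", "1990-12-31"),
                   resurvey = c("1991-01-01", "2015-12-31")),
    species = list(
      list(name = "synthetic sp. A",
           coef = list(mean_sst.autumn = -2.5, seasonality = -2),
           intercept = 0.5),
      list(name = "synthetic sp. B",
           coef = list(mean_sst.autumn = -3),
           intercept = 0)),
    events = list(minDuration = 5L, maxGap = 2L, windowHalfwidth = 5L,
                  smooth = 31L),
    screening = list(rCut = 0.70, pCut = 0.001, vifThreshold = 10),
    hp = list(reps = 100L, level = 0.95, quantileKeep = 0.75),
    nmds = list(starts = 100L, perms = 999L),
    dOffset = 0
  )
}

#' Validate a pipeline configuration
#'
#' Fills missing sections from [defaultConfig()] (noting each default
#' applied) and checks ranges: correlation cut in (0, 1\], p cut in (0, 1),
#' non-overlapping ordered periods, positive replication counts.
#'
#' @param config nested list, or path to a JSON file.
#' @return the completed config, with a `notes` attribute listing applied
#'   defaults; stops with a schema error otherwise.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  def <- defaultConfig()
  notes <- character()
  for (sec in names(def)) {
    if (is.null(config[[sec]])) {
      config[[sec]] <- def[[sec]]
      notes <- c(notes, sprintf("section '%s' defaulted", sec))
    } else if (is.list(def[[sec]]) && !is.null(names(def[[sec]]))) {
      for (key in names(def[[sec]])) if (is.null(config[[sec]][[key]])) {
        config[[sec]][[key]] <- def[[sec]][[key]]
        notes <- c(notes, sprintf("'%s.%s' defaulted", sec, key))
      }
    }
  }
  sc <- config$screening
  if (sc$rCut <= 0 || sc$rCut > 1) stop("rCut must lie in (0, 1] (range error)")
  if (sc$pCut <= 0 || sc$pCut >= 1) stop("pCut must lie in (0, 1) (range error)")
  if (config$hp$reps < 1L) stop("hp reps must be >= 1 (range error)")
  b <- as.Date(unlist(config$periods$baseline))
  r <- as.Date(unlist(config$periods$resurvey))
  if (anyNA(b) || anyNA(r)) stop("unparseable period dates (schema error)")
  if (b[2L] >= r[1L]) stop("periods must be ordered and non-overlapping")
  attr(config, "notes") <- notes
  config
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Simulates (or loads) the grid and species records, builds the anomaly
#' table, screens variables per species, runs the iterative hierarchical
#' partitioning with its randomization test, clusters species by their
#' I-profiles, ordinates site-by-species records by NMDS with vector
#' fitting, and writes every table plus a manifest to `outDir`. All
#' randomized stages consume seeds fanned out deterministically from
#' `seed`.
#'
#' @param config configuration (list or JSON path), see [validateConfig()].
#' @param outDir output directory (created).
#' @param seed master seed.
#' @param grid optional pre-built [SSTGrid-class] (skips simulation).
#' @param speciesStatus optional data.frame of species records (skips the
#'   species simulation); columns `species`, `site_id`, `status`.
#' @return invisibly, a list with `table`, `screen`, `hp`, `dendrogram`,
#'   `ordination`, `manifest`.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = tempfile("run"),
                        seed = 1L, grid = NULL, speciesStatus = NULL) {
  config <- validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(sim = seed, species = seed + 1000L, hp = seed + 2000L,
                nmds = seed + 3000L, perm = seed + 4000L)
  if (is.null(grid)) {
    simArgs <- config$simulation
    simArgs$seed <- seeds$sim
    grid <- simulateGrid(do.call(simulationConfig, simArgs))
  }
  baseline <- periodSpec("baseline", config$periods$baseline[[1L]],
                         config$periods$baseline[[2L]])
  resurvey <- periodSpec("resurvey", config$periods$resurvey[[1L]],
                         config$periods$resurvey[[2L]])
  ev <- config$events
  tab <- buildVariableTable(grid, baseline, resurvey,
                            thresholds = NULL,
                            minDuration = ev$minDuration, maxGap = ev$maxGap,
                            windowHalfwidth = ev$windowHalfwidth,
                            smooth = ev$smooth, dOffset = config$dOffset)
  writeTSV(tab, file.path(outDir, "variable_table.tsv"))
  if (is.null(speciesStatus)) {
    speciesStatus <- do.call(rbind, lapply(seq_along(config$species),
      function(i) {
        sp <- config$species[[i]]
        simulateSpecies(tab, unlist(sp$coef), sp$intercept %||% 0,
                        species = sp$name, seed = seeds$species + i)
      }))
  }
  writeTSV(speciesStatus, file.path(outDir, "species_status.tsv"))
  spNames <- unique(speciesStatus$species)
  screenOut <- list(); hpOut <- list(); profiles <- list()
  for (i in seq_along(spNames)) {
    sp <- spNames[i]
    st <- speciesStatus[speciesStatus$species == sp, ]
    scr <- screenVariables(tab, st, config$screening$rCut,
                           config$screening$pCut,
                           config$screening$vifThreshold)
    ip <- iteratePartition(st, tab, scr$retained,
                           reps = config$hp$reps, level = config$hp$level,
                           seed = seeds$hp + 100L * i,
                           quantileKeep = config$hp$quantileKeep)
    screenOut[[sp]] <- scr
    hpOut[[sp]] <- ip
    profiles[[sp]] <- setNames(ip$final@table$I, ip$final@table$variable)
    writeTSV(ip$final@table,
             file.path(outDir, sprintf("hp_%s.tsv", gsub("[^A-Za-z0-9]+", "_", sp))))
  }
  dend <- if (length(profiles) >= 2L) speciesDendrogram(profiles) else NULL
  # ordination records: one row per site x species over the union of the
  # species' HP-selected (relevant) variables; falls back to the final-run
  # variables when that union is too small to ordinate
  unionVars <- unique(unlist(lapply(hpOut, function(h) h$relevant)))
  if (length(unionVars) < 3L)
    unionVars <- unique(unlist(lapply(hpOut, function(h)
      h$final@table$variable)))
  recRows <- merge(speciesStatus, tab, by = "site_id")
  recMat <- as.matrix(recRows[, unionVars, drop = FALSE])
  ok <- complete.cases(recMat)
  ord <- NULL
  if (sum(ok) >= 4L) {
    ord <- runNMDS(recMat[ok, , drop = FALSE],
                   nStarts = config$nmds$starts, seed = seeds$nmds)
    ord <- fitVectors(ord, recMat[ok, , drop = FALSE],
                      nPerm = config$nmds$perms, seed = seeds$perm)
    sep <- groupSeparation(ord, recRows$status[ok])
    scoresDf <- data.frame(species = recRows$species[ok],
                           site_id = recRows$site_id[ok],
                           status = recRows$status[ok], ord@scores)
    writeTSV(scoresDf, file.path(outDir, "nmds_scores.tsv"))
    writeTSV(ord@vectors, file.path(outDir, "nmds_vectors.tsv"))
  } else sep <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("sstshift")),
    seed = seed, stage_seeds = seeds,
    config_hash = digestConfig(config),
    n_sites = length(gridSites(grid)),
    species = spNames,
    relevant = lapply(hpOut, function(h) h$relevant),
    stress = if (!is.null(ord)) ord@stress else NA,
    axis1_effect = if (!is.null(sep)) sep$effect else NA)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(table = tab, screen = screenOut, hp = hpOut,
                 dendrogram = dend, ordination = ord, separation = sep,
                 manifest = manifest, outDir = outDir))
}

digestConfig <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # dependency-free FNV-1a hash, enough to fingerprint a config
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
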