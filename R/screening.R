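# Variable screening: global Pearson filter on high positive correlations,
# then VIF-guided and per-species AIC-guided exclusion among the correlated
# extreme-event variables.

pearsonP <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t), df = n - 2)
}

flaggedPairs <- function(mat, rCut, pCut) {
  n <- nrow(mat)
  r <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  p <- pearsonP(r, n)
  flag <- r >= rCut & p < pCut
  flag[lower.tri(flag, diag = TRUE)] <- FALSE
  flag[is.na(flag)] <- FALSE
  which(flag, arr.ind = TRUE)
}

#' Pearson correlation filter over all sites
#'
#' Flags variable pairs with r >= `rCut` and two-sided p < `pCut` (high
#' positive correlations, i.e. near-identical longitudinal patterns of
#' change), then greedily drops — one variable per iteration — the flagged
#' variable with the highest mean |r| to its flagged partners (registry-order
#' tie-break) until no flagged pair remains. Constant columns are excluded
#' from testing, retained, and flagged.
#'
#' @param table data.frame of variables (non-numeric / id columns ignored).
#' @param rCut,pCut thresholds; defaults r >= 0.70, p < 0.001.
#' @param vars optional character subset of columns to screen.
#' @return list with `retained` (character), `dropped` (data.frame with
#'   `variable` and `reason`), `constant` (character).
#' @export
correlationFilter <- function(table, rCut = 0.70, pCut = 0.001, vars = NULL) {
  tab <- as.data.frame(table)
  if (is.null(vars))
    vars <- setdiff(colnames(tab)[vapply(tab, is.numeric, logical(1L))],
                    c("lon", "lat", "status"))
  mat <- as.matrix(tab[, vars, drop = FALSE])
  if (nrow(mat) < 3L) stop("need at least 3 rows to test correlations")
  sds <- apply(mat, 2L, sd, na.rm = TRUE)
  constant <- vars[!is.finite(sds) | sds < .Machine$double.eps]
  active <- setdiff(vars, constant)
  dropped <- character()
  repeat {
    m <- mat[, active, drop = FALSE]
    pairs <- flaggedPairs(m, rCut, pCut)
    if (nrow(pairs) == 0L) break
    r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
    involved <- sort(unique(c(pairs[, 1L], pairs[, 2L])))
    meanAbs <- vapply(involved, function(j) {
      partners <- c(pairs[pairs[, 1L] == j, 2L], pairs[pairs[, 2L] == j, 1L])
      mean(abs(r[j, partners]))
    }, numeric(1L))
    worst <- involved[which.max(meanAbs)]   # which.max: first max = registry order
    dropped <- c(dropped, active[worst])
    active <- active[-worst]
  }
  list(retained = c(active, constant),
       dropped = if (length(dropped))
         data.frame(variable = dropped, reason = "pearson r>=cut")
       else data.frame(variable = character(), reason = character()),
       constant = constant)
}

#' Variance inflation factors and iterative max-VIF dropping
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing column j on the remaining
#' columns. `vifRank` returns the VIFs in decreasing order; `vifPrune`
#' iteratively drops the highest-VIF column while the maximum exceeds
#' `threshold` (perfect collinearity gives infinite VIF and is dropped
#' first).
#'
#' @param table data.frame or matrix of numeric columns.
#' @param vars optional character subset of columns.
#' @return `vifRank`: named numeric vector, decreasing.
#' @export
vifRank <- function(table, vars = NULL) {
  mat <- as.matrix(as.data.frame(table)[, vars %||% colnames(as.data.frame(table)),
                                        drop = FALSE])
  mat <- mat[complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  if (k < 2L) stop("VIF needs at least 2 columns")
  if (nrow(mat) <= k) stop("VIF needs more rows than columns")
  v <- vapply(seq_len(k), function(j) {
    fit <- lm(mat[, j] ~ mat[, -j, drop = FALSE])
    r2 <- 1 - sum(resid(fit)^2) / sum((mat[, j] - mean(mat[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  names(v) <- colnames(mat)
  sort(v, decreasing = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname vifRank
#' @param threshold stop once max VIF <= this (default 10).
#' @return `vifPrune`: list with `retained` and `dropped` character vectors.
#' @export
vifPrune <- function(table, vars = NULL, threshold = 10) {
  tab <- as.data.frame(table)
  active <- vars %||% colnames(tab)
  dropped <- character()
  while (length(active) >= 2L) {
    v <- vifRank(tab, active)
    if (v[1L] <= threshold) break
    dropped <- c(dropped, names(v)[1L])
    active <- setdiff(active, names(v)[1L])
  }
  list(retained = active, dropped = dropped)
}

ridgeLogistic <- function(x, y, lambda = 1e-6, maxit = 100L) {
  X <- cbind(1, as.matrix(x))
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - p) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  p <- plogis(drop(X %*% beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  list(beta = beta, logLik = ll)
}

binomialAIC <- function(x, y) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(cbind(1, x), y, family = binomial())),
    error = function(e) NULL)
  separated <- is.null(fit) || !fit$converged ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  if (separated) {
    rf <- ridgeLogistic(x, y)
    return(list(aic = -2 * rf$logLik + 2 * 2, ridge = TRUE))
  }
  list(aic = fit$aic, ridge = FALSE)
}

#' AIC-guided exclusion among correlated pairs, on species cells only
#'
#' Recomputes Pearson correlations on the cells holding data for the
#' species; for each flagged pair (r >= `rCut`, p < `pCut`) fits the two
#' single-predictor binomial regressions of status on each variable and
#' drops the one with the larger AIC (first-by-registry-order tie-break).
#' Quasi-separated fits fall back to a lightly ridge-penalized likelihood
#' and are flagged.
#'
#' @param table variable table with `site_id`.
#' @param status data.frame with `site_id` and `status` for one species.
#' @param vars character subset of columns to test (typically the retained
#'   event variables).
#' @param rCut,pCut Pearson thresholds.
#' @return list with `retained`, `dropped` (data.frame: `variable`,
#'   `competitor`, `aic`, `aic_competitor`, `ridge`).
#' @export
aicPairSelect <- function(table, status, vars, rCut = 0.70, pCut = 0.001) {
  df <- merge(status[, c("site_id", "status")], as.data.frame(table),
              by = "site_id")
  y <- df$status
  active <- vars
  log <- list()
  repeat {
    mat <- as.matrix(df[, active, drop = FALSE])
    pairs <- flaggedPairs(mat, rCut, pCut)
    if (nrow(pairs) == 0L) break
    i <- pairs[1L, 1L]; j <- pairs[1L, 2L]
    a <- binomialAIC(mat[, i], y)
    b <- binomialAIC(mat[, j], y)
    dropIdx <- if (b$aic > a$aic) j else if (a$aic > b$aic) i else j
    keepIdx <- if (dropIdx == i) j else i
    log[[length(log) + 1L]] <- data.frame(
      variable = active[dropIdx], competitor = active[keepIdx],
      aic = if (dropIdx == i) a$aic else b$aic,
      aic_competitor = if (dropIdx == i) b$aic else a$aic,
      ridge = a$ridge || b$ridge)
    active <- active[-dropIdx]
  }
  list(retained = active,
       dropped = if (length(log)) do.call(rbind, log)
       else data.frame(variable = character(), competitor = character(),
                       aic = numeric(), aic_competitor = numeric(),
                       ridge = logical()))
}

#' Full screening pipeline for one species
#'
#' Fixed order: global Pearson correlation filter over all variables, then
#' iterative max-VIF pruning restricted to the retained extreme-event
#' variables, then per-species AIC pair selection among the event variables
#' on the species' cells.
#'
#' @param table a [buildVariableTable()] result.
#' @param status per-species status data.frame (`site_id`, `status`).
#' @param rCut,pCut Pearson thresholds.
#' @param vifThreshold VIF stopping threshold.
#' @return list with `retained` (character), and the per-stage reports
#'   `correlation`, `vif`, `aic`.
#' @export
screenVariables <- function(table, status, rCut = 0.70, pCut = 0.001,
                            vifThreshold = 10) {
  registry <- attr(table, "registry")
  stage1 <- correlationFilter(table, rCut, pCut)
  eventVars <- intersect(stage1$retained,
                         registry$variable[registry$family %in% c("mhw", "mcs")])
  stage2 <- if (length(eventVars) >= 2L) {
    evMat <- as.data.frame(table)[, eventVars, drop = FALSE]
    if (sum(complete.cases(evMat)) > length(eventVars))
      vifPrune(evMat, eventVars, vifThreshold)
    else list(retained = eventVars, dropped = character())
  } else list(retained = eventVars, dropped = character())
  stage3 <- if (length(stage2$retained) >= 2L)
    aicPairSelect(table, status, stage2$retained, rCut, pCut)
  else list(retained = stage2$retained,
            dropped = data.frame(variable = character()))
  retained <- union(setdiff(stage1$retained, eventVars), stage3$retained)
  # keep registry order
  retained <- registry$variable[registry$variable %in% retained]
  list(retained = retained, correlation = stage1, vif = stage2, aic = stage3)
}
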