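# Hierarchical partitioning of goodness-of-fit over all predictor
# hierarchies (the Shapley decomposition of the fit), with a randomization
# significance test, the iterative <=12-variable protocol, and the
# species-similarity dendrogram.

#' Goodness-of-fit of a status model on a variable subset
#'
#' Fits an intercept-plus-subset regression of the 0/1 status and returns
#' the improvement in deviance over the intercept-only model (twice the
#' log-likelihood gain). The empty subset returns 0 exactly. The
#' `"gaussian"` family uses squared-error deviance (explained sum of
#' squares), which admits closed-form checks. Quasi-separated binomial fits
#' fall back to a lightly ridge-penalized likelihood.
#'
#' @param status 0/1 response vector.
#' @param x matrix/data.frame of predictors (may have zero columns).
#' @param family `"binomial"` or `"gaussian"`.
#' @return numeric scalar >= 0 (up to numerical noise).
#' @export
gofFit <- function(status, x, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  y <- as.numeric(status)
  x <- as.matrix(x)
  if (ncol(x) == 0L) return(0)
  if (family == "gaussian") {
    fit <- lm.fit(cbind(1, x), y)
    return(sum((y - mean(y))^2) - sum(fit$residuals^2))
  }
  logisticDevianceGain(y, x)
}

# Newton/IRLS logistic deviance gain over the intercept-only model.
# Lean replacement for glm.fit on the 2^K-subset hot path (thousands of tiny
# fits per partition); identical MLE, with step-halving and a ridge fallback
# for (quasi-)separated data.
logisticDevianceGain <- function(y, x) {
  X <- cbind(1, x)
  n <- length(y)
  p0 <- mean(y)
  if (p0 <= 0 || p0 >= 1) return(0)
  nullDev <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  beta <- c(qlogis(p0), numeric(ncol(X) - 1L))
  eta <- rep(qlogis(p0), n)
  dev <- nullDev
  for (it in 1:25) {
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w)
    g <- crossprod(X, y - mu)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {            # singular Hessian: separation or collinearity
      rf <- ridgeLogistic(x, y)
      ll0 <- -nullDev / 2
      return(max(0, 2 * (rf$logLik - ll0)))
    }
    newBeta <- beta + step
    newEta <- drop(X %*% newBeta)
    mu2 <- pmin(pmax(plogis(newEta), 1e-12), 1 - 1e-12)
    newDev <- -2 * sum(y * log(mu2) + (1 - y) * log(1 - mu2))
    half <- 0L
    while (newDev > dev + 1e-10 && half < 10L) {   # safeguard: step halving
      step <- step / 2
      newBeta <- beta + step
      newEta <- drop(X %*% newBeta)
      mu2 <- pmin(pmax(plogis(newEta), 1e-12), 1 - 1e-12)
      newDev <- -2 * sum(y * log(mu2) + (1 - y) * log(1 - mu2))
      half <- half + 1L
    }
    done <- abs(dev - newDev) < 1e-9
    beta <- newBeta; eta <- newEta; dev <- newDev
    if (done) break
  }
  max(0, nullDev - dev)
}

#' Hierarchical partitioning of goodness-of-fit
#'
#' Computes the goodness-of-fit of every subset of the K <= 12 predictors
#' and decomposes the full-model fit into per-variable independent
#' contributions by Shapley weighting:
#' I_k = sum over subsets S not containing k of s!(K-1-s)!/K! times
#' \[gof(S + k) - gof(S)\]. The joint contribution is
#' J_k = gof(k alone) - I_k. By construction sum(I) equals the full-model
#' goodness-of-fit.
#'
#' @param status 0/1 response.
#' @param table matrix/data.frame of predictors, K <= 12 columns.
#' @param family goodness-of-fit family (see [gofFit()]).
#' @return an [HPResult-class].
#' @export
hierPart <- function(status, table, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  x <- as.matrix(table)
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(x)))
  keep <- complete.cases(x) & !is.na(status)
  x <- x[keep, , drop = FALSE]
  y <- as.numeric(status)[keep]
  K <- ncol(x)
  if (K < 1L) stop("at least one predictor required")
  if (K > 12L)
    stop("more than 12 variables per partition; use iteratePartition()")
  gofs <- subsetGofs(y, x, family)
  I <- shapleyI(gofs, K)
  single <- gofs[1L + bitwShiftL(1L, seq_len(K) - 1L)]
  J <- single - I
  gofFull <- gofs[length(gofs)]
  tab <- data.frame(variable = vars, I = I, J = J,
                    I_percent = if (sum(I) != 0) 100 * I / sum(I) else NA_real_,
                    stringsAsFactors = FALSE)
  new("HPResult", table = tab, gofFull = gofFull, measure = family,
      n = length(y), k = K)
}

# gof of all 2^K subsets, indexed by bitmask + 1; the binomial family runs
# through the compiled Newton sweep, everything else through gofFit()
subsetGofs <- function(y, x, family) {
  if (family == "binomial" && !anyNA(x) && !anyNA(y))
    return(subset_gofs_cpp(x, y))
  K <- ncol(x)
  vapply(0:(2^K - 1L), function(mask) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:(K - 1L))) != 0L)
    gofFit(y, x[, cols, drop = FALSE], family)
  }, numeric(1L))
}

shapleyI <- function(gofs, K) {
  wts <- vapply(0:(K - 1L), function(s)
    factorial(s) * factorial(K - 1L - s) / factorial(K), numeric(1L))
  sizes <- vapply(0:(2^K - 1L), function(mask) sum(bitwAnd(
    mask, bitwShiftL(1L, 0:(K - 1L))) != 0L), integer(1L))
  I <- numeric(K)
  for (k in seq_len(K)) {
    bit <- bitwShiftL(1L, k - 1L)
    without <- which(bitwAnd(0:(2^K - 1L), bit) == 0L)
    s <- sizes[without]
    I[k] <- sum(wts[s + 1L] * (gofs[without + bit] - gofs[without]))
  }
  I
}

#' @describeIn HPResult-class display the partitioning table
#' @param object an `HPResult`
#' @export
setMethod("show", "HPResult", function(object) {
  cat(sprintf("HPResult (%s): n = %d, K = %d, full-model gof = %.4f\n",
              object@measure, object@n, object@k, object@gofFull))
  print(object@table, row.names = FALSE, digits = 4)
})

#' @rdname HPResult-class
#' @param x an `HPResult`
#' @export
hpTable <- function(x) x@table

#' Randomization significance test for independent contributions
#'
#' For each repetition the rows of the predictor table are jointly permuted
#' against the status vector (preserving predictor inter-correlations) and
#' all independent contributions recomputed. Z_k is the observed I_k minus
#' the randomized mean, over the randomized standard deviation; a variable
#' is significant when its observed I exceeds the upper `level` percentile
#' of its randomized distribution. Deterministic given `seed`.
#'
#' @param status 0/1 response.
#' @param table predictors (K <= 12).
#' @param reps number of repetitions (default 100).
#' @param level confidence level for the upper limit (default 0.95).
#' @param seed RNG seed.
#' @param family goodness-of-fit family.
#' @return an [HPResult-class] whose table gains `Z` and `significant`.
#' @export
randomizationTest <- function(status, table, reps = 100L, level = 0.95,
                              seed = 1L, family = "binomial") {
  obs <- hierPart(status, table, family)
  x <- as.matrix(table)
  keep <- complete.cases(x) & !is.na(status)
  x <- x[keep, , drop = FALSE]
  y <- as.numeric(status)[keep]
  K <- ncol(x)
  randI <- withSeed(seed, {
    matrix(vapply(seq_len(reps), function(r) {
      xp <- x[sample.int(nrow(x)), , drop = FALSE]
      hierPart(y, xp, family)@table$I
    }, numeric(K)), nrow = reps, ncol = K, byrow = TRUE)
  })
  mu <- colMeans(randI)
  sdev <- apply(randI, 2L, sd)
  Z <- ifelse(sdev > 0, (obs@table$I - mu) / sdev, NA_real_)
  upper <- apply(randI, 2L, quantile, probs = level, names = FALSE)
  obs@table$Z <- Z
  obs@table$significant <- obs@table$I > upper
  obs
}

chunkByMarginalGof <- function(status, tab, vars, family, chunk = 12L) {
  gofs <- vapply(vars, function(v)
    gofFit(status[!is.na(tab[[v]]) & !is.na(status)],
           tab[[v]][!is.na(tab[[v]]) & !is.na(status)], family),
    numeric(1L))
  ord <- vars[order(-gofs)]
  split(ord, ceiling(seq_along(ord) / chunk))
}

#' Iterative hierarchical-partitioning protocol
#'
#' Stage 1: for each extreme-event kind (MHW, MCS), run a randomized
#' partition on that kind's seasonal variables (chunked to <= 12 by
#' descending marginal goodness-of-fit when more survive screening) and keep
#' the variables that are statistically significant and have I at or above
#' the 0.75 quantile of I within their run. Stage 2: run the final
#' randomized partition on the kept event variables together with all
#' non-event variables; a pool still exceeding 12 is partitioned in chunks
#' and the variables with the highest independent contributions (up to 12)
#' proceed, flagged in the report. Variables with I above the median of the
#' final run are reported as "relevant".
#'
#' @param status per-species status data.frame (`site_id`, `status`) or 0/1
#'   vector aligned with `table` rows.
#' @param table a [buildVariableTable()] result (rows subset to the species'
#'   sites when `status` is a vector).
#' @param vars character: candidate variables (typically
#'   `screenVariables()$retained`).
#' @param reps,level,seed randomization-test controls.
#' @param quantileKeep stage-1 I-quantile (default 0.75).
#' @param family goodness-of-fit family.
#' @return list with `final` ([HPResult-class] with `relevant` column),
#'   `stage1` (per-kind [HPResult-class] list), `kept` (stage-1 survivors),
#'   `chunked` (logical flag), `relevant` (character).
#' @export
iteratePartition <- function(status, table, vars, reps = 100L, level = 0.95,
                             seed = 1L, quantileKeep = 0.75,
                             family = "binomial") {
  tab <- as.data.frame(table)
  if (is.data.frame(status)) {
    df <- merge(status[, c("site_id", "status")], tab, by = "site_id")
    y <- df$status
    tab <- df
  } else {
    y <- as.numeric(status)
  }
  registry <- attr(table, "registry")
  fam <- setNames(registry$family, registry$variable)
  scope <- setNames(registry$scope, registry$variable)
  seasonal <- function(v) scope[v] %in% c("winter", "spring", "summer", "autumn")
  stage1 <- list(); kept <- character(); runIdx <- 0L
  for (kind in c("mhw", "mcs")) {
    kv <- vars[fam[vars] == kind & seasonal(vars)]
    if (length(kv) == 0L) next
    chunks <- if (length(kv) > 12L)
      chunkByMarginalGof(y, tab, kv, family) else list(kv)
    for (ch in chunks) {
      runIdx <- runIdx + 1L
      hp <- randomizationTest(y, tab[, ch, drop = FALSE], reps, level,
                              seed + runIdx, family)
      t1 <- hp@table
      qI <- quantile(t1$I, quantileKeep, names = FALSE)
      kept <- c(kept, t1$variable[t1$significant & t1$I >= qI])
      stage1[[paste0(kind, ".", length(stage1) + 1L)]] <- hp
    }
  }
  finalVars <- c(kept, vars[!fam[vars] %in% c("mhw", "mcs")])
  finalVars <- registry$variable[registry$variable %in% finalVars]
  chunked <- length(finalVars) > 12L
  if (chunked) {
    # oversized final pool: partition in chunks and keep the variables with
    # the highest independent contributions, up to 12
    pooledI <- numeric(0)
    for (ch in chunkByMarginalGof(y, tab, finalVars, family)) {
      runIdx <- runIdx + 1L
      hp <- hierPart(y, tab[, ch, drop = FALSE], family)
      pooledI <- c(pooledI, setNames(hp@table$I, hp@table$variable))
    }
    finalVars <- names(sort(pooledI, decreasing = TRUE))[
      seq_len(min(12L, length(pooledI)))]
    finalVars <- registry$variable[registry$variable %in% finalVars]
  }
  if (length(finalVars) == 0L) stop("no variables reached the final partition")
  final <- randomizationTest(y, tab[, finalVars, drop = FALSE], reps, level,
                             seed + runIdx + 1L, family)
  medI <- median(final@table$I)
  final@table$relevant <- final@table$I > medI
  list(final = final, stage1 = stage1, kept = kept, chunked = chunked,
       relevant = final@table$variable[final@table$relevant])
}

#' Species-similarity dendrogram from independent-contribution profiles
#'
#' Agglomerative clustering (complete linkage, Euclidean distance) of
#' species over their final-run I-profiles on a shared variable axis;
#' variables missing for a species are filled with 0 (flagged via the
#' `filled` attribute).
#'
#' @param profiles species x variables numeric matrix of final I values, or
#'   a named list of named I vectors.
#' @return list with `tree` (an `hclust`), `matrix` (the heat-map-ready
#'   species x variables matrix).
#' @export
speciesDendrogram <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles) && !is.matrix(profiles)) {
    vars <- unique(unlist(lapply(profiles, names)))
    mat <- t(vapply(profiles, function(p) {
      out <- setNames(numeric(length(vars)), vars)
      out[names(p)] <- p
      out
    }, numeric(length(vars))))
  } else {
    mat <- as.matrix(profiles)
  }
  if (nrow(mat) < 2L) stop("need at least 2 species")
  tree <- hclust(dist(mat, method = "euclidean"), method = "complete")
  list(tree = tree, matrix = mat)
}
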