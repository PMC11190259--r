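# Two-dimensional non-metric multidimensional scaling of records in anomaly
# space, with environmental-vector fitting and a status-separation summary.

#' Two-dimensional NMDS of an anomaly matrix
#'
#' Columns are z-scored (the table mixes degrees C, percent and ratios, so
#' unscaled Euclidean distances would be dominated by large-unit variables),
#' Euclidean dissimilarities are computed, and Kruskal's stress-1 is
#' minimized by isotonic-regression NMDS over `nStarts` random starts
#' (vegan's engine); the best configuration is centred and rotated to
#' principal axes. Deterministic given `seed`.
#'
#' @param mat records x variables numeric matrix/data.frame.
#' @param k ordination dimension (2).
#' @param nStarts number of random starts (the "100 random iterations").
#' @param seed RNG seed.
#' @param scale z-score columns first?
#' @return an [OrdinationResult-class].
#' @export
runNMDS <- function(mat, k = 2L, nStarts = 100L, seed = 1L, scale = TRUE) {
  m <- as.matrix(mat)
  if (nrow(m) < 4L) stop("need at least 4 records")
  if (scale) {
    keep <- apply(m, 2L, sd, na.rm = TRUE) > .Machine$double.eps
    m <- apply(m[, keep, drop = FALSE], 2L, zscore)
  }
  d <- dist(m, method = "euclidean")
  fit <- withSeed(seed,
    vegan::metaMDS(d, k = k, try = nStarts, trymax = nStarts,
                   autotransform = FALSE, wascores = FALSE, trace = 0))
  sc <- vegan::scores(fit, display = "sites")
  sc <- scale(sc, center = TRUE, scale = FALSE)
  rownames(sc) <- rownames(m)
  colnames(sc) <- c("NMDS1", "NMDS2")
  new("OrdinationResult", scores = unclass(sc), stress = fit$stress,
      vectors = data.frame(), nStarts = as.integer(nStarts))
}

#' @describeIn OrdinationResult-class compact display
#' @param object an `OrdinationResult`
#' @export
setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d records, stress-1 = %.4f (%d starts)\n",
              nrow(object@scores), object@stress, object@nStarts))
  if (nrow(object@vectors))
    cat(sprintf("  %d fitted vectors\n", nrow(object@vectors)))
})

#' Fit environmental vectors onto an ordination
#'
#' For each variable, an OLS regression of the (centred) variable on the
#' two ordination axes gives the direction (normalized coefficient vector)
#' and r-squared; the p-value is (1 + number of permuted r2 >= observed) /
#' (nPerm + 1), permuting the variable across records. Zero-variance
#' variables are skipped with a flag.
#'
#' @param result an [OrdinationResult-class].
#' @param variables records x variables matrix/data.frame aligned with the
#'   ordination rows.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed.
#' @return the [OrdinationResult-class] with a filled `vectors` slot
#'   (`variable`, `dx`, `dy`, `r2`, `p`, `skipped`).
#' @export
fitVectors <- function(result, variables, nPerm = 999L, seed = 1L) {
  sc <- result@scores
  X <- cbind(1, sc)
  XtXinv <- solve(crossprod(X))
  hat <- X %*% XtXinv %*% t(X)
  vmat <- as.matrix(variables)
  r2of <- function(v) {
    vc <- v - mean(v)
    fitted <- hat %*% v
    1 - sum((v - fitted)^2) / sum(vc^2)
  }
  rows <- withSeed(seed, lapply(colnames(vmat), function(nm) {
    v <- vmat[, nm]
    if (anyNA(v) || sd(v) < .Machine$double.eps)
      return(data.frame(variable = nm, dx = NA_real_, dy = NA_real_,
                        r2 = NA_real_, p = NA_real_, skipped = TRUE))
    b <- drop(XtXinv %*% crossprod(X, v))[2:3]
    dir <- b / sqrt(sum(b^2))
    r2 <- r2of(v)
    exceed <- sum(vapply(seq_len(nPerm), function(i)
      r2of(v[sample.int(length(v))]) >= r2, logical(1L)))
    data.frame(variable = nm, dx = dir[1L], dy = dir[2L], r2 = r2,
               p = (1 + exceed) / (nPerm + 1), skipped = FALSE)
  }))
  result@vectors <- do.call(rbind, rows)
  result
}

#' Shepard diagram diagnostics
#'
#' Returns, for every record pair, the input dissimilarity, the
#' configuration distance in the ordination, and the isotonic-fitted
#' disparity (the monotone regression of configuration distance on the rank
#' order of dissimilarity that Kruskal stress-1 is computed against).
#'
#' @param result an [OrdinationResult-class].
#' @param mat the data matrix the ordination was run on (z-scored the same
#'   way when `scale = TRUE` was used).
#' @param scale apply the same z-scoring as [runNMDS()]?
#' @return data.frame with columns `dissimilarity`, `distance`, `disparity`,
#'   sorted by dissimilarity.
#' @export
shepardDiagnostics <- function(result, mat, scale = TRUE) {
  m <- as.matrix(mat)
  if (scale) {
    keep <- apply(m, 2L, sd, na.rm = TRUE) > .Machine$double.eps
    m <- apply(m[, keep, drop = FALSE], 2L, zscore)
  }
  diss <- as.vector(dist(m))
  conf <- as.vector(dist(result@scores))
  ord <- order(diss)
  fit <- stats::isoreg(conf[ord])
  data.frame(dissimilarity = diss[ord], distance = conf[ord],
             disparity = fit$yf)
}

#' Axis-1 separation of persistence status groups
#'
#' Descriptive summary of how the first NMDS axis discriminates persistent
#' (1) from extirpated (0) records: group means, the Wilcoxon rank-sum
#' statistic, and the rank-biserial correlation as effect size
#' (r = 1 - 2W/(n0 n1), in \[-1, 1\]).
#'
#' @param result an [OrdinationResult-class].
#' @param status 0/1 vector aligned with ordination rows.
#' @return list with `mean0`, `mean1`, `W`, `effect`.
#' @export
groupSeparation <- function(result, status) {
  a1 <- result@scores[, 1L]
  status <- as.integer(status)
  g0 <- a1[status == 0L]; g1 <- a1[status == 1L]
  if (!length(g0) || !length(g1)) stop("empty status group")
  W <- suppressWarnings(wilcox.test(g0, g1)$statistic)
  effect <- 1 - 2 * unname(W) / (length(g0) * length(g1))
  list(mean0 = mean(g0), mean1 = mean(g1), W = unname(W), effect = effect)
}
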