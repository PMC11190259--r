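test_that("goodness-of-fit is zero for the empty set and near the null
           deviance for a separating predictor", {
  set.seed(1)
  y <- rbinom(40, 1, 0.5)
  expect_identical(gofFit(y, matrix(numeric(0), 40, 0)), 0)
  # perfectly separating predictor: the fit (ridge fallback if needed)
  # recovers essentially the whole null deviance
  x <- ifelse(y == 1, 1, -1) + rnorm(40, 0, 0.01)
  nullDev <- -2 * sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
  expect_gt(gofFit(y, matrix(x)), 0.95 * nullDev)
})

test_that("K = 1 partition puts everything in the independent contribution", {
  set.seed(2)
  x <- matrix(rnorm(50), dimnames = list(NULL, "only"))
  y <- rbinom(50, 1, plogis(x))
  hp <- hierPart(y, x)
  expect_equal(hpTable(hp)$I, gofFit(y, x))
  expect_equal(hpTable(hp)$J, 0)
})

test_that("partition matches the all-orderings oracle at K = 3 and K = 4", {
  for (K in c(3L, 4L)) {
    set.seed(10 + K)
    x <- matrix(rnorm(60 * K), 60, K,
                dimnames = list(NULL, paste0("v", 1:K)))
    x[, 2] <- x[, 1] + rnorm(60, 0, 0.8)       # induce correlation
    y <- rbinom(60, 1, plogis(0.8 * x[, 1] - 0.5 * x[, K]))
    hp <- hierPart(y, x)
    expect_equal(hpTable(hp)$I, oracleOrderingsI(y, x), tolerance = 1e-10)
    expect_equal(sum(hpTable(hp)$I), hp@gofFull, tolerance = 1e-10)
    expect_equal(hpTable(hp)$I + hpTable(hp)$J,
                 sapply(1:K, function(j) gofFit(y, x[, j, drop = FALSE])),
                 tolerance = 1e-8)
  }
})

test_that("gaussian mode with an orthonormal design decomposes in closed form", {
  set.seed(5)
  # centre before orthonormalizing so the columns are orthogonal to the
  # intercept as well; otherwise the closed form only holds approximately
  Q <- qr.Q(qr(scale(matrix(rnorm(50 * 3), 50, 3), scale = FALSE)))
  colnames(Q) <- c("q1", "q2", "q3")
  y <- drop(Q %*% c(2, -1, 0.5)) + rnorm(50, 0, 0.3)
  hp <- hierPart(y, Q, family = "gaussian")
  ss <- sum((y - mean(y))^2)
  marginal <- sapply(1:3, function(j) cor(y, Q[, j])^2 * ss)
  expect_equal(hpTable(hp)$I, marginal, tolerance = 1e-6)
  expect_lt(max(abs(hpTable(hp)$J)), 1e-6)
})

test_that("exchangeable predictors receive equal contributions on average", {
  set.seed(20)
  rel <- replicate(20, {
    base <- rnorm(400)
    x <- cbind(c1 = base + rnorm(400), c2 = base + rnorm(400))
    y <- rbinom(400, 1, plogis(base))
    I <- hpTable(hierPart(y, x))$I
    (I[1] - I[2]) / mean(I)
  })
  # symmetric within simulation error (per-replicate sd of the relative
  # asymmetry is ~0.45, so judge the mean against its own standard error)
  expect_lt(abs(mean(rel)), 3 * sd(rel) / sqrt(length(rel)) + 0.05)
})

test_that("randomization test is seed-deterministic and flags a generator", {
  set.seed(30)
  x <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rbinom(80, 1, plogis(3 * x[, 2]))
  r1 <- randomizationTest(y, x, reps = 50, seed = 7)
  r2 <- randomizationTest(y, x, reps = 50, seed = 7)
  expect_identical(hpTable(r1), hpTable(r2))
  expect_true(hpTable(r1)$significant[2])
  expect_gt(hpTable(r1)$Z[2], 2)
})

test_that("K > 12 is refused and routed to the iterative protocol", {
  set.seed(40)
  x <- matrix(rnorm(30 * 13), 30, 13)
  y <- rbinom(30, 1, 0.5)
  expect_error(hierPart(y, x), "iteratePartition")
})

test_that("adding a pure-noise column does not inflate other contributions", {
  set.seed(50)
  diffs <- sapply(1:25, function(i) {
    x <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(100, 1, plogis(x[, 1]))
    I2 <- hpTable(hierPart(y, x))$I[1]
    x3 <- cbind(x, noise = rnorm(100))
    I3 <- hpTable(hierPart(y, x3))$I[1]
    I3 - I2
  })
  expect_lt(abs(mean(diffs)), 0.2)
})

test_that("the iterative protocol recovers a planted two-variable signal", {
  cfg <- simulationConfig(nSites = 40, start = "1982-01-01",
                          end = "1997-12-31", boundary = "1989-12-31",
                          seed = 3)
  tab <- buildVariableTable(simulateGrid(cfg),
                            periodSpec("baseline", "1982-01-01", "1989-12-31"),
                            periodSpec("resurvey", "1990-01-01", "1997-12-31"))
  st <- simulateSpecies(tab, c(mean_sst.autumn = -3, seasonality = -2),
                        intercept = 0, seed = 8)
  scr <- screenVariables(tab, st)
  ip <- iteratePartition(st, tab, scr$retained, reps = 30, seed = 5)
  expect_s4_class(ip$final, "HPResult")
  expect_lte(ip$final@k, 12L)
  expect_true(all(c("relevant", "significant") %in% colnames(hpTable(ip$final))))
  # conservation holds on the final run too
  expect_equal(sum(hpTable(ip$final)$I), ip$final@gofFull, tolerance = 1e-8)
  # the planted driver should surface among the relevant set
  expect_true("mean_sst.autumn" %in% ip$relevant ||
                "seasonality" %in% ip$relevant)
  # reproducible under a fixed seed
  ip2 <- iteratePartition(st, tab, scr$retained, reps = 30, seed = 5)
  expect_identical(hpTable(ip2$final), hpTable(ip$final))
})

test_that("an all-noise table yields relevant-by-median but no significance", {
  set.seed(60)
  x <- as.data.frame(matrix(rnorm(60 * 6), 60, 6))
  colnames(x) <- paste0("n", 1:6)
  y <- rbinom(60, 1, 0.5)
  rt <- randomizationTest(y, x, reps = 60, seed = 2)
  tabr <- hpTable(rt)
  relevant <- tabr$I > median(tabr$I)
  expect_identical(sum(relevant), 3L)          # median rule: half above
  expect_lte(sum(tabr$significant), 2L)        # mostly non-significant
})

test_that("species dendrogram merges identical profiles first and matches
           a brute-force agglomeration", {
  profs <- list(spA = c(v1 = 0, v2 = 0), spB = c(v1 = 0, v2 = 0),
                spC = c(v1 = 10, v2 = 10))
  dd <- speciesDendrogram(profs)
  expect_equal(dd$tree$height[1], 0)
  first <- sort(-dd$tree$merge[1, ])
  expect_identical(first, c(1L, 2L))           # the two identical profiles
  # cophenetic distances equal the O(n^3) oracle
  set.seed(70)
  mat <- matrix(rnorm(7 * 4), 7, 4,
                dimnames = list(paste0("sp", 1:7), paste0("v", 1:4)))
  dd2 <- speciesDendrogram(mat)
  coph <- as.matrix(cophenetic(dd2$tree))
  oracle <- oracleCompleteLinkCophenetic(mat)
  expect_equal(unname(coph), unname(oracle), tolerance = 1e-10)
  # missing variables are filled with zero on the shared axis
  profs2 <- list(a = c(v1 = 1), b = c(v2 = 2))
  dd3 <- speciesDendrogram(profs2)
  expect_equal(unname(dd3$matrix), rbind(c(1, 0), c(0, 2)))
  expect_error(speciesDendrogram(mat[1, , drop = FALSE]), "at least 2")
})
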