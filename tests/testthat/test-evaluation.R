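test_that("average precision handles perfect, chance-level and tied rankings", {
  expect_equal(averagePrecision(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 100)
  # all scores tied: precision equals prevalence at the single threshold
  expect_equal(averagePrecision(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 30)
  # chance level equals prevalence for random scores (Monte Carlo)
  aps <- vapply(1:20, function(s) {
    set.seed(s)
    y <- c(rep(1, 100), rep(0, 900))
    averagePrecision(runif(1000), y)
  }, 0)
  expect_lt(abs(mean(aps) - 10), 2)
  expect_error(averagePrecision(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("average precision matches the exhaustive-threshold oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    s <- runif(n)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[sample(n, 1)] <- 1
    expect_equal(averagePrecision(s, y), oracleAveragePrecision(s, y),
      tolerance = 1e-12)
  }
  # with ties between scores
  for (i in 1:20) {
    set.seed(100 + i)
    n <- 10
    s <- sample(seq(0.1, 0.5, 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    expect_equal(averagePrecision(s, y), oracleAveragePrecision(s, y),
      tolerance = 1e-12)
  }
})

test_that("recall and PPV follow from the detection counts", {
  r <- detectionRates(tp = 159, fp = 79, fn = 37)
  expect_equal(r$recallRounded, 81.1)
  expect_equal(r$ppvRounded, 66.8)
  z <- detectionRates(0, 0, 0)
  expect_true(is.na(z$recall) && is.na(z$ppv))
})

test_that("pooled detection metrics match candidates to expert masks", {
  ns <- asNamespace("petstage")
  d <- c(16, 16, 16)
  pet <- array(0, d)
  pet[4:6, 4:6, 4:6] <- 5    # expert lesion A
  pet[11:13, 11:13, 11:13] <- 7  # expert lesion B
  pet[4:6, 11:13, 4:6] <- 3  # a physiological blob
  mk <- function(xr, yr, zr, id) {
    mask <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
    ns$makeFinding(id, mask, pet, c(3, 3, 3))
  }
  expA <- mk(4:6, 4:6, 4:6, "expA")
  expB <- mk(11:13, 11:13, 11:13, "expB")
  candA <- mk(4:6, 4:6, 4:6, "c1")       # matches A
  candPhys <- mk(4:6, 11:13, 4:6, "c2")  # matches nothing
  candB <- mk(11:13, 11:13, 11:13, "c3") # matches B but classified negative
  sub <- list(subjectId = "s1", dim = d,
    candidates = list(candA, candPhys, candB),
    suspicious = c(TRUE, TRUE, FALSE),
    experts = list(expA, expB))
  m <- pooledDetectionMetrics(list(sub))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 1))
  expect_equal(m$recall, 50)
  expect_equal(m$ppv, 50)
  # subject without expert positives and no predictions: recall 100 by
  # convention; with predictions: recall NA (excluded from the summary)
  noPos <- list(subjectId = "s2", dim = d, candidates = list(),
    suspicious = logical(), experts = list())
  m2 <- pooledDetectionMetrics(list(sub, noPos))
  expect_equal(m2$perSubject$recall[2], 100)
  fpOnly <- list(subjectId = "s3", dim = d, candidates = list(candPhys),
    suspicious = TRUE, experts = list())
  m3 <- pooledDetectionMetrics(list(sub, fpOnly))
  expect_true(is.na(m3$perSubject$recall[3]))
  expect_error(pooledDetectionMetrics(list(sub, sub)), "duplicate")
})

test_that("per-subject summaries report the Table-style quantiles", {
  ns <- asNamespace("petstage")
  d <- c(8, 8, 8)
  pet <- array(0, d); pet[2:3, 2:3, 2:3] <- 5
  f <- ns$makeFinding("f", as.matrix(expand.grid(2:3, 2:3, 2:3)), pet, c(3, 3, 3))
  subs <- lapply(1:4, function(i) {
    list(subjectId = paste0("s", i), dim = d, candidates = list(f),
      suspicious = TRUE, experts = if (i <= 2) list(f) else list())
  })
  m <- pooledDetectionMetrics(subs)
  expect_equal(unname(m$summary["recall", "average"]), 100)
  expect_equal(colnames(m$summary), c("average", "min", "q1", "median", "q3", "max"))
})

test_that("bootstrap CI is seeded, degenerate on constants, and covers", {
  subs <- as.list(rnorm(30, mean = 2))
  metric <- function(s) mean(unlist(s))
  a <- bootstrapCi(metric, subs, B = 200, seed = 9)
  b <- bootstrapCi(metric, subs, B = 200, seed = 9)
  expect_identical(a$replicates, b$replicates)
  cst <- bootstrapCi(metric, as.list(rep(3, 10)), B = 50, seed = 1)
  expect_equal(cst$high - cst$low, 0)
  # coverage of the true mean across simulation repetitions
  hits <- 0
  nRep <- 300
  for (i in seq_len(nRep)) {
    set.seed(5000 + i)
    x <- as.list(rnorm(30))
    ci <- bootstrapCi(metric, x, B = 400, seed = i)
    if (ci$low <= 0 && ci$high >= 0) hits <- hits + 1
  }
  expect_gt(hits / nRep, 0.92)
  expect_lt(hits / nRep, 0.98)
})

test_that("bootstrap redraws replicates on which the metric is undefined", {
  subs <- as.list(c(NA, 1, 2, 3))
  metric <- function(s) {
    v <- unlist(s)
    if (anyNA(v)) return(NA_real_)
    mean(v)
  }
  ci <- bootstrapCi(metric, subs, B = 50, seed = 3)
  expect_gt(ci$nRedrawn, 0)
  expect_false(anyNA(ci$replicates))
})

test_that("paired z-test matches the closed form and handles degeneracy", {
  expect_equal(pairedZTest(1:10, 1:10)$pRaw, 1)
  r <- pairedZTest(2:11, 1:10)
  expect_equal(r$pRaw, 0)
  expect_true(r$degenerate)
  set.seed(7)
  a <- rnorm(2000, mean = 0.3)
  b <- rnorm(2000)
  r2 <- pairedZTest(a, b, nComparisons = 5)
  d <- a - b
  pExp <- 2 * (1 - pnorm(abs(mean(d) / sd(d))))
  expect_equal(r2$pRaw, pExp, tolerance = 1e-12)
  expect_equal(r2$pBonferroni, min(1, pExp * 5))
})

test_that("location accuracy scopes to suspicious or all findings", {
  pred <- c("a", "b", "c", "d")
  exp <- c("a", "b", "x", "y")
  susp <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(locationAccuracy(pred, exp, susp, "suspicious_only"), 100)
  expect_equal(locationAccuracy(pred, exp, susp, "all"), 50)
  expect_error(locationAccuracy(pred, exp, rep(FALSE, 4), "suspicious_only"),
    "empty")
})
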