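toyCfg <- function(...) {
  modelConfig(convFilters = c(3, 4), fcWidth = 6, nLocationClasses = 4,
    finalPool = 2, ...)
}

test_that("seeded initialisation is reproducible and config-validated", {
  m1 <- buildModel(toyCfg(), seed = 7)
  m2 <- buildModel(toyCfg(), seed = 7)
  expect_identical(m1$weights, m2$weights)
  m3 <- buildModel(toyCfg(), seed = 8)
  expect_false(identical(m1$weights, m3$weights))
  expect_error(modelConfig(nLocationClasses = 1), "nLocationClasses")
  expect_error(modelConfig(convBlocks = 9), "build error")
})

test_that("the tracer bit feeds the suspicious head only", {
  m <- buildModel(toyCfg(dualTracer = TRUE), seed = 3)
  set.seed(1)
  x <- matrix(runif(4096 * 26), 4096, 26)
  pPSMA <- predictFinding(m, x, tracer = "PSMA")
  pFDG <- predictFinding(m, x, tracer = "FDG")
  expect_identical(pPSMA$locationProbs, pFDG$locationProbs)
  expect_false(identical(pPSMA$pSuspicious, pFDG$pSuspicious))
  # single-tracer variant: the bit is not an input at all
  mS <- buildModel(toyCfg(dualTracer = FALSE), seed = 3)
  expect_equal(nrow(mS$weights$suspW1) + 1, nrow(m$weights$suspW1))
  q1 <- predictFinding(mS, x, "PSMA")
  q2 <- predictFinding(mS, x, "FDG")
  expect_identical(q1$pSuspicious, q2$pSuspicious)
})

test_that("predictions are normalised, deterministic, and shape-checked", {
  m <- buildModel(toyCfg(), seed = 1)
  set.seed(2)
  x <- matrix(runif(4096 * 26), 4096, 26)
  p <- predictFinding(m, x)
  expect_gte(p$pSuspicious, 0); expect_lte(p$pSuspicious, 1)
  expect_equal(sum(p$locationProbs), 1, tolerance = 1e-6)
  expect_identical(predictFinding(m, x)$pSuspicious, p$pSuspicious)
  expect_error(predictFinding(m, matrix(0, 10, 26)), "shape")
})

test_that("backpropagation matches finite differences on every tensor", {
  ns <- asNamespace("petstage")
  m <- buildModel(toyCfg(dualTracer = TRUE), seed = 2)
  set.seed(4)
  x <- matrix(runif(4096 * 26), 4096, 26)
  lg <- ns$cnnLossGrad(m, x, tracer = 1, y = 1, locClass = 3)
  eps <- 1e-5
  set.seed(5)
  for (nm in names(m$weights)) {
    w0 <- m$weights[[nm]]
    for (i in sample(length(w0), min(3, length(w0)))) {
      mp <- m; mp$weights[[nm]][i] <- w0[i] + eps
      mm <- m; mm$weights[[nm]][i] <- w0[i] - eps
      num <- (ns$cnnLossGrad(mp, x, 1, 1, 3)$loss -
          ns$cnnLossGrad(mm, x, 1, 1, 3)$loss) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4,
        label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("the location loss has exactly zero gradient on the tracer-bit weights", {
  ns <- asNamespace("petstage")
  cfg <- toyCfg(dualTracer = TRUE)
  cfg$lossWeights <- c(0, 1)  # location loss only
  m <- buildModel(cfg, seed = 2)
  set.seed(6)
  x <- matrix(runif(4096 * 26), 4096, 26)
  lg <- ns$cnnLossGrad(m, x, tracer = 1, y = 1, locClass = 2)
  tracerRow <- nrow(m$weights$suspW1)  # the bit is the last input row
  expect_true(all(lg$grads$suspW1[tracerRow, ] == 0))
  # the whole suspicious head is silent under the location loss
  expect_true(all(lg$grads$suspW2 == 0))
  # while conv weights still receive location gradient
  expect_gt(max(abs(lg$grads$conv1W)), 0)
})

test_that("a masked location label contributes no location gradient", {
  ns <- asNamespace("petstage")
  m <- buildModel(toyCfg(), seed = 2)
  set.seed(7)
  x <- matrix(runif(4096 * 26), 4096, 26)
  lg <- ns$cnnLossGrad(m, x, 0, 1, NA)
  expect_true(all(lg$grads$locW2 == 0))
  expect_equal(lg$lossL, 0)
})

test_that("a small configuration can overfit a handful of phantom findings", {
  ns <- asNamespace("petstage")
  coh <- generateCohort(4, tracer = "PSMA", seed = 91)
  recs <- list()
  for (gs in coh$subjects) {
    s <- gs$subject
    for (f in s@findings) {
      recs[[length(recs) + 1]] <- list(
        x = ns$stackToInput(extractMpr(s@volume, f@suvMaxVoxel)),
        y = as.integer(f@labelSuspicious == "suspicious"),
        loc = f@labelLocation)
    }
  }
  recs <- recs[seq_len(min(20, length(recs)))]
  classes <- sort(unique(vapply(recs, `[[`, "", "loc")))
  m <- buildModel(modelConfig(convFilters = c(4), fcWidth = 16,
    nLocationClasses = length(classes), finalPool = 8, posWeight = 4),
    seed = 11)
  st <- ns$adamInit(m$weights)
  acc <- function() {
    ok <- vapply(recs, function(r) {
      fw <- ns$cnnForward(m, r$x, 0)
      (fw$pSuspicious >= 0.5) == (r$y == 1) &&
        which.max(fw$locationProbs) == match(r$loc, classes)
    }, TRUE)
    mean(ok)
  }
  done <- FALSE
  for (ep in 1:200) {
    g <- NULL
    for (r in recs) {
      lg <- ns$cnnLossGrad(m, r$x, 0, r$y, match(r$loc, classes))
      g <- ns$sumGrads(g, lg$grads)
    }
    u <- ns$adamStep(m$weights, ns$scaleGrads(g, 1 / length(recs)), st,
      lr = 1e-2)
    m$weights <- u$weights; st <- u$state
    if (ep %% 10 == 0 && acc() == 1) { done <- TRUE; break }
  }
  expect_true(done || acc() == 1)
})

test_that("models survive a save/load round trip with their sidecar", {
  m <- buildModel(toyCfg(), seed = 1)
  m$locationClasses <- c("a", "b", "c", "d")
  path <- tempfile()
  saveModel(m, path)
  back <- loadModel(path)
  expect_identical(back$weights, m$weights)
  expect_identical(back$locationClasses, m$locationClasses)
  sidecar <- paste0(path, ".json")
  expect_true(file.exists(sidecar))
  meta <- jsonlite::read_json(sidecar)
  expect_equal(unlist(meta$locationClasses), m$locationClasses)
})
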