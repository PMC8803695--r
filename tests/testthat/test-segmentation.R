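test_that("a single blob is thresholded at 45% of its peak", {
  # compact blob (zero background beyond the mask): exactly one finding
  # whose mask is exactly the voxel set at or above 45% of the peak
  pet <- blobVolume(c(32, 32, 32), center = c(16, 16, 16), peak = 10)
  pet[pet < 4.5] <- 0
  fs <- incrementalConnectedComponents(pet, segmentationConfig())
  expect_length(fs, 1)
  f <- fs[[1]]
  expect_equal(suvMax(f), 10)
  ns <- asNamespace("petstage")
  d <- dim(pet)
  want <- sort(which(pet >= 4.5))
  expect_equal(sort(ns$voxelToLinear(findingMask(f), d)), want)
  # with smooth tails the peeling continues below the first threshold: the
  # leading finding is unchanged and every later one stays below it
  pet2 <- blobVolume(c(32, 32, 32), center = c(16, 16, 16), peak = 10)
  fs2 <- incrementalConnectedComponents(pet2, segmentationConfig())
  expect_equal(sort(ns$voxelToLinear(findingMask(fs2[[1]]), d)), want)
  expect_true(all(vapply(fs2[-1], suvMax, 0) < 4.5))
})

test_that("nothing above the floor yields an empty finding list", {
  pet <- array(0.5, c(8, 8, 8))
  expect_length(incrementalConnectedComponents(pet, segmentationConfig()), 0)
  expect_length(incrementalConnectedComponents(array(0, c(8, 8, 8)),
    segmentationConfig()), 0)
})

test_that("two separated blobs are emitted in SUVmax order and match the flood-fill oracle", {
  pet <- array(0, c(32, 32, 32))
  pet[7:11, 7:11, 7:11] <- 10   # two isolated plateau uptake sites
  pet[22:26, 22:26, 22:26] <- 6
  fs <- incrementalConnectedComponents(pet, segmentationConfig())
  expect_length(fs, 2)
  expect_equal(suvMax(fs[[1]]), max(pet))
  expect_gt(suvMax(fs[[1]]), suvMax(fs[[2]]))
  ns <- asNamespace("petstage")
  d <- dim(pet)
  oracle <- oracleSegment(pet)
  got <- lapply(fs, function(f) sort(ns$voxelToLinear(findingMask(f), d)))
  expect_equal(got, oracle)
})

test_that("segmentation equals the brute-force oracle on random smoothed fields", {
  ns <- asNamespace("petstage")
  for (seed in 1:3) {
    pet <- randomSuvField(c(32, 32, 32), seed = seed, peak = 8)
    fs <- incrementalConnectedComponents(pet, segmentationConfig())
    oracle <- oracleSegment(pet)
    d <- dim(pet)
    got <- lapply(fs, function(f) sort(ns$voxelToLinear(findingMask(f), d)))
    expect_equal(got, oracle)
    # masks pairwise disjoint; every voxel above the floor assigned
    all <- unlist(got)
    expect_false(anyDuplicated(all) > 0)
    expect_true(all(which(pet > 1.0) %in% all))
  }
})

test_that("raising the floor never increases the number of findings", {
  pet <- randomSuvField(c(24, 24, 24), seed = 77, peak = 6)
  nPrev <- Inf
  for (fl in c(0.5, 1, 2, 3)) {
    n <- length(incrementalConnectedComponents(pet,
      segmentationConfig(suvFloor = fl)))
    expect_lte(n, nPrev)
    nPrev <- n
  }
})

test_that("seed-based group-A segmentation hill-climbs, deduplicates and skips dead seeds", {
  pet <- blobVolume(c(32, 32, 32), c(16, 16, 16), 10)
  cand <- incrementalConnectedComponents(pet, segmentationConfig())[[1]]
  # a seed on the blob flank reaches the same region as the candidate scheme
  fs <- segmentGroupA(pet, list(c(13, 14, 16)), segmentationConfig())
  expect_length(fs, 1)
  expect_identical(sort(findingMask(fs[[1]])[, 1] +
      32 * (findingMask(fs[[1]])[, 2] - 1) +
      1024 * (findingMask(fs[[1]])[, 3] - 1)),
    sort(findingMask(cand)[, 1] + 32 * (findingMask(cand)[, 2] - 1) +
      1024 * (findingMask(cand)[, 3] - 1)))
  # two seeds in the same blob merge to one finding
  fs2 <- segmentGroupA(pet, list(c(13, 14, 16), c(18, 17, 16)),
    segmentationConfig())
  expect_length(fs2, 1)
  # a seed on zero uptake yields nothing (exact zeros outside the blob)
  petZ <- pet
  petZ[petZ < 0.01] <- 0
  fs3 <- segmentGroupA(petZ, list(c(1, 1, 1)), segmentationConfig())
  expect_length(fs3, 0)
})

test_that("group-B segmentation floors at the liver reference mean and truncates", {
  # plateau uptake (no sub-threshold shells): floor from the reference region
  # must exclude the low-uptake site entirely
  d <- c(40, 40, 40)
  pet <- array(0, d)
  pet[8:12, 8:12, 8:12] <- 10    # tumour-like site
  pet[28:32, 28:32, 28:32] <- 1.5  # below the liver mean
  ref <- as.matrix(expand.grid(18:22, 18:22, 18:22))
  pet[ref] <- 2.0
  cfg <- segmentationConfig(liverReference = ref)
  fs <- segmentGroupB(pet, cfg)
  expect_length(fs, 1)
  expect_equal(suvMax(fs[[1]]), 10)
  # sphere-specified reference behaves like the mask
  cfgS <- segmentationConfig(liverReference = list(center = c(20, 20, 20),
    radiusMm = 6))
  fsS <- segmentGroupB(pet, cfgS)
  expect_length(fsS, 1)
  expect_error(segmentGroupB(pet, segmentationConfig()), "liverReference")
})

test_that("group-B truncation keeps the highest-SUVmax regions", {
  d <- c(30, 30, 60)
  pet <- array(0, d)
  # 27 separated single-voxel spikes with distinct intensities
  centers <- as.matrix(expand.grid(c(5, 15, 25), c(5, 15, 25),
    c(10, 30, 50)))
  vals <- seq(2, 12, length.out = nrow(centers))
  pet[centers] <- vals
  ref <- as.matrix(expand.grid(1:2, 1:2, 1:2))  # mean 0 reference
  cfg <- segmentationConfig(maxRegions = 10, liverReference = ref)
  cfg$suvFloor <- 1
  fs <- segmentGroupB(pet, cfg)
  expect_length(fs, 10)
  kept <- sort(vapply(fs, suvMax, 0), decreasing = TRUE)
  expect_equal(kept, sort(vals, decreasing = TRUE)[1:10])
  # zero-uptake reference mean: same result as an explicit floor of 0
  cfg0 <- segmentationConfig(liverReference = ref)
  fs0 <- segmentGroupB(pet, cfg0)
  cfgF <- segmentationConfig(suvFloor = 0, maxRegions = 100)
  fsF <- incrementalConnectedComponents(pet, cfgF)
  expect_equal(length(fs0), length(fsF))
})

test_that("auto-nonsuspicious excludes expert-suspicious overlap and respects the group-B limit", {
  s <- tinySubject(blobs = list(
    list(center = c(7, 7, 7), peak = 8, suspicious = TRUE, location = "bone"),
    list(center = c(17, 17, 17), peak = 6, suspicious = FALSE,
      location = "liver")))
  auto <- generateAutoNonsuspicious(s)
  peaks <- t(vapply(auto, function(f) f@suvMaxVoxel, integer(3)))
  # no auto finding may sit on the expert-suspicious lesion
  expect_false(any(peaks[, 1] == 7 & peaks[, 2] == 7 & peaks[, 3] == 7))
  expect_true(all(vapply(auto, function(f) f@labelSuspicious, "") ==
    "nonsuspicious"))
  expect_true(all(vapply(auto, function(f) f@provenance, "") ==
    "auto_nonsuspicious"))
  # the physiological blob is recovered
  expect_true(any(peaks[, 1] == 17 & peaks[, 2] == 17 & peaks[, 3] == 17))
  # group-B subject with more than nine suspicious findings: nothing
  sB <- s
  sB@group <- "B"
  sB@findings <- rep(Filter(function(f) f@labelSuspicious == "suspicious",
    s@findings), 12)
  expect_length(generateAutoNonsuspicious(sB), 0)
  # no uptake above SUV 1: nothing
  sLow <- tinySubject(id = "low", blobs = list())
  expect_length(generateAutoNonsuspicious(sLow), 0)
})
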