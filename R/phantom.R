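# Anatomical class list the phantom emits: staging-relevant lesion zones
# plus tracer-specific physiological organs.
PHANTOM_CLASSES <- c("regional_node", "extrapelvic_node", "bone",
  "other_organ", "liver", "spleen", "kidney", "bladder", "salivary",
  "brain", "cardiac")

#' Default location taxonomy for phantom data
#'
#' Lesion zones map to their staging role; organ classes are physiological.
#'
#' @return A [locationTaxonomy()].
#' @export
defaultTaxonomy <- function() {
  locationTaxonomy(c(
    regional_node = "regional_node", extrapelvic_node = "extrapelvic_node",
    bone = "bone", other_organ = "other_organ",
    liver = "physiological", spleen = "physiological",
    kidney = "physiological", bladder = "physiological",
    salivary = "physiological", brain = "physiological",
    cardiac = "physiological"))
}

#' Phantom generator configuration
#'
#' The phantom emulates a whole-body PET/CT at the 3 mm working resolution:
#' tracer-specific physiological organs painted as ellipsoids, spherical
#' lesions inserted in class-consistent anatomical zones (regional nodes in
#' the pelvis, extrapelvic nodes retroperitoneal, bone lesions inside
#' high-HU spine/pelvis structures, other-organ lesions in lung), Gaussian
#' PSF blur, and voxelwise Gaussian noise proportional to local SUV.
#'
#' @param grid grid shape (default 64 x 64 x 160 at 3 mm).
#' @param tracer "PSMA" or "FDG" (selects the physiological organ set).
#' @param lesionSpec named integer vector of lesion counts per anatomical
#'   class, names from regional_node / extrapelvic_node / bone / other_organ.
#' @param suvRange lesion SUVmax range (uniform draw), default 4-15.
#' @param radiusRangeMm lesion radius range in mm, default 6-9.
#' @param psfFwhmMm PET point-spread FWHM in mm (default 6).
#' @param noiseSigma Gaussian noise s.d. as a fraction of local SUV
#'   (default 0.05).
#' @param backgroundSuv soft-tissue background SUV (default 0.3).
#' @param seed integer seed.
#' @return A classed list of settings.
#' @export
phantomConfig <- function(grid = c(64, 64, 160), tracer = "PSMA",
                          lesionSpec = c(regional_node = 1, bone = 2),
                          suvRange = c(4, 15), radiusRangeMm = c(6, 9),
                          psfFwhmMm = 6, noiseSigma = 0.05,
                          backgroundSuv = 0.3, seed = 1) {
  stopifnot(tracer %in% c("PSMA", "FDG"))
  if (length(lesionSpec)) {
    bad <- setdiff(names(lesionSpec),
      c("regional_node", "extrapelvic_node", "bone", "other_organ"))
    if (length(bad)) stop("unknown lesion classes: ", paste(bad, collapse = ", "))
  }
  if (suvRange[1] <= 1) stop("lesion SUV range must lie above the 1.0 floor")
  structure(list(grid = as.integer(grid), tracer = tracer,
    lesionSpec = lesionSpec, suvRange = suvRange,
    radiusRangeMm = radiusRangeMm, psfFwhmMm = psfFwhmMm,
    noiseSigma = noiseSigma, backgroundSuv = backgroundSuv,
    seed = as.integer(seed)), class = "PhantomConfig")
}

# Ellipsoid voxel mask as linear indices.
ellipsoidMask <- function(d, center, radii) {
  xr <- pmax(1L, floor(center[1] - radii[1])):pmin(d[1], ceiling(center[1] + radii[1]))
  yr <- pmax(1L, floor(center[2] - radii[2])):pmin(d[2], ceiling(center[2] + radii[2]))
  zr <- pmax(1L, floor(center[3] - radii[3])):pmin(d[3], ceiling(center[3] + radii[3]))
  g <- expand.grid(x = xr, y = yr, z = zr)
  keep <- ((g$x - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
    ((g$z - center[3]) / radii[3])^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# Tracer-specific organ templates: name, class, center, radii, SUV, HU.
phantomOrgans <- function(tracer) {
  if (tracer == "PSMA") {
    list(
      list(class = "liver", center = c(20, 30, 100), radii = c(11, 9, 9), suv = 2.5, hu = 60),
      list(class = "spleen", center = c(46, 30, 100), radii = c(5, 5, 6), suv = 2.0, hu = 50),
      list(class = "kidney", center = c(18, 42, 82), radii = c(4, 4, 5), suv = 6, hu = 40),
      list(class = "kidney", center = c(46, 42, 82), radii = c(4, 4, 5), suv = 6, hu = 40),
      list(class = "bladder", center = c(32, 26, 34), radii = c(5, 5, 5), suv = 12, hu = 10),
      list(class = "salivary", center = c(26, 32, 152), radii = c(3, 3, 3), suv = 5, hu = 40),
      list(class = "salivary", center = c(38, 32, 152), radii = c(3, 3, 3), suv = 5, hu = 40))
  } else {
    list(
      list(class = "brain", center = c(32, 32, 152), radii = c(7, 7, 6), suv = 8, hu = 40),
      list(class = "cardiac", center = c(26, 28, 112), radii = c(5, 5, 5), suv = 5, hu = 40),
      list(class = "liver", center = c(20, 30, 100), radii = c(11, 9, 9), suv = 2.5, hu = 60),
      list(class = "bladder", center = c(32, 26, 34), radii = c(5, 5, 5), suv = 8, hu = 10))
  }
}

# Lesion zone sampling boxes (voxel ranges) per anatomical class, chosen to
# stay clear of the organ templates.
phantomZones <- function() {
  list(
    regional_node = list(x = c(20, 44), y = c(13, 18), z = c(34, 52)),
    extrapelvic_node = list(x = c(26, 38), y = c(28, 36), z = c(60, 78)),
    bone = list(x = c(31, 33), y = c(43, 45), z = c(45, 135)),
    other_organ = list(x = c(42, 47), y = c(28, 36), z = c(110, 126)))
}

#' Generate one synthetic phantom subject
#'
#' Paints the tracer's physiological organs and the configured lesions,
#' applies PSF blur and voxelwise noise, re-derives expert-style finding
#' masks by 45%-of-peak thresholding around each inserted structure, and
#' returns the subject together with its ground truth (true findings and
#' the stage implied by the true lesion classes). Same seed, same output,
#' bit for bit; two tracers at the same seed share identical lesion
#' geometry and differ only in the physiological organ map.
#'
#' @param cfg a [phantomConfig()].
#' @param subjectId identifier for the emitted subject.
#' @return list with `subject` (a [Subject-class] carrying expert findings)
#'   and `groundTruth` (list with `findings`, `lesionClasses`, `stage`).
#' @export
generateSubject <- function(cfg, subjectId = "phantom01") {
  d <- cfg$grid
  maxTries <- 20L
  for (attempt in seq_len(maxTries)) {
    lesions <- withSeed(deriveSeed(cfg$seed, 1000 + attempt), {
      drawLesions(cfg)
    })
    built <- buildPhantomVolume(cfg, lesions)
    ok <- validatePhantom(built, lesions)
    if (ok) break
    if (attempt == maxTries) {
      stop("phantom generation failed: lesion placements merge after blur")
    }
  }
  pet <- built$pet
  ct <- built$ct
  vol <- PetCtVolume(pet = pet, ct = ct, spacing = c(3, 3, 3))
  # expert-style annotations: 45%-of-peak regions around each structure
  findingsList <- list()
  i <- 0L
  for (les in lesions) {
    i <- i + 1L
    peak <- localPeak(pet, les$center, les$radiusVox + 1)
    comp <- connectedComponent(pet >= 0.45 * pet[matrix(peak, 1)], peak, 26)
    findingsList[[i]] <- makeFinding(sprintf("les%02d", i), comp, pet,
      c(3, 3, 3), labelSuspicious = "suspicious",
      labelLocation = les$class, provenance = "expert")
  }
  for (org in phantomOrgans(cfg$tracer)) {
    i <- i + 1L
    peak <- localPeak(pet, org$center, max(org$radii))
    if (pet[matrix(peak, 1)] <= 1) next
    comp <- connectedComponent(pet >= 0.45 * pet[matrix(peak, 1)], peak, 26)
    findingsList[[i]] <- makeFinding(sprintf("org%02d", i), comp, pet,
      c(3, 3, 3), labelSuspicious = "nonsuspicious",
      labelLocation = org$class, provenance = "expert")
  }
  findingsList <- Filter(Negate(is.null), findingsList)
  subj <- Subject(subjectId, cfg$tracer, vol, findingsList, group = "A")
  lesionClasses <- vapply(lesions, function(l) l$class, "")
  gt <- list(findings = findingsList[seq_along(lesions)],
    lesionClasses = lesionClasses,
    stage = assignStage(lesionClasses, defaultTaxonomy()))
  list(subject = subj, groundTruth = gt)
}

# Draw lesion centers, radii and SUVs for every class in lesionSpec, enforcing
# in-zone pairwise separation.
drawLesions <- function(cfg) {
  zones <- phantomZones()
  out <- list()
  for (cls in names(cfg$lesionSpec)) {
    nles <- cfg$lesionSpec[[cls]]
    if (nles == 0) next
    z <- zones[[cls]]
    placed <- list()
    for (i in seq_len(nles)) {
      for (try in 1:200) {
        ctr <- c(round(runif(1, z$x[1], z$x[2])),
          round(runif(1, z$y[1], z$y[2])),
          round(runif(1, z$z[1], z$z[2])))
        rVox <- runif(1, cfg$radiusRangeMm[1], cfg$radiusRangeMm[2]) / 3
        okSep <- all(vapply(placed, function(p) {
          sqrt(sum((p$center - ctr)^2)) >= (p$radiusVox + rVox + 4)
        }, TRUE))
        if (okSep) {
          placed[[i]] <- list(class = cls, center = ctr, radiusVox = rVox,
            suv = runif(1, cfg$suvRange[1], cfg$suvRange[2]))
          break
        }
        if (try == 200) stop("unreachable lesion layout for class ", cls)
      }
    }
    out <- c(out, placed)
  }
  out
}

# Paint organs + lesions, blur, add noise. Deterministic given cfg and the
# lesion draw (noise stream derived from cfg$seed only, so the field is
# shared across tracers at equal seed).
buildPhantomVolume <- function(cfg, lesions) {
  d <- cfg$grid
  pet <- array(0, d)
  ct <- array(-1000, d)
  # body: soft-tissue cylinder with elliptical cross-section
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  body2d <- ((g$x - d[1] / 2) / (d[1] / 2 - 3))^2 +
    ((g$y - d[2] / 2) / (d[2] / 2 - 5))^2 <= 1
  bodyIdx <- which(body2d)
  for (z in seq_len(d[3])) {
    plane <- matrix(-1000, d[1], d[2])
    plane[bodyIdx] <- 30
    ct[, , z] <- plane
    petPlane <- matrix(0, d[1], d[2])
    petPlane[bodyIdx] <- cfg$backgroundSuv
    pet[, , z] <- petPlane
  }
  # lungs (low HU) and bone structures (high HU)
  for (m in list(list(c(20, 32, 118), c(9, 8, 13), -800),
    list(c(44, 32, 118), c(9, 8, 13), -800))) {
    ct[ellipsoidMask(d, m[[1]], m[[2]])] <- m[[3]]
  }
  spine <- as.matrix(expand.grid(x = 29:35, y = 41:47, z = 30:140))
  ct[spine] <- 700
  for (m in list(list(c(16, 36, 40), c(5, 4, 7)), list(c(48, 36, 40), c(5, 4, 7)))) {
    ct[ellipsoidMask(d, m[[1]], m[[2]])] <- 700
  }
  for (org in phantomOrgans(cfg$tracer)) {
    mask <- ellipsoidMask(d, org$center, org$radii)
    pet[mask] <- pmax(pet[mask], org$suv)
    ct[mask] <- org$hu
  }
  for (les in lesions) {
    mask <- ellipsoidMask(d, les$center, rep(les$radiusVox, 3))
    pet[mask] <- pmax(pet[mask], les$suv)
    ct[mask] <- pmax(ct[mask], 40)
  }
  sigmaVox <- cfg$psfFwhmMm / 2.3548 / 3
  pet <- gaussianBlur3d(pet, sigmaVox)
  noise <- withSeed(deriveSeed(cfg$seed, 2), array(rnorm(prod(d)), d))
  pet <- pet + cfg$noiseSigma * pet * noise
  pet[pet < 0] <- 0
  list(pet = pet, ct = ct)
}

# Highest-PET voxel within a ball around a template center.
localPeak <- function(pet, center, radiusVox) {
  d <- dim(pet)
  mask <- ellipsoidMask(d, center, rep(radiusVox, 3))
  vals <- pet[mask]
  as.integer(mask[which.max(vals), ])
}

# A draw is valid when every lesion's 45% region is disjoint from every
# other structure's peak (no merging after blur).
validatePhantom <- function(built, lesions) {
  pet <- built$pet
  d <- dim(pet)
  if (!length(lesions)) return(TRUE)
  peaks <- lapply(lesions, function(l) localPeak(pet, l$center, l$radiusVox + 1))
  masks <- lapply(seq_along(lesions), function(i) {
    p <- peaks[[i]]
    comp <- connectedComponent(pet >= 0.45 * pet[matrix(p, 1)], p, 26)
    voxelToLinear(comp, d)
  })
  peakLin <- vapply(peaks, function(p) voxelToLinear(matrix(p, 1), d), 0L)
  for (i in seq_along(masks)) {
    others <- peakLin[-i]
    if (any(others %in% masks[[i]])) return(FALSE)
  }
  TRUE
}

#' Generate a phantom cohort
#'
#' Draws each subject's target stage from `stageMix`, derives a lesion
#' specification achieving it, and generates the subjects. The returned
#' metadata table carries each subject's true stage for stratified
#' splitting.
#'
#' @param n number of subjects.
#' @param stageMix data.frame with columns `n`, `m`, `prob`: the target
#'   (N, M) stage distribution. Default spans all N and M categories.
#' @param tracer "PSMA" or "FDG".
#' @param seed integer seed.
#' @param ... further arguments passed to [phantomConfig()].
#' @return list with `subjects` (list of per-subject `generateSubject()`
#'   results) and `metadata` (data.frame subjectId / tracer / nStage /
#'   mStage).
#' @export
generateCohort <- function(n, stageMix = defaultStageMix(), tracer = "PSMA",
                           seed = 1, ...) {
  stopifnot(n >= 1)
  stopifnot(all(c("n", "m", "prob") %in% names(stageMix)))
  picks <- withSeed(deriveSeed(seed, 3), {
    sample.int(nrow(stageMix), n, replace = TRUE, prob = stageMix$prob)
  })
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    target <- stageMix[picks[i], ]
    spec <- withSeed(deriveSeed(seed, 100 + i), {
      lesionSpecFor(target$n, target$m)
    })
    cfg <- phantomConfig(tracer = tracer, lesionSpec = spec,
      seed = deriveSeed(seed, 200 + i), ...)
    subjects[[i]] <- generateSubject(cfg, sprintf("P%03d", i))
  }
  metadata <- data.frame(
    subjectId = vapply(subjects, function(s) s$subject@subjectId, ""),
    tracer = tracer,
    nStage = vapply(subjects, function(s) s$groundTruth$stage@nStage, ""),
    mStage = vapply(subjects, function(s) s$groundTruth$stage@mStage, ""),
    stringsAsFactors = FALSE)
  list(subjects = subjects, metadata = metadata)
}

#' @rdname generateCohort
#' @export
defaultStageMix <- function() {
  data.frame(
    n = c("N0", "N1", "N2", "N0", "N0", "N0", "N0", "N0", "N1"),
    m = c("M0", "M0", "M0", "M1a", "M1b_u", "M1b_o", "M1b_d", "M1c", "M1b_o"),
    prob = c(0.22, 0.13, 0.13, 0.10, 0.10, 0.10, 0.10, 0.06, 0.06),
    stringsAsFactors = FALSE)
}

# Lesion counts realising a target (N, M) stage; counts with a free range
# are drawn from the caller's RNG stream.
lesionSpecFor <- function(nStage, mStage) {
  spec <- c(regional_node = 0, extrapelvic_node = 0, bone = 0, other_organ = 0)
  spec["regional_node"] <- switch(nStage, N0 = 0, N1 = 1,
    N2 = sample(2:3, 1))
  if (mStage == "M1a") spec["extrapelvic_node"] <- sample(1:2, 1)
  if (mStage == "M1b_u") spec["bone"] <- 1
  if (mStage == "M1b_o") spec["bone"] <- sample(2:3, 1)
  if (mStage == "M1b_d") spec["bone"] <- sample(4:5, 1)
  if (mStage == "M1c") spec["other_organ"] <- 1
  spec[spec > 0]
}
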