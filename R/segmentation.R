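#' Segmentation configuration
#'
#' Parameters of the incremental connected-component segmentation: regions
#' are peeled off in order of decreasing SUVmax, each thresholded at
#' `thresholdFraction` of its own peak (45% by default).
#'
#' @param thresholdFraction per-region threshold as a fraction of the
#'   region's SUVmax; must lie in (0, 1). Default 0.45.
#' @param suvFloor minimum SUV for a region peak (default 1.0).
#' @param connectivity voxel connectivity, 6 or 26 (default 26).
#' @param maxRegions optional cap: keep only the `maxRegions` regions of
#'   highest SUVmax (the group-B scheme uses 100).
#' @param liverReference optional reference region for the group-B floor:
#'   either an n x 3 voxel index matrix, or a list
#'   `list(center = c(x,y,z), radiusMm = 15)` describing a sphere.
#' @return A classed list of settings.
#' @export
segmentationConfig <- function(thresholdFraction = 0.45, suvFloor = 1.0,
                               connectivity = 26, maxRegions = NULL,
                               liverReference = NULL) {
  if (!(thresholdFraction > 0 && thresholdFraction < 1)) {
    stop("thresholdFraction: must lie strictly between 0 and 1")
  }
  if (suvFloor < 0) stop("suvFloor: must be >= 0")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  structure(list(
    thresholdFraction = thresholdFraction, suvFloor = suvFloor,
    connectivity = connectivity, maxRegions = maxRegions,
    liverReference = liverReference), class = "SegmentationConfig")
}

#' Incremental connected-component segmentation
#'
#' Deterministic peeling procedure: while any unassigned voxel exceeds the
#' SUV floor, take the unassigned voxel of globally maximal SUV (ties broken
#' by lowest linear index), set the threshold to `thresholdFraction` times
#' that peak, extract the connected component of unassigned voxels at or
#' above the threshold containing the peak, and emit it as a candidate
#' finding. Findings are returned sorted by SUVmax descending; when
#' `maxRegions` is set only the highest-SUVmax findings are kept.
#'
#' @param pet 3-D non-negative SUV array.
#' @param cfg a [segmentationConfig()].
#' @param spacing voxel spacing in mm (for finding volumes).
#' @param idPrefix prefix for generated finding ids.
#' @return list of [Finding-class] (provenance "candidate"); empty when no
#'   voxel exceeds the floor.
#' @export
incrementalConnectedComponents <- function(pet, cfg = segmentationConfig(),
                                           spacing = c(3, 3, 3),
                                           idPrefix = "cand") {
  stopifnot(all(pet >= 0))
  d <- dim(pet)
  work <- pet
  out <- list()
  n <- 0L
  repeat {
    peakLin <- which.max(work)  # first index on ties = lowest linear index
    peakVal <- work[peakLin]
    if (!length(peakVal) || peakVal <= cfg$suvFloor) break
    t <- cfg$thresholdFraction * peakVal
    eligible <- work >= t  # unassigned voxels only: assigned are set to -1
    seed <- linearToVoxel(peakLin, d)[1, ]
    comp <- connectedComponent(eligible, seed, cfg$connectivity)
    n <- n + 1L
    out[[n]] <- makeFinding(sprintf("%s%03d", idPrefix, n), comp, pet,
      spacing, provenance = "candidate")
    work[voxelToLinear(comp, d)] <- -1
  }
  if (!length(out)) return(list())
  ord <- order(-vapply(out, function(f) f@suvMax, 0),
    vapply(out, function(f) voxelToLinear(matrix(f@suvMaxVoxel, 1), d), 0L))
  out <- out[ord]
  if (!is.null(cfg$maxRegions) && length(out) > cfg$maxRegions) {
    out <- out[seq_len(cfg$maxRegions)]
  }
  out
}

#' Seed-based segmentation (group-A annotation scheme)
#'
#' Emulates semi-automatic expert annotation: from each seed voxel a local
#' maximum is found by hill climbing over the 26-neighbourhood; the region is
#' then grown at `thresholdFraction` of that local maximum. Seeds landing on
#' zero uptake yield no finding; duplicate regions (identical SUVmax voxel)
#' are merged.
#'
#' @param pet 3-D non-negative SUV array.
#' @param seeds list (or n x 3 matrix) of 1-based voxel indices.
#' @param cfg a [segmentationConfig()].
#' @param spacing voxel spacing in mm.
#' @return list of [Finding-class] with provenance "expert".
#' @export
segmentGroupA <- function(pet, seeds, cfg = segmentationConfig(),
                          spacing = c(3, 3, 3)) {
  if (is.matrix(seeds)) seeds <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
  d <- dim(pet)
  peaks <- list()
  for (s in seeds) {
    stopifnot(all(s >= 1), all(s <= d))
    p <- hillClimb(pet, as.integer(s))
    if (pet[matrix(p, 1)] <= 0) next  # zero-uptake seed: no finding
    peaks[[length(peaks) + 1]] <- p
  }
  if (!length(peaks)) return(list())
  peakLin <- vapply(peaks, function(p) voxelToLinear(matrix(p, 1), d), 0L)
  peaks <- peaks[!duplicated(peakLin)]
  out <- list()
  for (i in seq_along(peaks)) {
    p <- peaks[[i]]
    peakVal <- pet[matrix(p, 1)]
    t <- cfg$thresholdFraction * peakVal
    comp <- connectedComponent(pet >= t, p, cfg$connectivity)
    f <- makeFinding(sprintf("seed%03d", i), comp, pet, spacing,
      provenance = "expert")
    out[[length(out) + 1]] <- f
  }
  # regions that converged to distinct starts may still share a SUVmax voxel
  lin <- vapply(out, function(f) voxelToLinear(matrix(f@suvMaxVoxel, 1), d), 0L)
  out[!duplicated(lin)]
}

# Hill climbing to a 26-neighbourhood local maximum; on ties the neighbour
# with the lowest linear index wins, and climbing stops when no neighbour
# strictly exceeds the current voxel.
hillClimb <- function(pet, start) {
  d <- dim(pet)
  offs <- neighbourOffsets(26)
  cur <- start
  repeat {
    nb <- sweep(offs, 2, cur, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    vals <- pet[nb]
    curVal <- pet[matrix(cur, 1)]
    if (!length(vals) || max(vals) <= curVal) return(cur)
    best <- which(vals == max(vals))
    if (length(best) > 1) {
      lin <- voxelToLinear(nb[best, , drop = FALSE], d)
      best <- best[which.min(lin)]
    }
    cur <- as.integer(nb[best, ])
  }
}

#' Liver-referenced segmentation (group-B annotation scheme)
#'
#' The SUV floor is set to the mean uptake over a PERCIST-style liver
#' reference region (a supplied mask or sphere); segmentation then proceeds
#' as [incrementalConnectedComponents()] and is truncated to the
#' `maxRegions` (default 100) findings of highest SUVmax.
#'
#' @param pet 3-D non-negative SUV array.
#' @param cfg a [segmentationConfig()] with `liverReference` set.
#' @param spacing voxel spacing in mm.
#' @return list of [Finding-class].
#' @export
segmentGroupB <- function(pet, cfg, spacing = c(3, 3, 3)) {
  if (is.null(cfg$liverReference)) {
    stop("configuration error: segmentGroupB requires cfg$liverReference")
  }
  ref <- cfg$liverReference
  d <- dim(pet)
  if (is.matrix(ref)) {
    mask <- ref
  } else {
    # sphere given as center + radius in mm
    r <- ref$radiusMm / spacing
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    keep <- ((g$x - ref$center[1]) / r[1])^2 +
      ((g$y - ref$center[2]) / r[2])^2 +
      ((g$z - ref$center[3]) / r[3])^2 <= 1
    mask <- as.matrix(g[keep, ])
  }
  floorVal <- mean(pet[mask])
  cfg2 <- cfg
  cfg2$suvFloor <- floorVal
  if (is.null(cfg2$maxRegions)) cfg2$maxRegions <- 100L
  incrementalConnectedComponents(pet, cfg2, spacing)
}

#' Automatic generation of nonsuspicious training regions
#'
#' Candidate regions with SUVmax above 1 that the experts did not label
#' suspicious are generated by [incrementalConnectedComponents()] and
#' labelled nonsuspicious (anatomical location left unlabeled). A candidate
#' is excluded when its SUVmax voxel lies inside an expert-suspicious mask or
#' its mask shares any voxel with one. The operation applies only to group-A
#' subjects, or group-B subjects with at most nine expert-suspicious
#' findings (images where every suspicious site is known to be annotated).
#'
#' @param subject a [Subject-class] with expert findings attached.
#' @param cfg a [segmentationConfig()]; its floor is forced to 1.0 SUV.
#' @return list of [Finding-class] with provenance "auto_nonsuspicious"
#'   (possibly empty).
#' @export
generateAutoNonsuspicious <- function(subject, cfg = segmentationConfig()) {
  expSusp <- Filter(function(f) f@labelSuspicious == "suspicious",
    subject@findings)
  if (subject@group == "B" && length(expSusp) > 9) return(list())
  cfg2 <- cfg
  cfg2$suvFloor <- 1.0
  cfg2$maxRegions <- NULL
  pet <- subject@volume@pet
  d <- dim(pet)
  cands <- incrementalConnectedComponents(pet, cfg2,
    spacing = subject@volume@spacing, idPrefix = "auto")
  if (!length(cands)) return(list())
  suspLin <- if (length(expSusp)) {
    sort(unique(unlist(lapply(expSusp, function(f) voxelToLinear(f@mask, d)))))
  } else integer()
  keep <- vapply(cands, function(f) {
    peak <- voxelToLinear(matrix(f@suvMaxVoxel, 1), d)
    if (peak %in% suspLin) return(FALSE)
    !any(voxelToLinear(f@mask, d) %in% suspLin)
  }, TRUE)
  cands <- cands[keep]
  lapply(cands, function(f) {
    f@labelSuspicious <- "nonsuspicious"
    f@provenance <- "auto_nonsuspicious"
    f
  })
}

#' Write findings as a label map plus CSV table
#'
#' @param subject a [Subject-class].
#' @param labelMapPath optional NIfTI path for the integer label map
#'   (finding i gets label i).
#' @param csvPath optional path for the finding table CSV.
#' @return invisibly, the finding table.
#' @export
writeFindings <- function(subject, labelMapPath = NULL, csvPath = NULL) {
  tab <- findingTable(subject)
  if (!is.null(labelMapPath)) {
    d <- dim(subject@volume@pet)
    lab <- array(0L, d)
    for (i in seq_along(subject@findings)) {
      lab[subject@findings[[i]]@mask] <- i
    }
    img <- RNifti::asNifti(lab)
    M <- diag(4); diag(M)[1:3] <- subject@volume@spacing
    M[1:3, 4] <- subject@volume@origin
    RNifti::pixdim(img) <- subject@volume@spacing
    RNifti::qform(img) <- structure(M, code = 2L)
    RNifti::sform(img) <- structure(M, code = 2L)
    RNifti::writeNifti(img, labelMapPath, datatype = "int16")
  }
  if (!is.null(csvPath)) write.csv(tab, csvPath, row.names = FALSE)
  invisible(tab)
}
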