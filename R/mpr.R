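# The fixed anterior-posterior plane offsets (mm) of the 13-plane stack,
# symmetric and denser near the centre plane.
MPR_OFFSETS_MM <- c(-144, -96, -48, -24, -12, -6, 0, 6, 12, 24, 48, 96, 144)

# In-plane sample offsets in voxels: 64 samples spanning 192 mm at 3 mm,
# with the centre voxel at sample position 32.
MPR_INPLANE <- -31:32

#' Extract the 13-plane coronal MPR stack for a finding
#'
#' Samples thirteen coronal planes (constant anterior-posterior coordinate at
#' the fixed offsets -144..+144 mm from the centre voxel) over a
#' 192 mm x 192 mm window centred on the finding's SUVmax position, at the
#' 3 mm working resolution (64 x 64 samples; the centre lands on sample
#' (32, 32)). PET is clamped to [0, 15] SUV and divided by 15; CT is clamped
#' to [-300, 300] HU and mapped affinely to [0, 1]. Samples outside the
#' volume take the window minimum (0 after normalisation).
#'
#' @param vol a [PetCtVolume-class] at 3 mm isotropic spacing.
#' @param center integer(3), 1-based voxel index of the finding's SUVmax.
#' @return An [MprStack-class] (13 x 2 x 64 x 64, values in [0, 1]).
#' @export
extractMpr <- function(vol, center) {
  checkIsotropic3(vol)
  d <- dim(vol@pet)
  center <- as.integer(center)
  stopifnot(all(center >= 1), all(center <= d))
  planes <- array(0, c(13L, 2L, 64L, 64L))
  xs <- center[1] + MPR_INPLANE
  zs <- center[3] + MPR_INPLANE
  okx <- xs >= 1 & xs <= d[1]
  okz <- zs >= 1 & zs <= d[3]
  for (p in seq_along(MPR_OFFSETS_MM)) {
    y <- center[2] + as.integer(MPR_OFFSETS_MM[p] / 3)
    if (y < 1 || y > d[2]) next
    petPlane <- matrix(0, 64, 64)
    ctPlane <- matrix(-300, 64, 64)
    petPlane[okx, okz] <- vol@pet[xs[okx], y, zs[okz]]
    ctPlane[okx, okz] <- vol@ct[xs[okx], y, zs[okz]]
    planes[p, 1, , ] <- windowPet(petPlane)
    planes[p, 2, , ] <- windowCt(ctPlane)
  }
  # planes entirely outside the volume keep PET 0; their CT must also map to
  # the window minimum
  for (p in seq_along(MPR_OFFSETS_MM)) {
    y <- center[2] + as.integer(MPR_OFFSETS_MM[p] / 3)
    if (y < 1 || y > d[2]) planes[p, 2, , ] <- 0
  }
  new("MprStack", planes = planes, offsetsMm = MPR_OFFSETS_MM,
    centerVoxel = center)
}

windowPet <- function(v) pmin(pmax(v, 0), 15) / 15
windowCt <- function(v) (pmin(pmax(v, -300), 300) + 300) / 600

checkIsotropic3 <- function(vol) {
  if (max(abs(vol@spacing - 3)) > 1e-6) {
    stop("volume is not at 3 mm isotropic spacing; run resampleIsotropic() first")
  }
  invisible(TRUE)
}

#' Affine-augmented MPR extraction
#'
#' Draws an isotropic scale s ~ U(0.8, 1.2) and three rotation angles
#' ~ U(-17.2, 17.2) degrees about the patient axes from a seeded generator,
#' applies the affine about the centre position to the sampling coordinates
#' (extrinsic rotations composed in x, y, z order), and re-extracts the
#' 13-plane stack with trilinear interpolation. With the scale and rotation
#' ranges collapsed to the identity the output equals [extractMpr()]
#' bit-exactly.
#'
#' @param vol a [PetCtVolume-class] at 3 mm isotropic spacing.
#' @param center integer(3), SUVmax voxel index.
#' @param seed integer seed for the augmentation draw.
#' @param scaleRange,rotRangeDeg sampling ranges for scale and rotation.
#' @return An [MprStack-class].
#' @export
augmentAffine <- function(vol, center, seed,
                          scaleRange = c(0.8, 1.2),
                          rotRangeDeg = c(-17.2, 17.2)) {
  checkIsotropic3(vol)
  d <- dim(vol@pet)
  center <- as.integer(center)
  draw <- withSeed(seed, {
    list(s = runif(1, scaleRange[1], scaleRange[2]),
      ang = runif(3, rotRangeDeg[1], rotRangeDeg[2]) * pi / 180)
  })
  identityDraw <- draw$s == 1 && all(draw$ang == 0)
  if (identityDraw) return(extractMpr(vol, center))
  R <- rotZ(draw$ang[3]) %*% rotY(draw$ang[2]) %*% rotX(draw$ang[1])
  A <- R * draw$s
  # sampling positions in voxel units relative to the centre (isotropic grid,
  # so voxel-space rotation equals world-space rotation); all 13 planes are
  # gathered in one trilinear call over a cached base grid
  rel <- mprBaseGrid()
  coords <- rel %*% t(A)
  coords[, 1] <- coords[, 1] + center[1]
  coords[, 2] <- coords[, 2] + center[2]
  coords[, 3] <- coords[, 3] + center[3]
  petV <- windowPet(sampleTrilinear(vol@pet, coords, oob = 0))
  ctV <- windowCt(sampleTrilinear(vol@ct, coords, oob = -300))
  planes <- array(0, c(13L, 2L, 64L, 64L))
  planes[, 1, , ] <- aperm(array(petV, c(64, 64, 13)), c(3, 1, 2))
  planes[, 2, , ] <- aperm(array(ctV, c(64, 64, 13)), c(3, 1, 2))
  new("MprStack", planes = planes, offsetsMm = MPR_OFFSETS_MM,
    centerVoxel = center)
}

# cached (13*64*64) x 3 matrix of sampling offsets in voxel units, ordered
# in-plane x fastest, then in-plane z, then plane
.mprGridCache <- new.env(parent = emptyenv())
mprBaseGrid <- function() {
  if (!is.null(.mprGridCache$rel)) return(.mprGridCache$rel)
  nS <- 64L * 64L
  rel <- cbind(
    rep(rep(MPR_INPLANE, 64), 13),
    rep(MPR_OFFSETS_MM / 3, each = nS),
    rep(rep(MPR_INPLANE, each = 64), 13))
  .mprGridCache$rel <- rel
  rel
}

rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# Flatten an MprStack to the network input: a (64*64) x 26 matrix with
# channel c = (plane-1)*2 + modality (PET first).
stackToInput <- function(stack) {
  x <- matrix(0, 64 * 64, 26)
  for (p in 1:13) {
    x[, (p - 1) * 2 + 1] <- as.vector(stack@planes[p, 1, , ])
    x[, (p - 1) * 2 + 2] <- as.vector(stack@planes[p, 2, , ])
  }
  x
}

# Fast path used by training and batch prediction: produces the network
# input matrix directly (identical values to extractMpr/augmentAffine +
# stackToInput, without materialising the MprStack object). `seed = NULL`
# gives the plain (identity) extraction.
trainingInput <- function(vol, center, seed = NULL,
                          scaleRange = c(0.8, 1.2),
                          rotRangeDeg = c(-17.2, 17.2)) {
  center <- as.integer(center)
  rel <- mprBaseGrid()
  if (is.null(seed)) {
    coords <- rel
  } else {
    draw <- withSeed(seed, {
      list(s = runif(1, scaleRange[1], scaleRange[2]),
        ang = runif(3, rotRangeDeg[1], rotRangeDeg[2]) * pi / 180)
    })
    if (draw$s == 1 && all(draw$ang == 0)) {
      coords <- rel
    } else {
      R <- rotZ(draw$ang[3]) %*% rotY(draw$ang[2]) %*% rotX(draw$ang[1])
      coords <- rel %*% t(R * draw$s)
    }
  }
  coords <- coords + rep(center, each = nrow(rel))
  cppExtractStack(vol@pet, vol@ct, dim(vol@pet), coords)
}
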