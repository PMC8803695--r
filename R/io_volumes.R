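#' Load a co-registered PET/CT pair from NIfTI files
#'
#' Reads SUV-calibrated PET and HU CT volumes, reorients both to the package
#' convention (grid axes left-right, anterior-posterior, inferior-superior),
#' and returns them on the PET grid. If the CT grid differs in spacing,
#' origin or shape, the CT is resampled onto the PET grid by trilinear
#' interpolation. Negative PET values are clamped to 0 SUV.
#'
#' @param petPath,ctPath paths to 3-D NIfTI volumes (.nii / .nii.gz).
#' @return A [PetCtVolume-class] on the PET grid.
#' @export
loadVolumePair <- function(petPath, ctPath) {
  pet <- RNifti::readNifti(petPath)
  ct <- RNifti::readNifti(ctPath)
  if (length(dim(pet)) != 3 || length(dim(ct)) != 3) {
    stop("format error: inputs must be 3-D volumes")
  }
  pet <- reorientCanonical(pet)
  ct <- reorientCanonical(ct)
  petGeom <- niftiGeometry(pet)
  ctGeom <- niftiGeometry(ct)
  petArr <- array(as.numeric(pet), dim(pet))
  ctArr <- array(as.numeric(ct), dim(ct))
  sameGrid <- identical(dim(petArr), dim(ctArr)) &&
    max(abs(petGeom$spacing - ctGeom$spacing)) < 1e-6 &&
    max(abs(petGeom$origin - ctGeom$origin)) < 1e-3
  if (!sameGrid) {
    ctArr <- resampleOntoGrid(ctArr, ctGeom, petGeom, dim(petArr))
  }
  PetCtVolume(pet = petArr, ct = ctArr, spacing = petGeom$spacing,
    origin = petGeom$origin)
}

# Reorient an RNifti image so that grid axes run left->right,
# posterior->anterior, inferior->superior (orientation code "LAS" in RNifti's
# RAS-based convention maps axis 1 to L-R). Errors when the affine carries no
# usable orientation.
reorientCanonical <- function(img) {
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA)
  if (is.na(orient) || nchar(orient) != 3) {
    stop("orientation error: cannot determine patient axes from the affine")
  }
  if (orient != "RAS") RNifti::orientation(img) <- "RAS"
  img
}

niftiGeometry <- function(img) {
  M <- RNifti::xform(img)
  spacing <- sqrt(colSums(M[1:3, 1:3]^2))
  list(spacing = as.numeric(spacing), origin = as.numeric(M[1:3, 4]),
    affine = M)
}

# Resample `arr` (geometry `fromGeom`) onto the grid described by `toGeom`
# with dimensions `toDim`, sampling positions clamped to the source extent.
resampleOntoGrid <- function(arr, fromGeom, toGeom, toDim) {
  g <- expand.grid(i = seq_len(toDim[1]), j = seq_len(toDim[2]),
    k = seq_len(toDim[3]))
  world <- cbind(
    toGeom$origin[1] + (g$i - 1) * toGeom$spacing[1],
    toGeom$origin[2] + (g$j - 1) * toGeom$spacing[2],
    toGeom$origin[3] + (g$k - 1) * toGeom$spacing[3])
  src <- cbind(
    (world[, 1] - fromGeom$origin[1]) / fromGeom$spacing[1] + 1,
    (world[, 2] - fromGeom$origin[2]) / fromGeom$spacing[2] + 1,
    (world[, 3] - fromGeom$origin[3]) / fromGeom$spacing[3] + 1)
  d <- dim(arr)
  for (a in 1:3) src[, a] <- pmin(pmax(src[, a], 1), d[a])
  array(sampleTrilinear(arr, src), toDim)
}

#' Write a PET/CT pair to NIfTI files
#'
#' Grids are written at double precision so a write/read round trip
#' reproduces values exactly.
#'
#' @param vol a [PetCtVolume-class].
#' @param petPath,ctPath output paths (.nii or .nii.gz).
#' @return invisibly, the two paths.
#' @export
writeVolumePair <- function(vol, petPath, ctPath) {
  writeOne <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    M <- diag(4)
    diag(M)[1:3] <- vol@spacing
    M[1:3, 4] <- vol@origin
    RNifti::pixdim(img) <- vol@spacing
    RNifti::qform(img) <- structure(M, code = 2L)
    RNifti::sform(img) <- structure(M, code = 2L)
    RNifti::writeNifti(img, path, datatype = "double")
  }
  writeOne(vol@pet, petPath)
  writeOne(vol@ct, ctPath)
  invisible(c(petPath, ctPath))
}

#' Resample a PET/CT pair to an isotropic grid
#'
#' Both channels are resampled by trilinear interpolation onto an isotropic
#' lattice (default 3 mm, the network's working resolution). The world extent
#' is preserved to within one voxel.
#'
#' @param vol a [PetCtVolume-class].
#' @param targetMm target voxel size in mm (default 3).
#' @return A [PetCtVolume-class] at `targetMm` isotropic spacing.
#' @export
resampleIsotropic <- function(vol, targetMm = 3.0) {
  stopifnot(targetMm > 0)
  d <- dim(vol@pet)
  if (any(d < 2)) {
    stop(sprintf("degenerate axis %d: a single-slice axis cannot be resampled",
      which(d < 2)[1]))
  }
  if (max(abs(vol@spacing - targetMm)) < 1e-9) {
    return(vol)
  }
  extent <- d * vol@spacing
  newDim <- pmax(2L, as.integer(round(extent / targetMm)))
  fromGeom <- list(spacing = vol@spacing, origin = vol@origin)
  toGeom <- list(spacing = rep(targetMm, 3), origin = vol@origin)
  pet <- resampleOntoGrid(vol@pet, fromGeom, toGeom, newDim)
  ct <- resampleOntoGrid(vol@ct, fromGeom, toGeom, newDim)
  PetCtVolume(pet = pet, ct = ct, spacing = rep(targetMm, 3),
    origin = vol@origin, axes = vol@axes)
}
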