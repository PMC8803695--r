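#' @import methods
NULL

#' Co-registered PET/CT volume pair
#'
#' Holds a PET grid in standardized uptake value (SUV) units and a CT grid in
#' Hounsfield units (HU) on a common voxel lattice, together with the
#' geometry needed to map voxel indices to patient (LPS) world coordinates.
#' Voxel indices are 1-based throughout the package; world coordinates are
#' millimetres.
#'
#' @slot pet 3-D numeric array, SUV, non-negative.
#' @slot ct 3-D numeric array, HU, same dimensions as `pet`.
#' @slot spacing numeric(3), voxel size in mm per axis, all positive.
#' @slot origin numeric(3), world position (mm) of voxel (1,1,1).
#' @slot axes character(3), patient axis carried by each grid axis; the
#'   package convention is `c("LR","AP","IS")`: axis 1 left-right, axis 2
#'   anterior-posterior, axis 3 inferior-superior.
#' @export
setClass("PetCtVolume",
  representation(
    pet = "array", ct = "array",
    spacing = "numeric", origin = "numeric", axes = "character"
  ),
  prototype(
    spacing = c(3, 3, 3), origin = c(0, 0, 0), axes = c("LR", "AP", "IS")
  )
)

setValidity("PetCtVolume", function(object) {
  msg <- character()
  if (length(dim(object@pet)) != 3) msg <- c(msg, "pet must be a 3-D array")
  if (!identical(dim(object@pet), dim(object@ct))) {
    msg <- c(msg, "pet and ct must have identical dimensions")
  }
  if (length(object@spacing) != 3 || any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be three positive values (mm)")
  }
  if (length(object@origin) != 3) msg <- c(msg, "origin must be length 3")
  if (any(object@pet < 0)) msg <- c(msg, "pet values must be >= 0 (SUV)")
  if (length(msg)) msg else TRUE
})

#' Construct a PetCtVolume
#'
#' Negative PET values (reconstruction noise) are clamped to 0 SUV.
#'
#' @param pet,ct 3-D numeric arrays of identical dimension (SUV / HU).
#' @param spacing voxel size in mm per axis.
#' @param origin world position (mm) of voxel (1,1,1).
#' @param axes patient axis labels per grid axis.
#' @return A [PetCtVolume-class] object.
#' @export
PetCtVolume <- function(pet, ct, spacing = c(3, 3, 3), origin = c(0, 0, 0),
                        axes = c("LR", "AP", "IS")) {
  pet[pet < 0] <- 0
  new("PetCtVolume", pet = pet, ct = ct, spacing = as.numeric(spacing),
    origin = as.numeric(origin), axes = axes)
}

#' One contiguous uptake region
#'
#' The atomic unit the classifier is trained on and staging counts: a
#' 26-connected voxel set with its SUVmax, labels and provenance.
#'
#' @slot findingId character scalar identifier.
#' @slot mask integer matrix (n x 3) of 1-based voxel indices.
#' @slot suvMax maximum PET value over the mask.
#' @slot suvMaxVoxel integer(3), voxel index attaining `suvMax`.
#' @slot volumeMl region volume in millilitres.
#' @slot labelSuspicious one of "suspicious", "nonsuspicious", "unlabeled".
#' @slot labelLocation anatomical class name or NA when unlabeled.
#' @slot provenance one of "expert", "auto_nonsuspicious", "candidate".
#' @export
setClass("Finding",
  representation(
    findingId = "character", mask = "matrix", suvMax = "numeric",
    suvMaxVoxel = "integer", volumeMl = "numeric",
    labelSuspicious = "character", labelLocation = "character",
    provenance = "character"
  )
)

setValidity("Finding", function(object) {
  msg <- character()
  if (nrow(object@mask) < 1) msg <- c(msg, "mask must be non-empty")
  if (ncol(object@mask) != 3) msg <- c(msg, "mask must have 3 columns")
  if (!object@labelSuspicious %in% c("suspicious", "nonsuspicious", "unlabeled")) {
    msg <- c(msg, "invalid labelSuspicious")
  }
  if (!object@provenance %in% c("expert", "auto_nonsuspicious", "candidate")) {
    msg <- c(msg, "invalid provenance")
  }
  if (length(msg)) msg else TRUE
})

# Internal constructor: derives suvMax / suvMaxVoxel / volumeMl from the
# PET grid so the Finding invariants hold by construction.
makeFinding <- function(id, mask, pet, spacing,
                        labelSuspicious = "unlabeled",
                        labelLocation = NA_character_,
                        provenance = "candidate") {
  storage.mode(mask) <- "integer"
  vals <- pet[mask]
  i <- which.max(vals)
  new("Finding",
    findingId = as.character(id), mask = mask,
    suvMax = vals[i], suvMaxVoxel = as.integer(mask[i, ]),
    volumeMl = nrow(mask) * prod(spacing) / 1000,
    labelSuspicious = labelSuspicious,
    labelLocation = as.character(labelLocation),
    provenance = provenance)
}

# index Finding masks with pet[mask] -- mask is a 3-col index matrix
setMethod("show", "Finding", function(object) {
  cat(sprintf(
    "Finding %s: %d voxels, SUVmax %.2f at (%s), %.2f ml, %s/%s [%s]\n",
    object@findingId, nrow(object@mask), object@suvMax,
    paste(object@suvMaxVoxel, collapse = ","), object@volumeMl,
    object@labelSuspicious,
    ifelse(is.na(object@labelLocation), "-", object@labelLocation),
    object@provenance))
})

#' A subject: tracer, volume and findings
#'
#' @slot subjectId character scalar.
#' @slot tracer "PSMA" or "FDG".
#' @slot volume a [PetCtVolume-class].
#' @slot findings list of [Finding-class].
#' @slot group annotation scheme tag, "A" or "B".
#' @export
setClass("Subject",
  representation(
    subjectId = "character", tracer = "character",
    volume = "PetCtVolume", findings = "list", group = "character"
  ),
  prototype(group = "A")
)

setValidity("Subject", function(object) {
  msg <- character()
  if (!object@tracer %in% c("PSMA", "FDG")) {
    msg <- c(msg, "tracer must be 'PSMA' or 'FDG'")
  }
  if (!object@group %in% c("A", "B")) msg <- c(msg, "group must be 'A' or 'B'")
  d <- dim(object@volume@pet)
  for (f in object@findings) {
    if (!is(f, "Finding")) { msg <- c(msg, "findings must be Finding objects"); break }
    if (any(f@mask < 1) || any(t(f@mask) > d)) {
      msg <- c(msg, "finding mask outside volume bounds"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Subject
#' @param subjectId identifier.
#' @param tracer "PSMA" or "FDG".
#' @param volume a [PetCtVolume-class].
#' @param findings list of [Finding-class] objects.
#' @param group annotation scheme tag ("A" or "B").
#' @export
Subject <- function(subjectId, tracer, volume, findings = list(), group = "A") {
  new("Subject", subjectId = as.character(subjectId), tracer = tracer,
    volume = volume, findings = findings, group = group)
}

setMethod("show", "Subject", function(object) {
  d <- dim(object@volume@pet)
  cat(sprintf("Subject %s [%s, group %s]: volume %dx%dx%d, %d findings\n",
    object@subjectId, object@tracer, object@group, d[1], d[2], d[3],
    length(object@findings)))
})

#' The 13-plane two-channel network input
#'
#' Thirteen coronal multiplanar reformations (192 mm x 192 mm, 64 x 64
#' samples at 3 mm), two channels (PET, CT), windowed and normalised to
#' [0, 1], centred on a finding's SUVmax position.
#'
#' @slot planes numeric array 13 x 2 x 64 x 64.
#' @slot offsetsMm the 13 anterior-posterior plane offsets in mm.
#' @slot centerVoxel integer(3), the finding's SUVmax voxel.
#' @export
setClass("MprStack",
  representation(planes = "array", offsetsMm = "numeric",
    centerVoxel = "integer")
)

setValidity("MprStack", function(object) {
  msg <- character()
  if (!identical(dim(object@planes), c(13L, 2L, 64L, 64L))) {
    msg <- c(msg, "planes must be 13 x 2 x 64 x 64")
  }
  if (length(object@offsetsMm) != 13) msg <- c(msg, "need 13 offsets")
  rng <- range(object@planes)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1) {
    msg <- c(msg, "plane values must lie in [0,1] with no NAs")
  }
  if (length(msg)) msg else TRUE
})

#' PROMISE miTNM N/M stage for one subject
#'
#' @slot nStage "N0", "N1" or "N2" (regional nodes: none / single / multiple).
#' @slot mStage "M0", "M1a", "M1b_u", "M1b_o", "M1b_d" or "M1c".
#' @slot counts named integer vector of per-role finding counts.
#' @export
setClass("StageResult",
  representation(nStage = "character", mStage = "character",
    counts = "integer")
)

setValidity("StageResult", function(object) {
  msg <- character()
  if (!object@nStage %in% c("N0", "N1", "N2")) msg <- c(msg, "invalid nStage")
  if (!object@mStage %in% c("M0", "M1a", "M1b_u", "M1b_o", "M1b_d", "M1c")) {
    msg <- c(msg, "invalid mStage")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "StageResult", function(object) {
  cat(sprintf("miTNM stage: %s %s (counts: %s)\n", object@nStage,
    object@mStage,
    paste(names(object@counts), object@counts, sep = "=", collapse = ", ")))
})

setMethod("show", "PetCtVolume", function(object) {
  d <- dim(object@pet)
  cat(sprintf(
    "PetCtVolume %dx%dx%d @ (%g, %g, %g) mm; SUV range [%.2f, %.2f]; HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3],
    min(object@pet), max(object@pet), min(object@ct), max(object@ct)))
})

setMethod("show", "MprStack", function(object) {
  cat(sprintf("MprStack: 13 planes x 2 ch x 64 x 64, centred at (%s), value range [%.3f, %.3f]\n",
    paste(object@centerVoxel, collapse = ","),
    min(object@planes), max(object@planes)))
})

#' @rdname accessors
#' @param object a package object.
#' @export
setGeneric("petGrid", function(object) standardGeneric("petGrid"))
#' @rdname accessors
#' @export
setGeneric("ctGrid", function(object) standardGeneric("ctGrid"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("suvMax", function(object) standardGeneric("suvMax"))
#' @rdname accessors
#' @export
setGeneric("findingMask", function(object) standardGeneric("findingMask"))
#' @rdname accessors
#' @export
setGeneric("findings", function(object) standardGeneric("findings"))
#' @rdname accessors
#' @export
setGeneric("nStage", function(object) standardGeneric("nStage"))
#' @rdname accessors
#' @export
setGeneric("mStage", function(object) standardGeneric("mStage"))

#' Accessors for package classes
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
setMethod("petGrid", "PetCtVolume", function(object) object@pet)
#' @rdname accessors
setMethod("ctGrid", "PetCtVolume", function(object) object@ct)
#' @rdname accessors
setMethod("voxelSpacing", "PetCtVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("suvMax", "Finding", function(object) object@suvMax)
#' @rdname accessors
setMethod("findingMask", "Finding", function(object) object@mask)
#' @rdname accessors
setMethod("findings", "Subject", function(object) object@findings)
#' @rdname accessors
setMethod("nStage", "StageResult", function(object) object@nStage)
#' @rdname accessors
setMethod("mStage", "StageResult", function(object) object@mStage)

#' Tabulate a subject's findings
#'
#' @param subject a [Subject-class].
#' @return data.frame with one row per finding (id, SUVmax, SUVmax voxel,
#'   volume, labels, provenance).
#' @export
findingTable <- function(subject) {
  fs <- subject@findings
  if (!length(fs)) {
    return(data.frame(findingId = character(), suvMax = numeric(),
      x = integer(), y = integer(), z = integer(), volumeMl = numeric(),
      labelSuspicious = character(), labelLocation = character(),
      provenance = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    findingId = vapply(fs, function(f) f@findingId, ""),
    suvMax = vapply(fs, function(f) f@suvMax, 0),
    x = vapply(fs, function(f) f@suvMaxVoxel[1], 0L),
    y = vapply(fs, function(f) f@suvMaxVoxel[2], 0L),
    z = vapply(fs, function(f) f@suvMaxVoxel[3], 0L),
    volumeMl = vapply(fs, function(f) f@volumeMl, 0),
    labelSuspicious = vapply(fs, function(f) f@labelSuspicious, ""),
    labelLocation = vapply(fs, function(f) f@labelLocation, ""),
    provenance = vapply(fs, function(f) f@provenance, ""),
    stringsAsFactors = FALSE)
}
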