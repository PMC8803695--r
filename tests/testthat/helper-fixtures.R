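# Fixture builders shared across test files; everything is generated in
# code at test time.

# Isotropic Gaussian blob on a zero background.
blobVolume <- function(d = c(32, 32, 32), center = d / 2, peak = 10,
                       sigma = 2) {
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(peak * exp(-r2 / (2 * sigma^2)), d)
}

# Smoothed random non-negative SUV field with a controlled maximum.
randomSuvField <- function(d = c(32, 32, 32), seed = 1, peak = 8,
                           sigma = 2.5) {
  set.seed(seed)
  x <- array(rnorm(prod(d)), d)
  ns <- asNamespace("petstage")
  x <- ns$gaussianBlur3d(abs(x), sigma)
  x * (peak / max(x))
}

# A minimal PetCtVolume at 3 mm spacing around a given PET grid.
petCt <- function(pet, ct = NULL, spacing = c(3, 3, 3)) {
  if (is.null(ct)) ct <- array(0, dim(pet))
  PetCtVolume(pet = pet, ct = ct, spacing = spacing)
}

# A tiny labelled subject built from explicit finding descriptions:
# each entry list(center, peak, suspicious, location).
tinySubject <- function(id = "s1", tracer = "PSMA", d = c(24, 24, 24),
                        blobs = list(), group = "A") {
  pet <- array(0, d)
  for (b in blobs) {
    pet <- pet + blobVolume(d, b$center, b$peak, sigma = 1.5)
  }
  vol <- petCt(pet)
  fs <- list()
  ns <- asNamespace("petstage")
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    peakVox <- b$center
    comp <- ns$connectedComponent(pet >= 0.45 * pet[matrix(peakVox, 1)],
      peakVox, 26)
    fs[[i]] <- ns$makeFinding(sprintf("%s_f%d", id, i), comp, pet, c(3, 3, 3),
      labelSuspicious = if (isTRUE(b$suspicious)) "suspicious" else "nonsuspicious",
      labelLocation = b$location %||% NA_character_,
      provenance = "expert")
  }
  Subject(id, tracer, vol, fs, group = group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
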