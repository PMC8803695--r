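#' @importFrom stats rnorm runif quantile sd pnorm setNames aggregate
#' @importFrom utils head read.csv write.csv packageVersion
#' @importFrom Rcpp evalCpp
#' @useDynLib petstage, .registration = TRUE
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic code in the package goes
# through this so that user-visible seeds compose deterministically.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index; keeps every
# derived seed a valid 32-bit integer.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973 + 7) %%
    2147483647)
}

#' Trilinear sampling of a 3-D array at fractional voxel coordinates
#'
#' Samples `arr` at `coords` (an n x 3 matrix of 1-based, possibly fractional
#' voxel coordinates). Coordinates outside the grid return `oob`.
#' Sampling at exact integer coordinates returns the stored value exactly.
#'
#' @param arr 3-D numeric array.
#' @param coords n x 3 numeric matrix of voxel coordinates (1-based).
#' @param oob value used for samples outside the array extent.
#' @return numeric vector of length `nrow(coords)`.
#' @keywords internal
sampleTrilinear <- function(arr, coords, oob = 0) {
  cppTrilinear(arr, dim(arr), coords, oob)
}

# Separable 3-D Gaussian blur via banded matrix products along each axis.
# `sigmaVox` is the standard deviation in voxels (scalar or length 3).
# Kernel rows are renormalised at the borders so constants are preserved.
gaussianBlur3d <- function(arr, sigmaVox) {
  if (length(sigmaVox) == 1) sigmaVox <- rep(sigmaVox, 3)
  d <- dim(arr)
  blur1 <- function(n, sigma) {
    if (sigma <= 0) return(diag(n))
    r <- max(1L, ceiling(3 * sigma))
    pos <- seq_len(n)
    K <- outer(pos, pos, function(i, j) {
      w <- exp(-((i - j)^2) / (2 * sigma^2))
      w[abs(i - j) > r] <- 0
      w
    })
    K / rowSums(K)
  }
  # axis 1
  if (sigmaVox[1] > 0) {
    K <- blur1(d[1], sigmaVox[1])
    arr <- array(K %*% matrix(arr, d[1]), d)
  }
  # axis 2
  if (sigmaVox[2] > 0) {
    K <- blur1(d[2], sigmaVox[2])
    a <- aperm(arr, c(2, 1, 3))
    a <- array(K %*% matrix(a, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2, 1, 3))
  }
  # axis 3
  if (sigmaVox[3] > 0) {
    K <- blur1(d[3], sigmaVox[3])
    a <- aperm(arr, c(3, 1, 2))
    a <- array(K %*% matrix(a, d[3]), c(d[3], d[1], d[2]))
    arr <- aperm(a, c(2, 3, 1))
  }
  arr
}

# 26- or 6-neighbourhood integer offsets (k x 3 matrix, excludes the origin).
neighbourOffsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  storage.mode(g) <- "integer"
  unname(g)
}

# Convert voxel index matrix (n x 3, 1-based) to linear indices for dim `d`.
voxelToLinear <- function(vox, d) {
  as.integer(vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2])
}

linearToVoxel <- function(lin, d) {
  lin0 <- lin - 1L
  x <- lin0 %% d[1]
  y <- (lin0 %/% d[1]) %% d[2]
  z <- lin0 %/% (d[1] * d[2])
  cbind(x + 1L, y + 1L, z + 1L)
}

# Connected component of `eligible` voxels containing `seedVox`, by BFS.
# Returns an n x 3 integer matrix of voxel indices (includes the seed).
connectedComponent <- function(eligible, seedVox, connectivity = 26) {
  cppFloodFill(eligible, dim(eligible), as.integer(seedVox),
    as.integer(connectivity))
}

percentRound1 <- function(x) round(x, 1)
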