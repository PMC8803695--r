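# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Pure-R trilinear interpolation (border-clamped support, oob fill).
oracleTrilinear <- function(arr, coords, oob = 0) {
  d <- dim(arr)
  n <- nrow(coords)
  out <- numeric(n)
  for (r in seq_len(n)) {
    x <- coords[r, 1]; y <- coords[r, 2]; z <- coords[r, 3]
    if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3]) {
      out[r] <- oob
      next
    }
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    cl <- function(v, nmax) min(max(v, 1), nmax)
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx == 0) 1 - fx else fx) *
        (if (dy == 0) 1 - fy else fy) *
        (if (dz == 0) 1 - fz else fz)
      if (w > 0) {
        acc <- acc + w * arr[cl(x0 + dx, d[1]), cl(y0 + dy, d[2]),
          cl(z0 + dz, d[3])]
      }
    }
    out[r] <- acc
  }
  out
}

# Brute-force incremental connected-component segmentation: at every
# iteration rescan the whole grid for the unassigned maximum and flood-fill
# recursively from it. Returns a list of linear-index vectors.
oracleSegment <- function(pet, frac = 0.45, floor = 1.0, connectivity = 26) {
  d <- dim(pet)
  assigned <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  comps <- list()
  repeat {
    work <- pet
    work[assigned] <- -Inf
    bestLin <- which.max(work)
    best <- work[bestLin]
    if (!is.finite(best) || best <= floor) break
    t <- frac * best
    # flood fill with a preallocated queue and membership array
    inComp <- array(FALSE, d)
    queue <- integer(length(pet))
    queue[1] <- bestLin
    inComp[bestLin] <- TRUE
    head <- 1L; tail <- 1L
    while (head <= tail) {
      lin <- queue[head]; head <- head + 1L
      lin0 <- lin - 1
      vox <- c(lin0 %% d[1], (lin0 %/% d[1]) %% d[2],
        lin0 %/% (d[1] * d[2])) + 1
      for (k in seq_len(nrow(offs))) {
        nb <- vox + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        nlin <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (!assigned[nlin] && !inComp[nlin] && pet[nlin] >= t) {
          inComp[nlin] <- TRUE
          tail <- tail + 1L
          queue[tail] <- nlin
        }
      }
    }
    comp <- queue[seq_len(tail)]
    comps[[length(comps) + 1]] <- as.integer(sort(unname(comp)))
    assigned[comp] <- TRUE
  }
  comps
}

# Exhaustive-threshold average precision: walk every distinct score as a
# threshold and integrate the precision-recall steps directly.
oracleAveragePrecision <- function(scores, labels) {
  labels <- as.integer(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  prevR <- 0
  ap <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / sum(labels)
    ap <- ap + (rec - prevR) * prec
    prevR <- rec
  }
  100 * ap
}

# Literal enumeration of the miTNM rules from the role counts.
oracleStage <- function(r, a, b, cc) {
  n <- if (r == 0) "N0" else if (r == 1) "N1" else "N2"
  m <- if (cc >= 1) "M1c"
  else if (b >= 4) "M1b_d"
  else if (b >= 2 && b <= 3) "M1b_o"
  else if (b == 1) "M1b_u"
  else if (a >= 1) "M1a"
  else "M0"
  c(n, m)
}
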