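#' Model configuration for the multi-task uptake classifier
#'
#' The network is a shared convolutional trunk over the 26-channel 64 x 64
#' MPR input (13 planes x 2 modalities) followed by two fully connected
#' heads: a suspicious head ending in a single sigmoid output and a location
#' head ending in a softmax over the anatomical classes. When
#' `dualTracer = TRUE`, a binary tracer-type input is concatenated to the
#' first fully connected layer of the suspicious head only; the location
#' head never receives it.
#'
#' @param convBlocks number of conv(3x3) + ReLU + maxpool(2x2) blocks.
#' @param baseFilters filters in the first block; doubled each block.
#' @param fcWidth width of the hidden fully connected layer in each head.
#' @param nLocationClasses number of anatomical location classes (>= 2).
#' @param dualTracer wire the tracer bit into the suspicious head.
#' @param dropout dropout fraction on head hidden layers during training.
#' @param finalPool spatial size after adaptive average pooling of the last
#'   feature map (features = last filter count x finalPool^2).
#' @param convFilters optional explicit filter counts per block (overrides
#'   `convBlocks`/`baseFilters`).
#' @param lossWeights length-2 weights for (suspicious, location) losses.
#' @param posWeight multiplier on the suspicious-class term of the binary
#'   cross-entropy, countering the strong nonsuspicious majority among
#'   training findings (default 1 = unweighted).
#' @return A classed list of settings.
#' @export
modelConfig <- function(convBlocks = 4, baseFilters = 16, fcWidth = 128,
                        nLocationClasses = 2, dualTracer = FALSE,
                        dropout = 0, finalPool = 4, convFilters = NULL,
                        lossWeights = c(1, 1), posWeight = 1) {
  if (is.null(convFilters)) {
    convFilters <- baseFilters * 2^(seq_len(convBlocks) - 1)
  }
  if (nLocationClasses < 2) stop("nLocationClasses must be >= 2")
  if (any(c(convFilters, fcWidth, finalPool) <= 0)) {
    stop("filter counts, fcWidth and finalPool must be positive")
  }
  spatial <- 64 / 2^length(convFilters)
  if (spatial < 1 || spatial != round(spatial)) {
    stop("build error: too many conv blocks for the 64 x 64 input")
  }
  if (spatial %% finalPool != 0 && finalPool <= spatial) {
    stop("build error: finalPool must divide the final spatial size ", spatial)
  }
  if (finalPool > spatial) finalPool <- spatial
  structure(list(
    convFilters = as.integer(convFilters), fcWidth = as.integer(fcWidth),
    nLocationClasses = as.integer(nLocationClasses),
    dualTracer = isTRUE(dualTracer), dropout = dropout,
    finalPool = as.integer(finalPool), inputChannels = 26L,
    inputSize = 64L, lossWeights = lossWeights,
    posWeight = posWeight), class = "ModelConfig")
}

# im2col gather indices for an n x n plane with 3x3 kernel, zero padding 1.
# Returns an (n^2 x 9) integer matrix of row indices into the padded input
# (row n^2 + 1 is the zero row). Cached per size.
.im2colCache <- new.env(parent = emptyenv())
im2colIndex <- function(n) {
  key <- as.character(n)
  if (!is.null(.im2colCache[[key]])) return(.im2colCache[[key]])
  pos <- expand.grid(i = seq_len(n), j = seq_len(n))
  offs <- expand.grid(di = -1:1, dj = -1:1)
  idx <- matrix(n * n + 1L, n * n, 9)
  for (k in 1:9) {
    si <- pos$i + offs$di[k]
    sj <- pos$j + offs$dj[k]
    ok <- si >= 1 & si <= n & sj >= 1 & sj <= n
    idx[ok, k] <- as.integer(si[ok] + (sj[ok] - 1L) * n)
  }
  .im2colCache[[key]] <- idx
  idx
}

# average-pool gather indices from n x n down to m x m (factor f = n/m):
# (m^2 x f^2) matrix of row indices. Cached.
.avgCache <- new.env(parent = emptyenv())
avgPoolIndex <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.avgCache[[key]])) return(.avgCache[[key]])
  f <- n %/% m
  pos <- expand.grid(i = seq_len(m), j = seq_len(m))
  offs <- expand.grid(di = seq_len(f) - 1L, dj = seq_len(f) - 1L)
  idx <- matrix(0L, m * m, f * f)
  for (k in seq_len(f * f)) {
    si <- (pos$i - 1L) * f + 1L + offs$di[k]
    sj <- (pos$j - 1L) * f + 1L + offs$dj[k]
    idx[, k] <- as.integer(si + (sj - 1L) * n)
  }
  .avgCache[[key]] <- idx
  idx
}

heInit <- function(nr, nc, fanIn) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
}

#' Build the multi-task classifier
#'
#' Parameters are initialised from a seeded generator (He-scaled normal
#' weights, zero biases), so the same seed always yields identical tensors.
#'
#' @param cfg a [modelConfig()].
#' @param seed integer init seed.
#' @return A classed list (`PetstageModel`) holding the configuration and
#'   all weight tensors.
#' @export
buildModel <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "ModelConfig"))
  nF <- cfg$convFilters
  feat <- nF[length(nF)] * cfg$finalPool^2
  w <- withSeed(seed, {
    w <- list()
    cin <- cfg$inputChannels
    for (b in seq_along(nF)) {
      w[[paste0("conv", b, "W")]] <- heInit(9 * cin, nF[b], 9 * cin)
      w[[paste0("conv", b, "b")]] <- numeric(nF[b])
      cin <- nF[b]
    }
    dIn <- feat + as.integer(cfg$dualTracer)
    w$suspW1 <- heInit(dIn, cfg$fcWidth, dIn)
    w$suspB1 <- numeric(cfg$fcWidth)
    w$suspW2 <- heInit(cfg$fcWidth, 1, cfg$fcWidth)
    w$suspB2 <- numeric(1)
    w$locW1 <- heInit(feat, cfg$fcWidth, feat)
    w$locB1 <- numeric(cfg$fcWidth)
    w$locW2 <- heInit(cfg$fcWidth, cfg$nLocationClasses, cfg$fcWidth)
    w$locB2 <- numeric(cfg$nLocationClasses)
    w
  })
  structure(list(cfg = cfg, weights = w, locationClasses = NULL),
    class = "PetstageModel")
}

#' @export
print.PetstageModel <- function(x, ...) {
  nPar <- sum(vapply(x$weights, length, 0L))
  cat(sprintf(
    "PetstageModel: %d conv blocks (%s filters), fcWidth %d, %d location classes, %s; %d parameters\n",
    length(x$cfg$convFilters), paste(x$cfg$convFilters, collapse = "/"),
    x$cfg$fcWidth, x$cfg$nLocationClasses,
    if (x$cfg$dualTracer) "dual-tracer" else "single-tracer", nPar))
  invisible(x)
}

# Forward pass for one sample.
# x: (64*64 x 26) matrix; tracer: 0/1; returns activations cache when
# `keep = TRUE` (needed for the backward pass).
cnnForward <- function(model, x, tracer = 0, keep = FALSE,
                       dropMaskSusp = NULL, dropMaskLoc = NULL) {
  cfg <- model$cfg
  w <- model$weights
  n <- cfg$inputSize
  a <- x
  cache <- list(P = list(), mask = list(), poolSrc = list(), sizes = integer())
  for (b in seq_along(cfg$convFilters)) {
    idx <- im2colIndex(n)
    blk <- cppConvForward(a, idx, w[[paste0("conv", b, "W")]],
      w[[paste0("conv", b, "b")]], n)
    if (keep) {
      cache$P[[b]] <- blk$P
      cache$mask[[b]] <- blk$mask
      cache$poolSrc[[b]] <- blk$src
      cache$sizes[b] <- n
    }
    a <- blk$M
    n <- n %/% 2L
  }
  # adaptive average pooling to finalPool x finalPool
  if (n > cfg$finalPool) {
    gi <- avgPoolIndex(n, cfg$finalPool)
    f2 <- ncol(gi)
    Mp <- matrix(0, nrow(gi), ncol(a))
    for (k in seq_len(f2)) Mp <- Mp + a[gi[, k], , drop = FALSE]
    if (keep) { cache$avgFrom <- n; cache$avgIdx <- gi }
    a <- Mp / f2
  } else if (keep) {
    cache$avgFrom <- NULL
  }
  feat <- as.vector(a)
  featS <- if (cfg$dualTracer) c(feat, tracer) else feat
  h1 <- as.vector(featS %*% w$suspW1) + w$suspB1
  r1 <- h1 > 0
  h1 <- h1 * r1
  if (!is.null(dropMaskSusp)) h1 <- h1 * dropMaskSusp
  zS <- sum(h1 * w$suspW2) + w$suspB2
  g1 <- as.vector(feat %*% w$locW1) + w$locB1
  rg <- g1 > 0
  g1 <- g1 * rg
  if (!is.null(dropMaskLoc)) g1 <- g1 * dropMaskLoc
  zL <- as.vector(g1 %*% w$locW2) + w$locB2
  pS <- 1 / (1 + exp(-zS))
  eL <- exp(zL - max(zL))
  pL <- eL / sum(eL)
  out <- list(pSuspicious = as.numeric(pS), locationProbs = pL, zS = zS, zL = zL)
  if (keep) {
    cache$feat <- feat; cache$featS <- featS
    cache$h1 <- h1; cache$r1 <- r1; cache$g1 <- g1; cache$rg <- rg
    cache$dropS <- dropMaskSusp; cache$dropL <- dropMaskLoc
    cache$lastSpatial <- n
    out$cache <- cache
  }
  out
}

# Backward pass for one sample; returns gradients for every weight tensor.
# dzS: scalar gradient of the loss w.r.t. the suspicious logit.
# dzL: length-K gradient w.r.t. the location logits (zero vector when the
# location label is masked).
cnnBackward <- function(model, fwd, dzS, dzL) {
  cfg <- model$cfg
  w <- model$weights
  cache <- fwd$cache
  g <- list()
  # suspicious head
  dh1 <- dzS * as.vector(w$suspW2)
  if (!is.null(cache$dropS)) dh1 <- dh1 * cache$dropS
  dh1 <- dh1 * cache$r1
  g$suspW2 <- matrix(cache$h1 * dzS, ncol = 1)
  g$suspB2 <- dzS
  g$suspW1 <- outer(cache$featS, dh1)
  g$suspB1 <- dh1
  dFeatS <- as.vector(w$suspW1 %*% dh1)
  nFeat <- length(cache$feat)
  dFeat <- dFeatS[seq_len(nFeat)]
  # location head
  dg1 <- as.vector(w$locW2 %*% dzL)
  if (!is.null(cache$dropL)) dg1 <- dg1 * cache$dropL
  dg1 <- dg1 * cache$rg
  g$locW2 <- outer(cache$g1, dzL)
  g$locB2 <- dzL
  g$locW1 <- outer(cache$feat, dg1)
  g$locB1 <- dg1
  dFeat <- dFeat + as.vector(w$locW1 %*% dg1)
  # un-flatten to the pooled map
  nF <- cfg$convFilters
  Flast <- nF[length(nF)]
  dA <- matrix(dFeat, cfg$finalPool^2, Flast)
  # average-pool backward
  if (!is.null(cache$avgFrom)) {
    n <- cache$avgFrom
    gi <- cache$avgIdx
    f2 <- ncol(gi)
    dUp <- matrix(0, n * n, Flast)
    for (k in seq_len(f2)) dUp[gi[, k], ] <- dUp[gi[, k], ] + dA / f2
    dA <- dUp
  }
  # conv blocks in reverse
  for (b in rev(seq_along(nF))) {
    n <- cache$sizes[b]
    bwd <- cppConvBackward(dA, cache$poolSrc[[b]], cache$mask[[b]],
      cache$P[[b]], w[[paste0("conv", b, "W")]], im2colIndex(n),
      if (b > 1) nF[b - 1] else cfg$inputChannels, b > 1)
    g[[paste0("conv", b, "W")]] <- bwd$dW
    g[[paste0("conv", b, "b")]] <- as.numeric(bwd$db)
    if (b > 1) dA <- bwd$dX
  }
  g
}

# Loss and gradients for one labelled example.
# y: 0/1 suspicious label; locClass: 1-based class index or NA (masked).
cnnLossGrad <- function(model, x, tracer, y, locClass, dropout = 0) {
  cfg <- model$cfg
  maskS <- maskL <- NULL
  if (dropout > 0) {
    maskS <- (runif(cfg$fcWidth) >= dropout) / (1 - dropout)
    maskL <- (runif(cfg$fcWidth) >= dropout) / (1 - dropout)
  }
  fwd <- cnnForward(model, x, tracer, keep = TRUE,
    dropMaskSusp = maskS, dropMaskLoc = maskL)
  wS <- cfg$lossWeights[1]; wL <- cfg$lossWeights[2]
  pw <- if (is.null(cfg$posWeight)) 1 else cfg$posWeight
  eps <- 1e-12
  clsW <- if (y == 1) pw else 1
  lossS <- -clsW * (y * log(fwd$pSuspicious + eps) +
      (1 - y) * log(1 - fwd$pSuspicious + eps))
  dzS <- wS * clsW * (fwd$pSuspicious - y)
  K <- cfg$nLocationClasses
  if (is.na(locClass)) {
    lossL <- 0
    dzL <- numeric(K)
  } else {
    lossL <- -log(fwd$locationProbs[locClass] + eps)
    dzL <- wL * fwd$locationProbs
    dzL[locClass] <- dzL[locClass] - wL
  }
  grads <- cnnBackward(model, fwd, dzS, dzL)
  list(loss = wS * lossS + wL * lossL, lossS = lossS, lossL = lossL,
    grads = grads, pSuspicious = fwd$pSuspicious)
}

# Adam optimizer state and update.
adamInit <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
    v = lapply(weights, function(w) w * 0), t = 0)
}

adamStep <- function(weights, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(weights)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

sumGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scaleGrads <- function(g, s) lapply(g, function(x) x * s)

#' Classify one MPR stack
#'
#' Deterministic evaluation-mode forward pass. The location label is the
#' argmax of the class probabilities (ties resolved to the first class
#' index); the suspicious decision uses `threshold` (default 0.5).
#'
#' @param model a model from [buildModel()] or [trainModel()].
#' @param stack an [MprStack-class].
#' @param tracer "PSMA" or "FDG" (used only by dual-tracer models).
#' @param threshold decision threshold on the suspicious probability.
#' @return list with `pSuspicious`, `locationProbs`, `suspicious` (logical)
#'   and `locationLabel` (class name when the model carries a class list,
#'   else the class index).
#' @export
predictFinding <- function(model, stack, tracer = "PSMA", threshold = 0.5) {
  x <- if (is(stack, "MprStack")) stackToInput(stack) else stack
  if (!identical(dim(x), c(64L * 64L, 26L)) &&
      !identical(dim(x), c(4096L, 26L))) {
    stop("stack shape mismatch: expected 13 x 2 x 64 x 64 input")
  }
  bit <- tracerBit(tracer)
  fwd <- cnnForward(model, x, bit, keep = FALSE)
  k <- which.max(fwd$locationProbs)  # which.max returns first on ties
  lab <- if (!is.null(model$locationClasses)) model$locationClasses[k] else k
  list(pSuspicious = fwd$pSuspicious, locationProbs = fwd$locationProbs,
    suspicious = fwd$pSuspicious >= threshold, locationLabel = lab)
}

tracerBit <- function(tracer) {
  if (is.numeric(tracer)) return(as.numeric(tracer))
  switch(tracer, PSMA = 1, FDG = 0,
    stop("tracer must be 'PSMA' or 'FDG'"))
}

#' Save / load a trained model
#'
#' The weights are serialised as an RDS file with a JSON sidecar recording
#' the model configuration and the location-class list.
#'
#' @param model a `PetstageModel`.
#' @param path output path (".rds" appended if missing).
#' @return `saveModel`: invisibly, the path; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(model, path)
  sidecar <- sub("\\.rds$", ".json", path)
  cfgOut <- model$cfg
  class(cfgOut) <- NULL
  jsonlite::write_json(list(config = cfgOut,
    locationClasses = model$locationClasses),
    sidecar, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  readRDS(path)
}
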