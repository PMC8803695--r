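#' Per-epoch sampling configuration
#'
#' Balanced sampling caps the number of training examples drawn per subject
#' and per class at each epoch: at most 32 nonsuspicious (physiological) and
#' 32 suspicious findings for the suspicious task, and at most 4 findings
#' per anatomical location class for the location task; the union of the
#' two draws forms the epoch set. Sequential sampling returns every
#' training finding once, in a fixed order.
#'
#' @param mode "sequential" or "balanced".
#' @param maxPhysiologicalPerSubject,maxSuspiciousPerSubject caps for the
#'   suspicious-task draw (default 32 each).
#' @param maxPerLocationClassPerSubject cap for the location-task draw
#'   (default 4).
#' @param epochSeed base seed; the draw for epoch e uses a seed derived
#'   from (epochSeed, e), so any epoch is reproducible in isolation.
#' @return A classed list of settings.
#' @export
samplingConfig <- function(mode = c("balanced", "sequential"),
                           maxPhysiologicalPerSubject = 32,
                           maxSuspiciousPerSubject = 32,
                           maxPerLocationClassPerSubject = 4,
                           epochSeed = 1) {
  mode <- match.arg(mode)
  stopifnot(maxPhysiologicalPerSubject > 0, maxSuspiciousPerSubject > 0,
    maxPerLocationClassPerSubject > 0)
  structure(list(mode = mode,
    maxPhysiologicalPerSubject = as.integer(maxPhysiologicalPerSubject),
    maxSuspiciousPerSubject = as.integer(maxSuspiciousPerSubject),
    maxPerLocationClassPerSubject = as.integer(maxPerLocationClassPerSubject),
    epochSeed = as.integer(epochSeed)), class = "SamplingConfig")
}

#' Draw the training examples of one epoch
#'
#' @param subjects list of [Subject-class].
#' @param cfg a [samplingConfig()].
#' @param epoch epoch index (drives the per-epoch seed).
#' @return data.frame with columns `subjectId` and `findingId`.
#' @export
sampleEpoch <- function(subjects, cfg, epoch = 1) {
  rows <- list()
  for (s in subjects) {
    tab <- findingTable(s)
    tab <- tab[tab$labelSuspicious %in% c("suspicious", "nonsuspicious"), ,
      drop = FALSE]
    if (!nrow(tab)) next  # subject contributes nothing
    if (cfg$mode == "sequential") {
      sel <- tab$findingId
    } else {
      sel <- withSeed(deriveSeed(cfg$epochSeed, epoch * 131 +
          match(s@subjectId, vapply(subjects, function(x) x@subjectId, ""))), {
        non <- tab$findingId[tab$labelSuspicious == "nonsuspicious"]
        sus <- tab$findingId[tab$labelSuspicious == "suspicious"]
        draw <- function(v, k) if (length(v) <= k) v else sample(v, k)
        chosen <- c(draw(non, cfg$maxPhysiologicalPerSubject),
          draw(sus, cfg$maxSuspiciousPerSubject))
        lab <- tab[!is.na(tab$labelLocation) & tab$labelLocation != "NA", ]
        for (cls in unique(lab$labelLocation)) {
          ids <- lab$findingId[lab$labelLocation == cls]
          chosen <- c(chosen, draw(ids, cfg$maxPerLocationClassPerSubject))
        }
        unique(chosen)
      })
    }
    if (length(sel)) {
      rows[[length(rows) + 1]] <- data.frame(subjectId = s@subjectId,
        findingId = sel, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(subjectId = character(), findingId = character()))
  }
  do.call(rbind, rows)
}

#' Training configuration
#'
#' @param strategy one of "I".."VI": I sequential sampling; II balanced
#'   sampling; III balanced + affine augmentation; IV strategy III on FDG
#'   data with a 90/10 subject-level train/validation split; V fine-tuning
#'   of a IV checkpoint on PSMA data with strategy III; VI strategy III on
#'   the union of both tracers with the dual-tracer model.
#' @param epochs,batchSize,learningRate optimiser settings (Adam).
#' @param lrDecayEpoch optional epoch after which the learning rate is
#'   multiplied by `lrDecayFactor` (stabilises the final epochs).
#' @param lrDecayFactor multiplier applied from `lrDecayEpoch` on.
#' @param fdgSplitFraction training fraction of the FDG split (strategy IV).
#' @param seed master seed (initialisation, sampling, augmentation).
#' @param sampling a [samplingConfig()]; its mode is overridden by the
#'   strategy (sequential for I, balanced otherwise).
#' @param pretrained model checkpoint to start from (required for V).
#' @return A classed list of settings.
#' @export
trainConfig <- function(strategy = c("III", "I", "II", "IV", "V", "VI"),
                        epochs = 50, batchSize = 32, learningRate = 1e-3,
                        lrDecayEpoch = NULL, lrDecayFactor = 0.2,
                        fdgSplitFraction = 0.9, seed = 1,
                        sampling = samplingConfig(), pretrained = NULL) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), learningRate = learningRate,
    lrDecayEpoch = lrDecayEpoch, lrDecayFactor = lrDecayFactor,
    fdgSplitFraction = fdgSplitFraction, seed = as.integer(seed),
    sampling = sampling, pretrained = pretrained,
    augmentation = strategy %in% c("III", "IV", "V", "VI")),
    class = "TrainConfig")
}

# Flatten the labelled findings of a subject list into training records.
trainingRecords <- function(subjects, classes) {
  recs <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    for (fi in seq_along(s@findings)) {
      f <- s@findings[[fi]]
      if (!f@labelSuspicious %in% c("suspicious", "nonsuspicious")) next
      loc <- f@labelLocation
      locIdx <- if (is.na(loc) || !loc %in% classes) NA_integer_ else
        match(loc, classes)
      recs[[length(recs) + 1]] <- list(si = si, fi = fi,
        subjectId = s@subjectId, findingId = f@findingId,
        y = as.integer(f@labelSuspicious == "suspicious"),
        locIdx = locIdx, tracer = tracerBit(s@tracer),
        center = f@suvMaxVoxel)
    }
  }
  recs
}

# Union of location classes present in the data, in stable sorted order.
locationClassesOf <- function(subjects) {
  labs <- unlist(lapply(subjects, function(s) {
    vapply(s@findings, function(f) f@labelLocation, "")
  }))
  sort(unique(labs[!is.na(labs) & labs != "NA"]))
}

#' Train the multi-task classifier
#'
#' Implements the six training strategies. The model is trained with Adam
#' on the summed binary cross-entropy (suspicious head) and categorical
#' cross-entropy (location head, masked to zero for findings without an
#' anatomical label).
#'
#' @param psmaSubjects list of PSMA [Subject-class] (training data for
#'   I/II/III/V/VI).
#' @param fdgSubjects list of FDG subjects (required for IV and VI).
#' @param modelCfg a [modelConfig()]; for strategy VI `dualTracer` is
#'   forced on.
#' @param cfg a [trainConfig()].
#' @param valSubjects optional held-out subjects: the history then records
#'   validation AP per epoch.
#' @return list with `model` (carrying the location-class list) and
#'   `history` (data.frame epoch / meanLoss / nExamples / valAP).
#' @export
trainModel <- function(psmaSubjects = NULL, fdgSubjects = NULL,
                       modelCfg = modelConfig(), cfg = trainConfig(),
                       valSubjects = NULL) {
  strategy <- cfg$strategy
  if (strategy == "V" && is.null(cfg$pretrained)) {
    stop("strategy V requires a pretrained checkpoint (cfg$pretrained)")
  }
  if (strategy == "VI" && (is.null(psmaSubjects) || is.null(fdgSubjects))) {
    stop("strategy VI requires subjects from both tracers")
  }
  if (strategy == "IV") {
    if (is.null(fdgSubjects)) stop("strategy IV trains on FDG data")
    ids <- vapply(fdgSubjects, function(s) s@subjectId, "")
    nTrain <- max(1L, round(cfg$fdgSplitFraction * length(fdgSubjects)))
    ordIdx <- withSeed(deriveSeed(cfg$seed, 11),
      sample.int(length(fdgSubjects)))
    trainSubjects <- fdgSubjects[ordIdx[seq_len(nTrain)]]
    if (is.null(valSubjects) && nTrain < length(fdgSubjects)) {
      valSubjects <- fdgSubjects[ordIdx[-seq_len(nTrain)]]
    }
  } else if (strategy == "VI") {
    trainSubjects <- c(psmaSubjects, fdgSubjects)
  } else {
    if (is.null(psmaSubjects)) stop("no training subjects supplied")
    trainSubjects <- psmaSubjects
  }
  classes <- locationClassesOf(trainSubjects)
  if (length(classes) < 2) classes <- union(classes, c(".other1", ".other2"))
  mc <- modelCfg
  if (strategy == "VI") mc$dualTracer <- TRUE
  if (mc$nLocationClasses != length(classes)) {
    mc$nLocationClasses <- as.integer(length(classes))
  }
  if (strategy == "V") {
    model <- cfg$pretrained
    if (!is.null(model$locationClasses)) classes <- model$locationClasses
  } else {
    model <- buildModel(mc, seed = deriveSeed(cfg$seed, 17))
  }
  model$locationClasses <- classes
  sampling <- cfg$sampling
  sampling$mode <- if (strategy == "I") "sequential" else "balanced"
  sampling$epochSeed <- deriveSeed(cfg$seed, 23)
  trainLoop(model, trainSubjects, sampling, cfg, valSubjects)
}

# The epoch/minibatch loop shared by all strategies.
trainLoop <- function(model, trainSubjects, sampling, cfg, valSubjects) {
  classes <- model$locationClasses
  recs <- trainingRecords(trainSubjects, classes)
  if (!length(recs)) stop("no labelled findings to train on")
  key <- vapply(recs, function(r) paste(r$subjectId, r$findingId), "")
  state <- adamInit(model$weights)
  history <- data.frame()
  vols <- lapply(trainSubjects, function(s) s@volume)
  if (cfg$epochs == 0) {
    return(list(model = model, history = history))
  }
  for (epoch in seq_len(cfg$epochs)) {
    lrNow <- cfg$learningRate
    if (!is.null(cfg$lrDecayEpoch) && epoch > cfg$lrDecayEpoch) {
      lrNow <- lrNow * cfg$lrDecayFactor
    }
    sel <- sampleEpoch(trainSubjects, sampling, epoch)
    selKey <- paste(sel$subjectId, sel$findingId)
    idx <- match(selKey, key)
    idx <- idx[!is.na(idx)]
    idx <- withSeed(deriveSeed(sampling$epochSeed, 7000 + epoch), sample(idx))
    lossSum <- 0
    nDone <- 0L
    gAcc <- NULL
    nInBatch <- 0L
    for (j in seq_along(idx)) {
      r <- recs[[idx[j]]]
      vol <- vols[[r$si]]
      x <- trainingInput(vol, r$center,
        seed = if (cfg$augmentation)
          deriveSeed(cfg$seed, epoch * 100000 + idx[j]) else NULL)
      lg <- cnnLossGrad(model, x, r$tracer, r$y, r$locIdx,
        dropout = model$cfg$dropout)
      lossSum <- lossSum + lg$loss
      nDone <- nDone + 1L
      gAcc <- sumGrads(gAcc, lg$grads)
      nInBatch <- nInBatch + 1L
      if (nInBatch == cfg$batchSize || j == length(idx)) {
        upd <- adamStep(model$weights, scaleGrads(gAcc, 1 / nInBatch), state,
          lr = lrNow)
        model$weights <- upd$weights
        state <- upd$state
        gAcc <- NULL
        nInBatch <- 0L
      }
    }
    valAP <- NA_real_
    if (!is.null(valSubjects) && epoch == cfg$epochs) {
      ev <- evaluateModel(model, valSubjects)
      valAP <- ev$ap
    }
    history <- rbind(history, data.frame(epoch = epoch,
      meanLoss = lossSum / max(1L, nDone), nExamples = nDone, valAP = valAP))
  }
  list(model = model, history = history)
}

#' Evaluate a model on labelled subjects
#'
#' Runs the classifier on every labelled finding of the supplied subjects
#' and computes the pooled metrics: AP for the suspicious task and location
#' accuracy over expert-suspicious findings and over all labelled findings.
#'
#' @param model a trained model.
#' @param subjects list of [Subject-class].
#' @return list with `ap`, `accuracySuspicious`, `accuracyAll` and `table`
#'   (one row per finding: subjectId, findingId, label, score, predicted
#'   and expert location).
#' @export
evaluateModel <- function(model, subjects) {
  rows <- list()
  for (s in subjects) {
    vol <- s@volume
    for (f in s@findings) {
      if (!f@labelSuspicious %in% c("suspicious", "nonsuspicious")) next
      pr <- predictFinding(model, trainingInput(vol, f@suvMaxVoxel), s@tracer)
      rows[[length(rows) + 1]] <- data.frame(subjectId = s@subjectId,
        findingId = f@findingId,
        label = as.integer(f@labelSuspicious == "suspicious"),
        score = pr$pSuspicious,
        predictedLocation = as.character(pr$locationLabel),
        expertLocation = f@labelLocation, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ap <- if (any(tab$label == 1)) averagePrecision(tab$score, tab$label) else
    NA_real_
  labelled <- !is.na(tab$expertLocation) & tab$expertLocation != "NA"
  accS <- if (any(tab$label == 1 & labelled)) {
    locationAccuracy(tab$predictedLocation[labelled],
      tab$expertLocation[labelled], tab$label[labelled] == 1,
      "suspicious_only")
  } else NA_real_
  accA <- if (any(labelled)) {
    locationAccuracy(tab$predictedLocation[labelled],
      tab$expertLocation[labelled], tab$label[labelled] == 1, "all")
  } else NA_real_
  list(ap = ap, accuracySuspicious = accS, accuracyAll = accA, table = tab)
}

#' Subject-level stratified k-fold cross-validation
#'
#' Folds are stratified on the presence of suspicious findings (or on the
#' supplied strata), each subject appearing in exactly one validation fold.
#' The per-fold models are trained with [trainModel()] and evaluated on the
#' held-out fold; predictions are pooled across folds for the pooled
#' metrics.
#'
#' @param subjects list of [Subject-class].
#' @param k number of folds (default 4).
#' @param modelCfg a [modelConfig()].
#' @param cfg a [trainConfig()].
#' @param strata optional character vector (one per subject) to stratify on,
#'   e.g. the true stage.
#' @return list with `folds` (per-fold evaluation), `pooled` (metrics over
#'   pooled predictions) and `assignment` (fold id per subject).
#' @export
crossValidate <- function(subjects, k = 4, modelCfg = modelConfig(),
                          cfg = trainConfig(), strata = NULL) {
  n <- length(subjects)
  if (n < k) stop("fewer subjects than folds")
  if (is.null(strata)) {
    strata <- vapply(subjects, function(s) {
      any(vapply(s@findings, function(f) f@labelSuspicious == "suspicious",
        TRUE))
    }, TRUE)
    strata <- ifelse(strata, "pos", "neg")
  }
  fold <- integer(n)
  withSeed(deriveSeed(cfg$seed, 31), {
    # stratum-wise shuffle, then greedy assignment to the least-loaded fold
    # so fold sizes stay globally balanced across strata
    load <- integer(k)
    for (g in unique(strata)) {
      idx <- which(strata == g)
      idx <- sample(idx)
      for (i in idx) {
        f <- which.min(load)
        fold[i] <- f
        load[f] <- load[f] + 1L
      }
    }
  })
  folds <- vector("list", k)
  pooledTabs <- list()
  for (f in seq_len(k)) {
    tr <- subjects[fold != f]
    te <- subjects[fold == f]
    fit <- trainModel(psmaSubjects = tr, modelCfg = modelCfg, cfg = cfg)
    ev <- evaluateModel(fit$model, te)
    folds[[f]] <- ev
    pooledTabs[[f]] <- ev$table
  }
  tab <- do.call(rbind, pooledTabs)
  pooled <- list(
    ap = averagePrecision(tab$score, tab$label),
    table = tab)
  list(folds = folds, pooled = pooled, assignment = fold)
}
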