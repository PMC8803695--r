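#' Average precision (area under the precision-recall curve)
#'
#' Step-wise interpolation over descending-score thresholds: with equal
#' scores grouped into one threshold, AP = sum over thresholds of
#' (R_k - R_{k-1}) * P_k, returned as a percent.
#'
#' @param scores numeric prediction scores (higher = more suspicious).
#' @param labels binary labels (0/1 or logical) of the same length.
#' @return AP in percent (0..100).
#' @export
averagePrecision <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels)
  if (nPos == 0) stop("average precision is undefined without positive labels")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # group ties: keep only the last row of each distinct score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / nPos
  precision <- tp / (tp + fp)
  dR <- diff(c(0, recall))
  100 * sum(dR * precision)
}

#' Recall and positive predictive value from detection counts
#'
#' @param tp,fp,fn true positive, false positive and false negative counts.
#' @return list with `recall` and `ppv` in percent (1-decimal rounded values
#'   in `recallRounded` / `ppvRounded`).
#' @export
detectionRates <- function(tp, fp, fn) {
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  list(recall = recall, ppv = ppv,
    recallRounded = percentRound1(recall), ppvRounded = percentRound1(ppv))
}

# Match candidate findings to expert-suspicious findings within one subject.
# rule "suvmax": the candidate's SUVmax voxel lies inside an expert mask;
# rule "overlap": any shared voxel. Returns the matched expert index (or NA)
# per candidate.
matchFindings <- function(candidates, experts, d, rule = c("suvmax", "overlap")) {
  rule <- match.arg(rule)
  expLin <- lapply(experts, function(f) voxelToLinear(f@mask, d))
  vapply(candidates, function(f) {
    probe <- if (rule == "suvmax") {
      voxelToLinear(matrix(f@suvMaxVoxel, 1), d)
    } else {
      voxelToLinear(f@mask, d)
    }
    for (i in seq_along(expLin)) {
      if (any(probe %in% expLin[[i]])) return(i)
    }
    NA_integer_
  }, 1L)
}

#' Pooled and per-subject detection metrics
#'
#' A candidate classified suspicious counts as a true positive when it
#' matches an expert-suspicious finding (default rule: the candidate's
#' SUVmax voxel lies inside the expert mask), else as a false positive;
#' expert-suspicious findings matched by no suspicious candidate are false
#' negatives. Recall = TP/(TP+FN), PPV = TP/(TP+FP), in percent. Subjects
#' without expert positives are excluded from the per-subject recall
#' summary (recall is undefined there) unless they also have zero
#' suspicious candidates, in which case recall is 100 by convention.
#'
#' @param perSubject list with one entry per subject:
#'   `list(subjectId =, dim =, candidates = list of Finding,
#'   suspicious = logical vector parallel to candidates,
#'   experts = list of expert-suspicious Finding)`.
#' @param matchRule "suvmax" (default) or "overlap".
#' @return list with pooled counts and rates (`tp`, `fp`, `fn`, `recall`,
#'   `ppv`) and `perSubject`, a data.frame of the same metrics per subject
#'   with summary statistics in `summary`.
#' @export
pooledDetectionMetrics <- function(perSubject, matchRule = "suvmax") {
  ids <- vapply(perSubject, function(s) s$subjectId, "")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  rows <- lapply(perSubject, function(s) {
    allIds <- vapply(s$candidates, function(f) f@findingId, "")
    if (anyDuplicated(allIds)) stop("duplicate finding ids in subject ", s$subjectId)
    m <- matchFindings(s$candidates, s$experts, s$dim, matchRule)
    susp <- as.logical(s$suspicious)
    tp <- sum(susp & !is.na(m))
    fp <- sum(susp & is.na(m))
    matched <- unique(m[susp & !is.na(m)])
    fn <- length(s$experts) - length(matched)
    data.frame(subjectId = s$subjectId, tp = tp, fp = fp, fn = fn,
      nExpert = length(s$experts), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$recall <- ifelse(tab$nExpert > 0, 100 * tab$tp / (tab$tp + tab$fn),
    ifelse(tab$tp + tab$fp == 0, 100, NA_real_))
  tab$ppv <- ifelse(tab$tp + tab$fp > 0, 100 * tab$tp / (tab$tp + tab$fp),
    NA_real_)
  pooled <- detectionRates(sum(tab$tp), sum(tab$fp), sum(tab$fn))
  summarise <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(rep(NA_real_, 6))
    c(average = mean(v), min = min(v),
      q1 = unname(quantile(v, 0.25)), median = unname(quantile(v, 0.5)),
      q3 = unname(quantile(v, 0.75)), max = max(v))
  }
  list(tp = sum(tab$tp), fp = sum(tab$fp), fn = sum(tab$fn),
    recall = pooled$recall, ppv = pooled$ppv,
    perSubject = tab,
    summary = rbind(recall = summarise(tab$recall),
      ppv = summarise(tab$ppv), tp = summarise(tab$tp),
      fp = summarise(tab$fp), fn = summarise(tab$fn)))
}

#' Subject-level bootstrap confidence interval
#'
#' Resamples subjects with replacement B times (default 2000), recomputes
#' the pooled metric on each replicate and returns the percentile 2.5/97.5
#' bounds together with the replicate vector. Replicates on which the
#' metric is undefined (NA) are redrawn (bounded), and the redraw count is
#' reported.
#'
#' @param metricFun function(subset of subjects) -> scalar metric (may
#'   return NA when undefined).
#' @param subjects list of per-subject data passed to `metricFun`.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return list with `low`, `high`, `replicates`, `nRedrawn`.
#' @export
bootstrapCi <- function(metricFun, subjects, B = 2000, seed = 1) {
  n <- length(subjects)
  if (n < 2) stop("bootstrap needs at least 2 subjects")
  withSeed(seed, {
    reps <- numeric(B)
    nRedrawn <- 0L
    for (i in seq_len(B)) {
      val <- NA_real_
      tries <- 0L
      while (is.na(val) && tries < 100L) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- metricFun(subjects[idx])
        tries <- tries + 1L
      }
      if (tries > 1L) nRedrawn <- nRedrawn + (tries - 1L)
      if (is.na(val)) stop("metric undefined on 100 consecutive replicates")
      reps[i] <- val
    }
    list(low = unname(quantile(reps, 0.025)),
      high = unname(quantile(reps, 0.975)),
      replicates = reps, nRedrawn = nRedrawn)
  })
}

#' Paired z-test on bootstrap replicates
#'
#' Two-sided paired z-test between two metrics computed on the same
#' bootstrap resamples: with differences d = a - b, z = mean(d)/sd(d) and
#' p = 2(1 - Phi(|z|)), Bonferroni-corrected by the number of comparisons.
#'
#' @param repsA,repsB equal-length replicate vectors from the same bootstrap
#'   resamples.
#' @param nComparisons Bonferroni correction factor (default 1).
#' @return list with `z`, `pRaw`, `pBonferroni` and a `degenerate` flag for
#'   zero-variance differences.
#' @export
pairedZTest <- function(repsA, repsB, nComparisons = 1) {
  stopifnot(length(repsA) == length(repsB))
  d <- repsA - repsB
  s <- sd(d)
  degenerate <- FALSE
  if (s == 0) {
    degenerate <- TRUE
    if (mean(d) == 0) {
      z <- 0; pRaw <- 1
    } else {
      z <- sign(mean(d)) * Inf; pRaw <- 0
    }
  } else {
    z <- mean(d) / s
    pRaw <- 2 * (1 - pnorm(abs(z)))
  }
  list(z = z, pRaw = pRaw,
    pBonferroni = min(1, pRaw * nComparisons), degenerate = degenerate)
}

#' Percent agreement from a confusion matrix
#'
#' Rows are the annotation-derived categories, columns the predicted ones.
#' An optional merge map collapses categories (e.g. N1 and N2 into "N+")
#' before the agreement 100 * trace / total is computed. The integer-rounded
#' value is reported alongside the unrounded one.
#'
#' @param cm square numeric matrix with identical row/column name order.
#' @param merge optional named list: new label -> character vector of old
#'   labels. The groups must not overlap; unlisted labels stay as they are.
#' @return list with `percent` (unrounded) and `percentRounded`.
#' @export
stageAgreement <- function(cm, merge = NULL) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (!is.null(rownames(cm)) && !is.null(colnames(cm)) &&
      !identical(rownames(cm), colnames(cm))) {
    stop("row and column labels must match")
  }
  if (!is.null(merge)) {
    old <- unlist(merge)
    if (anyDuplicated(old)) stop("merge map is not a partition: duplicated labels")
    labs <- rownames(cm)
    if (is.null(labs)) stop("merge requires a labelled matrix")
    if (any(!old %in% labs)) {
      stop("merge map names labels absent from the matrix")
    }
    groupOf <- labs
    for (g in names(merge)) groupOf[labs %in% merge[[g]]] <- g
    newLabs <- unique(groupOf)
    M <- matrix(0, length(newLabs), length(newLabs),
      dimnames = list(newLabs, newLabs))
    for (i in seq_along(labs)) {
      for (j in seq_along(labs)) {
        M[groupOf[i], groupOf[j]] <- M[groupOf[i], groupOf[j]] + cm[i, j]
      }
    }
    cm <- M
  }
  pct <- 100 * sum(diag(cm)) / sum(cm)
  list(percent = pct, percentRounded = round(pct))
}

#' Build a stage confusion matrix
#'
#' @param annotated,predicted character vectors of per-subject stages
#'   (annotation-derived and predicted).
#' @param labels ordered category labels.
#' @return square integer matrix, rows = annotation, columns = prediction.
#' @export
stageConfusion <- function(annotated, predicted, labels) {
  stopifnot(length(annotated) == length(predicted))
  tab <- table(factor(annotated, levels = labels),
    factor(predicted, levels = labels))
  M <- matrix(as.integer(tab), length(labels), length(labels),
    dimnames = list(labels, labels))
  M
}

#' Anatomical location classification accuracy
#'
#' Fraction (percent) of expert-labelled findings whose predicted location
#' class equals the expert class. With `scope = "suspicious_only"` only
#' expert-suspicious findings are counted; with `scope = "all"` every
#' expert-labelled finding is.
#'
#' @param predicted character vector of predicted classes.
#' @param expert character vector of expert classes (same length).
#' @param suspicious logical vector: expert-suspicious flag per finding.
#' @param scope "suspicious_only" or "all".
#' @return accuracy in percent.
#' @export
locationAccuracy <- function(predicted, expert, suspicious,
                             scope = c("suspicious_only", "all")) {
  scope <- match.arg(scope)
  stopifnot(length(predicted) == length(expert))
  keep <- if (scope == "suspicious_only") as.logical(suspicious) else
    rep(TRUE, length(expert))
  keep <- keep & !is.na(expert)
  if (!any(keep)) stop("empty scope: no findings to score")
  100 * mean(predicted[keep] == expert[keep])
}
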