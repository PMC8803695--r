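#' Anatomical location taxonomy
#'
#' Maps every anatomical class the classifier can emit to its staging role.
#' Roles drive the PROMISE miTNM rules: `regional_node` counts toward the N
#' stage, `extrapelvic_node`, `bone` and `other_organ` toward the M stage;
#' `physiological` and `local_prostate` classes contribute to neither.
#'
#' @param roleMap named character vector: class name -> role, roles from
#'   `c("regional_node", "extrapelvic_node", "bone", "other_organ",
#'   "local_prostate", "physiological")`.
#' @return A classed list with `classes` and `roleMap`.
#' @export
locationTaxonomy <- function(roleMap) {
  roles <- c("regional_node", "extrapelvic_node", "bone", "other_organ",
    "local_prostate", "physiological")
  if (is.null(names(roleMap)) || any(!nzchar(names(roleMap)))) {
    stop("roleMap must be a named vector (class -> role)")
  }
  bad <- setdiff(unique(roleMap), roles)
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(roleMap))) stop("duplicate class names in roleMap")
  structure(list(classes = names(roleMap), roleMap = roleMap),
    class = "LocationTaxonomy")
}

#' Load a taxonomy from YAML
#' @param path YAML file mapping class names to roles.
#' @return A [locationTaxonomy()].
#' @export
readTaxonomy <- function(path) {
  y <- yaml::read_yaml(path)
  locationTaxonomy(unlist(y))
}

#' Assign PROMISE miTNM N and M stage from suspicious locations
#'
#' Counts findings per staging role and applies the rules: with r regional
#' nodes, the N stage is N0 (r = 0), N1 (r = 1) or N2 (r >= 2). With b bone
#' lesions, the bone pattern is unifocal M1b_u (b = 1), oligometastatic
#' M1b_o (2 <= b <= 3) or disseminated M1b_d (b >= 4). The reported M stage
#' is the most advanced applicable category, precedence
#' M1c > M1b_* > M1a > M0: any other-organ lesion gives M1c, else any bone
#' lesion its M1b subcategory, else any extrapelvic node M1a, else M0.
#'
#' @param suspiciousLocations character vector of anatomical class names of
#'   findings classified suspicious (possibly empty).
#' @param taxonomy a [locationTaxonomy()] covering every supplied class.
#' @return A [StageResult-class].
#' @export
assignStage <- function(suspiciousLocations, taxonomy) {
  unknown <- setdiff(suspiciousLocations, taxonomy$classes)
  if (length(unknown)) {
    stop("unknown anatomical class: ", paste(unknown, collapse = ", "))
  }
  roles <- taxonomy$roleMap[suspiciousLocations]
  r <- sum(roles == "regional_node")
  a <- sum(roles == "extrapelvic_node")
  b <- sum(roles == "bone")
  cc <- sum(roles == "other_organ")
  nStage <- if (r == 0) "N0" else if (r == 1) "N1" else "N2"
  mStage <- if (cc >= 1) {
    "M1c"
  } else if (b >= 4) {
    "M1b_d"
  } else if (b >= 2) {
    "M1b_o"
  } else if (b == 1) {
    "M1b_u"
  } else if (a >= 1) {
    "M1a"
  } else {
    "M0"
  }
  new("StageResult", nStage = nStage, mStage = mStage,
    counts = c(regional_node = as.integer(r), extrapelvic_node = as.integer(a),
      bone = as.integer(b), other_organ = as.integer(cc)))
}

#' Fully automatic N/M staging of one subject
#'
#' Pipeline composition: candidate regions with SUVmax above 1 are segmented
#' by [incrementalConnectedComponents()], each is represented by its MPR
#' stack and classified; the anatomical labels of regions with suspicious
#' probability at or above `threshold` feed [assignStage()].
#'
#' @param model a trained model carrying its location-class list.
#' @param subject a [Subject-class]; its volume must be at 3 mm isotropic
#'   spacing (resampled otherwise).
#' @param segCfg a [segmentationConfig()]; the floor is forced to 1.0 SUV.
#' @param taxonomy a [locationTaxonomy()].
#' @param threshold suspicious decision threshold (default 0.5).
#' @param candidates optional precomputed candidate findings (skips
#'   segmentation).
#' @return list with `stage` (a [StageResult-class]) and `table` (per
#'   candidate: id, SUVmax, suspicious probability, location label).
#' @export
stageSubject <- function(model, subject, segCfg = segmentationConfig(),
                         taxonomy, threshold = 0.5, candidates = NULL) {
  vol <- subject@volume
  if (max(abs(vol@spacing - 3)) > 1e-6) vol <- resampleIsotropic(vol, 3)
  if (is.null(candidates)) {
    cfg2 <- segCfg
    cfg2$suvFloor <- 1.0
    candidates <- incrementalConnectedComponents(vol@pet, cfg2,
      spacing = vol@spacing)
  }
  if (!length(candidates)) {
    return(list(stage = assignStage(character(), taxonomy),
      table = data.frame()))
  }
  rows <- lapply(candidates, function(f) {
    pr <- predictFinding(model, trainingInput(vol, f@suvMaxVoxel),
      subject@tracer, threshold)
    data.frame(findingId = f@findingId, suvMax = f@suvMax,
      pSuspicious = pr$pSuspicious, suspicious = pr$suspicious,
      locationLabel = as.character(pr$locationLabel),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  locs <- tab$locationLabel[tab$suspicious]
  # classes whose role is physiological never advance the stage; they are
  # filtered by role inside assignStage
  list(stage = assignStage(locs, taxonomy), table = tab)
}
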