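## End-to-end experiment orchestration: simulate -> GLM -> ROIs -> RSA ->
## bands -> group statistics, with a qualitative summary of the headline
## pattern (selective univariate activity, distributed multivariate
## information, topographic gradients).

#' Experiment configuration
#'
#' Bundles every knob of a full synthetic experiment. Defaults reproduce the
#' study-style conditions: 22 participants for the body and face tasks, 19
#' for the finger task, ROI size 50, 30 bands, minimum 5 voxels per band,
#' family alpha 0.05.
#'
#' @param taskId `"body"`, `"face"`, or `"finger"`.
#' @param seed master integer seed.
#' @param nSubjects cohort size (default 22, or 19 for the finger task).
#' @param somatotopy a [SomatotopyConfig-class].
#' @param recipe,localizerRecipe session recipes.
#' @param nHemispheres 1 or 2.
#' @param roiK ROI size in voxels.
#' @param nBands band count for the strip profile.
#' @param minVoxels minimum voxels per retained band.
#' @param bands compute band profiles?
#' @param familyAlpha family-wise alpha before Bonferroni correction.
#' @return list with class `"somaConfig"`.
#' @export
experimentConfig <- function(taskId, seed = 1L,
                             nSubjects = if (taskId == "finger") 19L else 22L,
                             somatotopy = defaultSomatotopy(taskId, seed = seed),
                             recipe = defaultRecipe(taskId),
                             localizerRecipe = defaultRecipe("localizer"),
                             nHemispheres = 1L, roiK = 50L, nBands = 30L,
                             minVoxels = 5L, bands = (taskId == "body"),
                             familyAlpha = 0.05) {
  stopifnot(taskId %in% c("body", "face", "finger"))
  structure(list(taskId = taskId, seed = as.integer(seed),
                 nSubjects = as.integer(nSubjects), somatotopy = somatotopy,
                 recipe = recipe, localizerRecipe = localizerRecipe,
                 nHemispheres = as.integer(nHemispheres),
                 roiK = as.integer(roiK), nBands = as.integer(nBands),
                 minVoxels = as.integer(minVoxels), bands = isTRUE(bands),
                 familyAlpha = familyAlpha),
            class = "somaConfig")
}

## which body part is primary for each ROI
.roiPrimary <- c(leg = "feet", hand = "hand", face = "lips")

## map task subparts to the ROI whose primary part they are (finger: hand)
.taskPrimaryROI <- c(body = NA, face = "face", finger = "hand")

## Analyze one simulated hemisphere of one subject: GLM, localizer ROIs,
## univariate maps, ROI crossnobis RDMs, optional band profile.
analyzeSubjectHemi <- function(sim, config) {
  task <- sim$sheet@conditionSet
  recipe <- config$recipe
  conds <- task@conditions

  fits <- lapply(sim$runs, function(r)
    fitRun(r, buildDesign(r, recipe@trS, recipe@hpCutoffS,
                          conditions = conds)))
  locConds <- sim$sheet@localizerConditions
  locFits <- lapply(sim$locRuns, function(r)
    fitRun(r, buildDesign(r, config$localizerRecipe@trS,
                          config$localizerRecipe@hpCutoffS,
                          conditions = locConds)))

  locMaps <- lapply(c(feet = "loc.feet", hand = "loc.hand",
                      lips = "loc.lips"), function(cn)
    suppressWarnings(contrastStat(locFits,
                                  makeContrast(locConds, cn,
                                               "vs_all_others"))))
  masks <- anatomicalMasks(sim$sheet)
  rois <- defineROIs(locMaps, masks, k = config$roiK)

  condMaps <- lapply(setNames(conds, conds), function(cn)
    suppressWarnings(contrastStat(fits, makeContrast(conds, cn, "vs_rest"))))

  univ <- vapply(condMaps, function(sm)
    vapply(rois@rois, function(roi) univariateLevel(sm, roi), numeric(1L)),
    numeric(length(rois@rois)))

  ps <- patternSet(fits, conds)
  rdms <- lapply(rois@rois, function(roi) {
    sub <- subsetVoxels(ps, roi)
    crossnobisRDM(prewhiten(sub, noiseCovariance(sub@residuals,
                                                 sub@runDofs)))
  })

  profile <- NULL
  if (config$bands) {
    part <- makeBands(c(0, config$somatotopy@axisLengthMM),
                      sim$sheet@coordsMM, config$nBands)
    profile <- bandProfiles(ps, condMaps, part, config$minVoxels)
  }
  list(rois = rois, univariate = univ, rdms = rdms, profile = profile,
       zones = sim$sheet@zoneMasks)
}

## long-format helper
rbindDf <- function(lst) do.call(rbind, c(lst, list(stringsAsFactors = FALSE,
                                                    make.row.names = FALSE)))

#' Run a full synthetic experiment
#'
#' Simulates a cohort under the configuration, estimates per-run condition
#' patterns by GLM, defines selectivity-based ROIs from the independent
#' localizer, computes noise-normalised crossnobis RDMs per ROI (and per
#' strip band for the body task), reduces them (across actions, adjacency
#' classes, hemispheres) and applies the group-level tests with Bonferroni
#' correction. Subjects are simulated and analysed one at a time, so memory
#' stays bounded; everything derives from the master seed.
#'
#' @param config a `"somaConfig"` from [experimentConfig()].
#' @param verbose print per-subject progress to stderr?
#' @return list with class `"somaExperiment"`: tables (`univariate`,
#'   `dissim`), per-comparison `stats`, band-level results (`bands`), MDS
#'   coordinates per ROI, per-subject ROI/zone bookkeeping, qualitative
#'   `flags`, and the seed `manifest`.
#' @export
runExperiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "somaConfig"))
  task <- makeTask(config$taskId)
  subjSeeds <- matrix(deriveSeeds(config$seed,
                                  config$nSubjects * config$nHemispheres),
                      config$nSubjects, config$nHemispheres)
  hemiNames <- c("L", "R")[seq_len(config$nHemispheres)]

  perSubj <- vector("list", config$nSubjects)
  for (i in seq_len(config$nSubjects)) {
    hemi <- lapply(seq_len(config$nHemispheres), function(h) {
      sim <- simulateSubject(config$taskId, config$somatotopy, config$recipe,
                             seed = subjSeeds[i, h],
                             localizerRecipe = config$localizerRecipe)
      res <- analyzeSubjectHemi(sim, config)
      rm(sim)
      res
    })
    names(hemi) <- hemiNames
    perSubj[[i]] <- hemi
    if (verbose) message(sprintf("subject %d/%d done", i, config$nSubjects))
  }

  ## ---- assemble long tables (averaging hemispheres within subject) ----
  roiNames <- names(perSubj[[1L]][[1L]]$rois@rois)
  conds <- task@conditions

  univLong <- rbindDf(lapply(seq_along(perSubj), function(i)
    rbindDf(lapply(hemiNames, function(h) {
      u <- perSubj[[i]][[h]]$univariate
      data.frame(subject = i, hemisphere = h,
                 roi = rep(rownames(u), times = ncol(u)),
                 condition = rep(colnames(u), each = nrow(u)),
                 level = as.vector(u))
    }))))

  hemAvg <- hemisphereAverage(univLong, dv = "level", subject = "subject",
                              hemisphere = "hemisphere",
                              factors = c("roi", "condition"))
  univAvg <- hemAvg$values

  subjectRDM <- function(i, roi)
    averageRDMs(lapply(hemiNames, function(h) perSubj[[i]][[h]]$rdms[[roi]]))

  alphaK <- bonferroniAlpha(config$familyAlpha, length(conds))
  alpha3 <- bonferroniAlpha(config$familyAlpha, 3L)
  alpha2 <- bonferroniAlpha(config$familyAlpha, 2L)

  stats <- list()
  dissim <- NULL
  flags <- list()
  bands <- NULL
  mds <- list()

  getLevel <- function(roi, condition)
    univAvg$level[univAvg$roi == roi & univAvg$condition == condition][
      order(univAvg$subject[univAvg$roi == roi &
                              univAvg$condition == condition])]

  if (config$taskId == "body") {
    af <- task@actionFactor
    parts <- unique(af$part)
    actions <- unique(af$action)
    ## body-part activity level = mean over the two action conditions
    partLevel <- function(roi, p) {
      ls <- vapply(af$condition[af$part == p],
                   function(cn) getLevel(roi, cn), numeric(config$nSubjects))
      rowMeans(ls)
    }
    selRows <- list(); selFlags <- list()
    for (roi in roiNames) for (p in parts) {
      tr <- oneSampleTest(partLevel(roi, p), "two", alpha3)
      selRows[[paste(roi, p)]] <-
        cbind(data.frame(roi = roi, part = p), tr)
    }
    stats$selectivity <- rbindDf(selRows)
    aboveZero <- with(stats$selectivity, significant & d > 0)
    flags$selectivity <- vapply(roiNames, function(roi) {
      rows <- stats$selectivity$roi == roi
      prim <- rows & stats$selectivity$part == .roiPrimary[[roi]]
      all(aboveZero[prim]) && !any(aboveZero[rows & !prim])
    }, logical(1L))

    ## body-part pair dissimilarities (averaged across actions)
    pairGroups <- actionAveragedGroups(task)
    pairVals <- rbindDf(lapply(seq_len(config$nSubjects), function(i)
      rbindDf(lapply(roiNames, function(roi) {
        v <- reduceRDM(subjectRDM(i, roi), pairGroups)
        data.frame(subject = i, roi = roi, type = "part_pair",
                   comparison = names(v), value = unname(v))
      }))))
    ## within-part action dissimilarities
    actGroups <- actionPairGroups(task)
    actVals <- rbindDf(lapply(seq_len(config$nSubjects), function(i)
      rbindDf(lapply(roiNames, function(roi) {
        v <- reduceRDM(subjectRDM(i, roi), actGroups)
        data.frame(subject = i, roi = roi, type = "action",
                   comparison = names(v), value = unname(v))
      }))))
    dissim <- rbind(pairVals, actVals)

    statRows <- function(df, alpha) rbindDf(lapply(
      split(df, df[c("roi", "comparison")], drop = TRUE), function(g)
        cbind(data.frame(roi = g$roi[1L], comparison = g$comparison[1L]),
              oneSampleTest(g$value[order(g$subject)], "greater", alpha))))
    stats$partDissim <- statRows(pairVals, alpha3)
    stats$actionDissim <- statRows(actVals, alpha3)

    ## univariate action differences (squeeze vs push per part per ROI)
    adRows <- list()
    for (roi in roiNames) for (p in parts) {
      cs <- af$condition[af$part == p]
      tr <- pairedTest(getLevel(roi, cs[1L]), getLevel(roi, cs[2L]),
                       "two", alpha3)
      adRows[[paste(roi, p)]] <- cbind(data.frame(roi = roi, part = p), tr)
    }
    stats$actionLevelDiff <- rbindDf(adRows)

    remotePair <- vapply(roiNames, function(roi) {
      others <- setdiff(parts, .roiPrimary[[roi]])
      nm <- paste(sort(others)[order(match(sort(others), parts))],
                  collapse = "-")
      cands <- names(pairGroups)[!grepl(.roiPrimary[[roi]],
                                        names(pairGroups), fixed = TRUE)]
      cands[1L]
    }, character(1L))
    flags$remoteInformation <- vapply(roiNames, function(roi) {
      r <- stats$partDissim
      any(r$significant[r$roi == roi & r$comparison == remotePair[[roi]]])
    }, logical(1L))
    flags$allPairsInformative <- vapply(roiNames, function(roi)
      all(stats$partDissim$significant[stats$partDissim$roi == roi]),
      logical(1L))

    ## ---- band-level strip profile ----
    if (config$bands) bands <- bandAnalysis(perSubj, hemiNames, task,
                                            config, alpha2)
  } else {
    ## face / finger: subpart levels, adjacency-grouped dissimilarities
    layout <- task@subpartOrder
    selRows <- list()
    for (roi in roiNames) for (cn in conds) {
      tr <- oneSampleTest(getLevel(roi, cn), "two", alphaK)
      selRows[[paste(roi, cn)]] <-
        cbind(data.frame(roi = roi, part = cn), tr)
    }
    stats$selectivity <- rbindDf(selRows)
    aboveZero <- with(stats$selectivity, significant & d > 0)
    primROI <- .taskPrimaryROI[[config$taskId]]
    flags$selectivity <- vapply(roiNames, function(roi) {
      rows <- stats$selectivity$roi == roi
      if (roi == primROI) all(aboveZero[rows]) else TRUE
    }, logical(1L))

    adj <- adjacencyPairs(layout)
    groups <- list(adjacent = adj$adjacent, nonAdjacent = adj$nonAdjacent)
    adjVals <- rbindDf(lapply(seq_len(config$nSubjects), function(i)
      rbindDf(lapply(roiNames, function(roi) {
        v <- reduceRDM(subjectRDM(i, roi), groups)
        data.frame(subject = i, roi = roi, type = "adjacency",
                   comparison = names(v), value = unname(v))
      }))))
    dissim <- adjVals

    stats$adjacencyDissim <- rbindDf(lapply(
      split(adjVals, adjVals[c("roi", "comparison")], drop = TRUE),
      function(g)
        cbind(data.frame(roi = g$roi[1L], comparison = g$comparison[1L]),
              oneSampleTest(g$value[order(g$subject)], "greater", alpha2))))

    stats$adjacencyContrast <- rbindDf(lapply(roiNames, function(roi) {
      a <- adjVals$value[adjVals$roi == roi &
                           adjVals$comparison == "adjacent"]
      b <- adjVals$value[adjVals$roi == roi &
                           adjVals$comparison == "nonAdjacent"]
      cbind(data.frame(roi = roi, comparison = "nonAdjacent-adjacent"),
            pairedTest(b, a, "two", config$familyAlpha))
    }))
    flags$topography <- setNames(with(stats$adjacencyContrast,
                                      significant & d > 0),
                                 stats$adjacencyContrast$roi)
    flags$allClassesInformative <- vapply(roiNames, function(roi)
      all(stats$adjacencyDissim$significant[
            stats$adjacencyDissim$roi == roi]), logical(1L))
  }

  ## group-mean MDS per ROI (visualization-only, like the study's plots)
  for (roi in roiNames) {
    gm <- averageRDMs(lapply(seq_len(config$nSubjects), subjectRDM,
                             roi = roi))
    mds[[roi]] <- suppressWarnings(classicalMDS(gm, nDims = 2L))
  }

  structure(list(config = config, task = task, univariate = univLong,
                 univariateAveraged = univAvg, hemisphereGate = hemAvg$gate,
                 dissim = dissim, stats = stats, bands = bands, mds = mds,
                 rois = lapply(perSubj, function(s)
                   lapply(s, function(h) h$rois@rois)),
                 flags = flags,
                 manifest = list(masterSeed = config$seed,
                                 subjectSeeds = subjSeeds)),
            class = "somaExperiment")
}

## Strip profile: band curves of univariate activity per body part and of
## action dissimilarity per body part; peak bands of each primary curve;
## tests of the other parts' action dissimilarity at those peaks.
bandAnalysis <- function(perSubj, hemiNames, task, config, alpha2) {
  af <- task@actionFactor
  parts <- unique(af$part)
  prof1 <- perSubj[[1L]][[1L]]$profile
  bandIds <- prof1@bandIds
  nS <- length(perSubj)

  partZ <- function(prof, p) {
    cs <- af$condition[af$part == p]
    rowMeans(prof@meanZ[, cs, drop = FALSE])
  }
  actGroups <- actionPairGroups(task)
  actD <- function(prof, p) vapply(prof@rdms, function(r)
    reduceRDM(r, actGroups[p]), numeric(1L))

  univCurves <- lapply(setNames(parts, parts), function(p) {
    m <- vapply(perSubj, function(s)
      rowMeans(vapply(hemiNames, function(h) partZ(s[[h]]$profile, p),
                      numeric(length(bandIds)))), numeric(length(bandIds)))
    setNames(rowMeans(m), bandIds)
  })
  dissCurves <- lapply(setNames(parts, parts), function(p) {
    vapply(perSubj, function(s)
      rowMeans(vapply(hemiNames, function(h) actD(s[[h]]$profile, p),
                      numeric(length(bandIds)))), numeric(length(bandIds)))
  })

  peakTests <- list()
  peaks <- list()
  for (p in parts) {
    curve <- setNames(rowMeans(dissCurves[[p]]), bandIds)
    pk <- findPeakBands(curve)
    peaks[[p]] <- pk
    others <- setdiff(parts, p)
    for (pk1 in pk) for (o in others) {
      row <- which(bandIds == pk1)
      tr <- oneSampleTest(dissCurves[[o]][row, ], "greater", alpha2)
      peakTests[[paste(p, pk1, o, sep = ".")]] <-
        cbind(data.frame(primaryPart = p, peakBand = pk1, testedPart = o),
              tr)
    }
  }
  list(bandIds = bandIds, univariateCurves = univCurves,
       dissimCurves = lapply(dissCurves, rowMeans), peaks = peaks,
       peakTests = rbindDf(peakTests))
}

#' Summarise an experiment's qualitative pattern
#'
#' Prints, per figure-analog, whether the headline pattern held: ROI
#' selectivity (only the primary body part active), distributed multivariate
#' information (dissimilarities above zero including remote pairs),
#' topographic gradient (adjacent < non-adjacent), and -- for the body task
#' with bands -- the peak-band action tests.
#'
#' @param exp a `"somaExperiment"` from [runExperiment()].
#' @return the flag list, invisibly.
#' @export
experimentSummary <- function(exp) {
  stopifnot(inherits(exp, "somaExperiment"))
  cat(sprintf("Task '%s', %d subjects, seed %d\n", exp$config$taskId,
              exp$config$nSubjects, exp$config$seed))
  fmt <- function(x) paste(sprintf("%s: %s", names(x),
                                   ifelse(x, "yes", "NO")), collapse = ", ")
  for (nm in names(exp$flags))
    cat(sprintf("  %-22s %s\n", nm, fmt(exp$flags[[nm]])))
  if (!is.null(exp$bands)) {
    pt <- exp$bands$peakTests
    cat(sprintf("  peak-band action tests: %d/%d significant\n",
                sum(pt$significant), nrow(pt)))
  }
  invisible(exp$flags)
}

#' @export
print.somaExperiment <- function(x, ...) {
  cat("somaExperiment (", x$config$taskId, " task)\n", sep = "")
  experimentSummary(x)
  invisible(x)
}
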