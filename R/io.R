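## I/O: NIfTI volumes + TSV events per run, JSON for RDMs / ROI sets / band
## partitions / configs, long-format CSV tables. Serialized voxel indices
## are 0-based (stated in each header/metadata); in R they are 1-based.

#' Write a simulated run as NIfTI + events TSV
#'
#' The 1-D sheet is laid out on a 1 x 1 x P grid (4-D with time); block
#' events go to a tab-separated file with columns `onset`, `duration`,
#' `condition`.
#'
#' @param runData a [RunData-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; writes `<prefix>_bold.nii.gz` and
#'   `<prefix>_events.tsv`.
#' @param trS repetition time (s), stored in the NIfTI header.
#' @return invisibly, the two file paths.
#' @export
writeRun <- function(runData, dir, prefix, trS = 1.45) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Y <- runData@timeseries
  arr <- array(t(Y), dim = c(1L, 1L, ncol(Y), nrow(Y)))
  niiPath <- file.path(dir, paste0(prefix, "_bold.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(1, 1, 1, trS)), niiPath)
  evPath <- file.path(dir, paste0(prefix, "_events.tsv"))
  ev <- data.frame(onset = runData@onsetsS, duration = runData@durationsS,
                   condition = runData@sequence)
  utils::write.table(ev, evPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bold = niiPath, events = evPath))
}

#' Read a run back from NIfTI + events TSV
#'
#' @param boldPath 4-D NIfTI path (1 x 1 x P x T layout).
#' @param eventsPath TSV with `onset`, `duration`, `condition`.
#' @param runIndex run number to record.
#' @return a [RunData-class].
#' @export
readRun <- function(boldPath, eventsPath, runIndex = 1L) {
  arr <- RNifti::readNifti(boldPath)
  d <- dim(arr)
  Y <- t(matrix(arr, prod(d[1:3]), d[4L]))
  ev <- utils::read.delim(eventsPath, stringsAsFactors = FALSE)
  new("RunData", timeseries = Y, sequence = as.character(ev$condition),
      onsetsS = ev$onset, durationsS = ev$duration,
      runIndex = as.integer(runIndex))
}

#' Build a pattern set from user-supplied beta volumes
#'
#' For data estimated outside the package: a 4-D NIfTI of beta patterns
#' (one volume per condition-run estimate) plus a label table assigning
#' each volume a condition and run. The resulting pattern set carries no
#' residuals, so a fixed-lambda [noiseCovariance()] (or an externally
#' estimated covariance) must be used for whitening.
#'
#' @param betaPath 4-D NIfTI of beta volumes.
#' @param labels data.frame with columns `condition` and `run`, one row per
#'   volume.
#' @param voxels optional voxel subset (1-based).
#' @return a [PatternSet-class] with empty residuals.
#' @export
patternSetFromNifti <- function(betaPath, labels, voxels = NULL) {
  arr <- RNifti::readNifti(betaPath)
  d <- dim(arr)
  B <- t(matrix(arr, prod(d[1:3]), d[4L]))   # volume x voxel
  if (nrow(labels) != nrow(B))
    stop("label table must have one row per beta volume", call. = FALSE)
  if (!is.null(voxels)) B <- B[, voxels, drop = FALSE]
  conds <- unique(as.character(labels$condition))
  runs <- sort(unique(labels$run))
  pat <- array(NA_real_, c(length(conds), length(runs), ncol(B)),
               dimnames = list(conds, NULL, NULL))
  for (r in seq_along(runs)) for (ci in seq_along(conds)) {
    row <- which(labels$condition == conds[ci] & labels$run == runs[r])
    if (length(row) != 1L)
      stop("need exactly one volume per condition and run", call. = FALSE)
    pat[ci, r, ] <- B[row, ]
  }
  new("PatternSet", patterns = pat, conditions = conds, residuals = list(),
      runDofs = numeric(), whitened = FALSE)
}

#' Write RDMs as a long-format CSV
#'
#' One row per upper-triangle cell: subject, region, condition_i,
#' condition_j, distance.
#'
#' @param rdms list of [RDM-class] whose `meta` carries `subject` and
#'   `region` entries (missing entries become NA).
#' @param path output CSV path.
#' @return invisibly, the written data.frame.
#' @export
writeRDMLong <- function(rdms, path) {
  rows <- lapply(rdms, function(r) {
    v <- r@values
    ut <- which(upper.tri(v), arr.ind = TRUE)
    data.frame(subject = r@meta$subject %||% NA,
               region = r@meta$region %||% NA,
               condition_i = rownames(v)[ut[, 1L]],
               condition_j = colnames(v)[ut[, 2L]],
               distance = v[ut], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an RDM (or several) to JSON
#'
#' @param rdms an [RDM-class] or list thereof.
#' @param path output JSON path.
#' @export
writeRDMJson <- function(rdms, path) {
  if (is(rdms, "RDM")) rdms <- list(rdms)
  payload <- lapply(rdms, function(r)
    list(conditions = rownames(r@values), estimator = r@estimator,
         meta = r@meta, values = unname(r@values)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
}

#' Serialize ROI sets and band partitions to JSON (0-based indices)
#'
#' @param x an [ROISet-class] or [BandPartition-class].
#' @param path output JSON path.
#' @export
writeRegionsJson <- function(x, path) {
  payload <- if (is(x, "ROISet")) {
    list(type = "ROISet", k = x@k, indexBase = 0L,
         rois = lapply(x@rois, function(v) v - 1L),
         sourceContrast = as.list(x@sourceContrast))
  } else if (is(x, "BandPartition")) {
    list(type = "BandPartition", nBands = x@nBands, edgesMM = x@edgesMM,
         indexBase = 0L, bands = lapply(x@bands, function(v) v - 1L),
         excluded = x@excluded, exclusionReason = x@exclusionReason,
         convention = "half-open [start,end), last band closed")
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
}

#' Save / load an experiment configuration as JSON
#'
#' The round trip `loadConfig(saveConfig(cfg))` reproduces the
#' configuration exactly.
#'
#' @param config a `"somaConfig"` from [experimentConfig()].
#' @param path JSON path.
#' @return `saveConfig`: the path, invisibly; `loadConfig`: the config.
#' @export
saveConfig <- function(config, path) {
  s <- config$somatotopy
  r <- config$recipe
  lr <- config$localizerRecipe
  n <- s@noise
  payload <- list(
    taskId = config$taskId, seed = config$seed,
    nSubjects = config$nSubjects, nHemispheres = config$nHemispheres,
    roiK = config$roiK, nBands = config$nBands,
    minVoxels = config$minVoxels, bands = config$bands,
    familyAlpha = config$familyAlpha,
    somatotopy = list(nVoxels = s@nVoxels, axisLengthMM = s@axisLengthMM,
                      zoneCenters = as.list(s@zoneCenters),
                      tuningWidthMM = s@tuningWidthMM,
                      primaryAmplitude = s@primaryAmplitude,
                      distributedAmplitude = s@distributedAmplitude,
                      neighborCorr = s@neighborCorr,
                      actionAmplitude = s@actionAmplitude, seed = s@seed,
                      noise = list(temporalAR1 = n@temporalAR1,
                                   spatialKernelMM = n@spatialKernelMM,
                                   voxelSdRange = n@voxelSdRange,
                                   scannerSd = n@scannerSd)),
    recipe = recipeToList(r), localizerRecipe = recipeToList(lr))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

recipeToList <- function(r)
  list(trS = r@trS, blockS = r@blockS,
       blocksPerConditionPerRun = r@blocksPerConditionPerRun,
       restBlocksPerRun = r@restBlocksPerRun, nRuns = r@nRuns,
       nVolumesPerRun = r@nVolumesPerRun, hpCutoffS = r@hpCutoffS)

recipeFromList <- function(l)
  new("SessionRecipe", trS = l$trS, blockS = l$blockS,
      blocksPerConditionPerRun = as.integer(l$blocksPerConditionPerRun),
      restBlocksPerRun = as.integer(l$restBlocksPerRun),
      nRuns = as.integer(l$nRuns),
      nVolumesPerRun = as.integer(l$nVolumesPerRun), hpCutoffS = l$hpCutoffS)

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sl <- p$somatotopy
  som <- new("SomatotopyConfig", nVoxels = as.integer(sl$nVoxels),
             axisLengthMM = sl$axisLengthMM,
             zoneCenters = unlist(sl$zoneCenters),
             tuningWidthMM = sl$tuningWidthMM,
             primaryAmplitude = sl$primaryAmplitude,
             distributedAmplitude = sl$distributedAmplitude,
             neighborCorr = sl$neighborCorr,
             actionAmplitude = sl$actionAmplitude,
             seed = as.integer(sl$seed),
             noise = new("NoiseConfig",
                         temporalAR1 = sl$noise$temporalAR1,
                         spatialKernelMM = sl$noise$spatialKernelMM,
                         voxelSdRange = sl$noise$voxelSdRange,
                         scannerSd = sl$noise$scannerSd))
  experimentConfig(taskId = p$taskId, seed = p$seed,
                   nSubjects = p$nSubjects, somatotopy = som,
                   recipe = recipeFromList(p$recipe),
                   localizerRecipe = recipeFromList(p$localizerRecipe),
                   nHemispheres = p$nHemispheres, roiK = p$roiK,
                   nBands = p$nBands, minVoxels = p$minVoxels,
                   bands = p$bands, familyAlpha = p$familyAlpha)
}

#' Write the main tables of an experiment as CSV files
#'
#' Deterministic long-format CSVs: `univariate.csv`, `dissim.csv`, and one
#' `stats_<name>.csv` per test family. Re-running the same configuration
#' reproduces the files byte-identically.
#'
#' @param exp a `"somaExperiment"`.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
writeExperimentCSVs <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    pth <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, pth, row.names = FALSE)
    paths <<- c(paths, pth)
  }
  wr(exp$univariate, "univariate")
  if (!is.null(exp$dissim)) wr(exp$dissim, "dissim")
  for (nm in names(exp$stats)) wr(exp$stats[[nm]], paste0("stats_", nm))
  invisible(paths)
}
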