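#' @rdname accessors
#' @param object an object.
#' @export
setGeneric("conditionLabels", function(object) standardGeneric("conditionLabels"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("nRuns", function(object) standardGeneric("nRuns"))

#' @rdname accessors
#' @export
setGeneric("rdmValues", function(object) standardGeneric("rdmValues"))

#' Accessors for somarsa objects
#'
#' Small read-only accessors: `conditionLabels()` returns condition labels,
#' `nVoxels()` the voxel count, `nRuns()` the run count, `rdmValues()` the
#' dissimilarity matrix of an [RDM-class].
#'
#' @name accessors
NULL

#' @rdname accessors
setMethod("conditionLabels", "ConditionSet", function(object) object@conditions)

#' @rdname accessors
setMethod("conditionLabels", "CorticalSheet",
          function(object) rownames(object@meanMaps))

#' @rdname accessors
setMethod("conditionLabels", "PatternSet", function(object) object@conditions)

#' @rdname accessors
setMethod("conditionLabels", "RDM", function(object) rownames(object@values))

#' @rdname accessors
setMethod("nVoxels", "CorticalSheet", function(object) length(object@coordsMM))

#' @rdname accessors
setMethod("nVoxels", "PatternSet", function(object) dim(object@patterns)[3L])

#' @rdname accessors
setMethod("nRuns", "PatternSet", function(object) dim(object@patterns)[2L])

#' @rdname accessors
setMethod("nRuns", "SessionRecipe", function(object) object@nRuns)

#' @rdname accessors
setMethod("rdmValues", "RDM", function(object) object@values)

setMethod("show", "ConditionSet", function(object) {
  cat(sprintf("ConditionSet '%s': %d conditions\n", object@taskId,
              length(object@conditions)))
  cat("  conditions:", paste(object@conditions, collapse = ", "), "\n")
  cat("  subpart order:", paste(object@subpartOrder, collapse = " < "), "\n")
})

setMethod("show", "SessionRecipe", function(object) {
  cat(sprintf(paste0("SessionRecipe: TR %.3g s, %g s blocks, %d/condition/run, ",
                     "%d rest, %d runs x %d volumes, hp %g s\n"),
              object@trS, object@blockS, object@blocksPerConditionPerRun,
              object@restBlocksPerRun, object@nRuns, object@nVolumesPerRun,
              object@hpCutoffS))
})

setMethod("show", "CorticalSheet", function(object) {
  cfg <- object@config
  cat(sprintf("CorticalSheet: %d voxels over %.1f mm, %d conditions\n",
              nVoxels(object), cfg@axisLengthMM, nrow(object@meanMaps)))
  cat(sprintf("  a = %g, epsilon = %g, rho = %g, sigma = %g mm\n",
              cfg@primaryAmplitude, cfg@distributedAmplitude,
              cfg@neighborCorr, cfg@tuningWidthMM))
})

setMethod("show", "RDM", function(object) {
  cat(sprintf("RDM (%s): %d conditions", object@estimator,
              nrow(object@values)))
  if (!is.null(object@meta$region)) cat(", region", object@meta$region)
  cat("\n")
  print(round(object@values, 4))
})

setMethod("show", "PatternSet", function(object) {
  d <- dim(object@patterns)
  cat(sprintf("PatternSet: %d conditions x %d runs x %d voxels (%s)\n",
              d[1L], d[2L], d[3L],
              if (object@whitened) "whitened" else "raw"))
})

setMethod("show", "NoiseCov", function(object) {
  cat(sprintf("NoiseCov: %d voxels, lambda = %.4f, pooled dof = %g\n",
              nrow(object@sigma), object@lambda, object@sourceDof))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: k = %d\n", object@k))
  for (nm in names(object@rois))
    cat(sprintf("  %s: %d voxels (contrast %s)\n", nm,
                length(object@rois[[nm]]), object@sourceContrast[nm]))
})

setMethod("show", "BandPartition", function(object) {
  cat(sprintf("BandPartition: %d bands of %.4f mm, %d excluded\n",
              object@nBands, diff(object@edgesMM)[1L],
              length(object@excluded)))
})
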