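#' @import methods
#' @importFrom stats rnorm runif convolve qnorm pt pf pnorm sd cov var
#'   shapiro.test t.test wilcox.test uniroot aov cmdscale dist median
#'   quantile setNames
#' @importFrom utils head tail
NULL

## Central data containers. All voxel indices are 1-based inside R; serialized
## outputs (JSON/CSV) use 0-based indices, stated in every output header.

#' Task condition set
#'
#' The conditions of one experimental task together with the cortical order of
#' its subparts (medial to lateral), which defines adjacency for topographic
#' analyses, and -- for the whole-body task -- the mapping of conditions to
#' (body part, action) pairs.
#'
#' @slot taskId one of `"body"`, `"face"`, `"finger"`, or `"localizer"`.
#' @slot conditions character vector of unique condition labels.
#' @slot subpartOrder character vector of subparts in cortical order.
#' @slot actionFactor data.frame with columns `condition`, `part`, `action`
#'   (zero rows for tasks without an action factor).
#' @export
setClass("ConditionSet",
  representation(taskId = "character", conditions = "character",
                 subpartOrder = "character", actionFactor = "data.frame"))

setValidity("ConditionSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@conditions))
    msg <- c(msg, "condition labels must be unique")
  if (anyDuplicated(object@subpartOrder))
    msg <- c(msg, "subpart labels must be unique")
  if (nrow(object@actionFactor) > 0L) {
    if (!all(c("condition", "part", "action") %in% names(object@actionFactor)))
      msg <- c(msg, "actionFactor needs columns condition, part, action")
    else if (!setequal(object@actionFactor$condition, object@conditions))
      msg <- c(msg, "actionFactor must cover exactly the conditions")
  }
  if (length(msg)) msg else TRUE
})

#' Block-design session recipe
#'
#' Timing parameters of one scanning session: repetition time, block duration,
#' how often each condition appears per run, rest blocks, number of runs and
#' volumes per run.
#'
#' @slot trS repetition time (s).
#' @slot blockS block duration (s); rest blocks share this duration.
#' @slot blocksPerConditionPerRun repeats of each condition per run.
#' @slot restBlocksPerRun number of rest blocks per run.
#' @slot nRuns number of runs in the session.
#' @slot nVolumesPerRun volumes acquired per run.
#' @slot hpCutoffS high-pass drift cutoff (s) used when building designs.
#' @export
setClass("SessionRecipe",
  representation(trS = "numeric", blockS = "numeric",
                 blocksPerConditionPerRun = "integer",
                 restBlocksPerRun = "integer", nRuns = "integer",
                 nVolumesPerRun = "integer", hpCutoffS = "numeric"))

setValidity("SessionRecipe", function(object) {
  msg <- character()
  if (object@trS <= 0 || object@blockS <= 0)
    msg <- c(msg, "trS and blockS must be positive")
  counts <- c(object@blocksPerConditionPerRun, object@nRuns,
              object@nVolumesPerRun)
  if (any(counts < 1L) || object@restBlocksPerRun < 0L)
    msg <- c(msg, "all counts must be positive (rest blocks may be 0)")
  if (length(msg)) msg else TRUE
})

#' Noise model configuration
#'
#' Scan noise is heteroscedastic Gaussian, AR(1) in time, and the sum of a
#' white component and a spatially smoothed component of equal variance
#' (thermal plus physiological noise).
#'
#' @slot temporalAR1 lag-1 autocorrelation phi, |phi| < 1.
#' @slot spatialKernelMM Gaussian length scale (mm) of the smooth component.
#' @slot voxelSdRange length-2 range of per-voxel noise SD multipliers.
#' @slot scannerSd overall noise scale (a.u.).
#' @export
setClass("NoiseConfig",
  representation(temporalAR1 = "numeric", spatialKernelMM = "numeric",
                 voxelSdRange = "numeric", scannerSd = "numeric"))

setValidity("NoiseConfig", function(object) {
  msg <- character()
  if (abs(object@temporalAR1) >= 1) msg <- c(msg, "|temporalAR1| must be < 1")
  if (length(object@voxelSdRange) != 2L || any(object@voxelSdRange <= 0))
    msg <- c(msg, "voxelSdRange must be two positive values")
  if (object@scannerSd < 0) msg <- c(msg, "scannerSd must be >= 0")
  if (object@spatialKernelMM <= 0) msg <- c(msg, "spatialKernelMM must be > 0")
  if (length(msg)) msg else TRUE
})

#' Somatotopic sheet configuration
#'
#' Parameters of the one-dimensional medio-lateral cortical sheet: geometry,
#' Gaussian mean-activation zones per subpart, the amplitude of the mean-free
#' distributed condition patterns, the correlation imposed between
#' neighbouring subparts' patterns, action-component amplitude, and the noise
#' model.
#'
#' @slot nVoxels number of voxels P along the axis.
#' @slot axisLengthMM axis length L (mm).
#' @slot zoneCenters named vector of subpart zone centres (mm), inside [0, L].
#' @slot tuningWidthMM Gaussian tuning width sigma (mm) of mean activation.
#' @slot primaryAmplitude peak mean response a (a.u.).
#' @slot distributedAmplitude amplitude epsilon of distributed patterns.
#' @slot neighborCorr correlation rho between adjacent subparts' patterns;
#'   subparts at rank distance k correlate rho^k.
#' @slot actionAmplitude amplitude of the action-specific pattern component;
#'   also sets the +/- actionAmplitude/2 univariate gain modulation between
#'   the two actions of the body task.
#' @slot noise a [NoiseConfig-class].
#' @slot seed integer seed for pattern and noise generation.
#' @export
setClass("SomatotopyConfig",
  representation(nVoxels = "integer", axisLengthMM = "numeric",
                 zoneCenters = "numeric", tuningWidthMM = "numeric",
                 primaryAmplitude = "numeric", distributedAmplitude = "numeric",
                 neighborCorr = "numeric", actionAmplitude = "numeric",
                 noise = "NoiseConfig", seed = "integer"))

setValidity("SomatotopyConfig", function(object) {
  msg <- character()
  if (object@neighborCorr < 0 || object@neighborCorr >= 1)
    msg <- c(msg, "neighborCorr must satisfy 0 <= rho < 1")
  if (object@distributedAmplitude < 0)
    msg <- c(msg, "distributedAmplitude must be >= 0")
  if (object@tuningWidthMM <= 0) msg <- c(msg, "tuningWidthMM must be > 0")
  if (is.null(names(object@zoneCenters)) || any(names(object@zoneCenters) == ""))
    msg <- c(msg, "zoneCenters must be named by subpart")
  if (any(object@zoneCenters < 0 | object@zoneCenters > object@axisLengthMM))
    msg <- c(msg, "zone centers must lie inside [0, axisLengthMM]")
  if (length(msg)) msg else TRUE
})

#' Ground-truth cortical sheet of one participant
#'
#' Per-voxel axis coordinates, noise-free condition mean maps, mean-free
#' distributed pattern components, ground-truth primary zones, and the factors
#' of the true noise covariance (per-voxel SDs and the sparse spatial
#' smoother), from which [trueNoiseCov()] reconstructs the voxel-by-voxel
#' covariance on demand.
#'
#' @slot coordsMM per-voxel medio-lateral coordinate (mm).
#' @slot meanMaps condition x voxel matrix of noise-free mean responses.
#' @slot distMaps condition x voxel matrix of mean-free pattern components.
#' @slot zoneMasks named list of voxel index vectors, one per subpart.
#' @slot voxelSd per-voxel noise SD multiplier (heteroscedastic).
#' @slot smoother sparse voxel x voxel spatial smoothing operator with unit
#'   row marginal variance.
#' @slot conditionSet the task [ConditionSet-class].
#' @slot localizerConditions labels of localizer conditions also carried by
#'   the sheet (possibly none).
#' @slot config the generating [SomatotopyConfig-class].
#' @export
setClass("CorticalSheet",
  representation(coordsMM = "numeric", meanMaps = "matrix",
                 distMaps = "matrix", zoneMasks = "list", voxelSd = "numeric",
                 smoother = "ANY", conditionSet = "ConditionSet",
                 localizerConditions = "character",
                 config = "SomatotopyConfig"))

setValidity("CorticalSheet", function(object) {
  msg <- character()
  eps <- object@config@distributedAmplitude
  rowm <- if (nrow(object@distMaps)) max(abs(rowMeans(object@distMaps))) else 0
  if (rowm > 1e-10 * max(eps, object@config@actionAmplitude, 1e-300))
    msg <- c(msg, "distributed maps must be mean-free per condition")
  if (!identical(dim(object@meanMaps), dim(object@distMaps)))
    msg <- c(msg, "meanMaps and distMaps must have identical dimensions")
  if (ncol(object@meanMaps) != length(object@coordsMM))
    msg <- c(msg, "map columns must match voxel count")
  if (length(msg)) msg else TRUE
})

#' One simulated run
#'
#' @slot timeseries volume x voxel matrix.
#' @slot sequence ordered condition labels of the movement blocks.
#' @slot onsetsS,durationsS per-block onset and duration (s).
#' @slot runIndex run number within the session.
#' @export
setClass("RunData",
  representation(timeseries = "matrix", sequence = "character",
                 onsetsS = "numeric", durationsS = "numeric",
                 runIndex = "integer"))

setValidity("RunData", function(object) {
  msg <- character()
  if (length(object@onsetsS) != length(object@sequence) ||
      length(object@durationsS) != length(object@sequence))
    msg <- c(msg, "onsets/durations must match the block sequence")
  if (length(object@onsetsS) > 1L) {
    ends <- object@onsetsS + object@durationsS
    if (any(diff(object@onsetsS) <= 0) ||
        any(object@onsetsS[-1L] < head(ends, -1L) - 1e-9))
      msg <- c(msg, "onsets must be increasing and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' GLM design matrix
#'
#' @slot X volume x regressor matrix.
#' @slot regressorType per-column type: condition, derivative, drift,
#'   intercept, or nuisance.
#' @slot conditionCols named integer vector locating condition columns.
#' @slot hpCutoffS high-pass cutoff (s) used for the drift basis.
#' @slot trS sampling interval (s).
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", regressorType = "character",
                 conditionCols = "integer", hpCutoffS = "numeric",
                 trS = "numeric"))

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (length(object@regressorType) != ncol(object@X))
    msg <- c(msg, "one regressorType per column required")
  if (qr(object@X)$rank < ncol(object@X))
    msg <- c(msg, "design matrix must have full column rank")
  if (length(msg)) msg else TRUE
})

#' Fitted run-level GLM
#'
#' @slot betas regressor x voxel coefficient matrix.
#' @slot residuals volume x voxel residual matrix.
#' @slot dof residual degrees of freedom (volumes - rank of design).
#' @slot sigma2 per-voxel residual variance (RSS/dof).
#' @slot design the [DesignMatrix-class] used.
#' @export
setClass("GLMFit",
  representation(betas = "matrix", residuals = "matrix", dof = "numeric",
                 sigma2 = "numeric", design = "DesignMatrix"))

setValidity("GLMFit", function(object) {
  msg <- character()
  if (object@dof <= 0) msg <- c(msg, "residual dof must be positive")
  X <- object@design@X
  ## scale floor keeps the check meaningful when residuals are ~0 (noiseless)
  sc <- norm(X, "F") * (norm(object@residuals, "F") + 1)
  if (max(abs(crossprod(X, object@residuals))) > 1e-8 * sc)
    msg <- c(msg, "residuals must be orthogonal to the design")
  if (length(msg)) msg else TRUE
})

#' Contrast specification over condition regressors
#'
#' @slot weights named numeric weights over condition labels.
#' @slot name contrast name.
#' @slot mode `"vs_rest"` or `"vs_all_others"`.
#' @export
setClass("ContrastSpec",
  representation(weights = "numeric", name = "character", mode = "character"))

setValidity("ContrastSpec", function(object) {
  msg <- character()
  w <- object@weights
  if (object@mode == "vs_rest") {
    if (sum(w != 0) != 1L || !isTRUE(all.equal(unname(w[w != 0]), 1)))
      msg <- c(msg, "vs_rest contrast must be a single +1 weight")
  } else if (object@mode == "vs_all_others") {
    if (abs(sum(w)) > 1e-12 || !isTRUE(all.equal(unname(max(w)), 1)))
      msg <- c(msg, "vs_all_others weights must be +1 on target, sum to 0")
  } else msg <- c(msg, "mode must be vs_rest or vs_all_others")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise contrast statistics
#'
#' @slot t,z,effect,variance per-voxel statistic vectors; z is the
#'   standard-normal quantile of the t cumulative probability (sign
#'   preserved), clipped at |z| = 8.2.
#' @slot dof degrees of freedom of t.
#' @slot source `"run"` or `"fixed_effects"`.
#' @slot nClipped number of voxels whose z hit the clip.
#' @export
setClass("StatMap",
  representation(t = "numeric", z = "numeric", effect = "numeric",
                 variance = "numeric", dof = "numeric", source = "character",
                 nClipped = "integer"))

#' Shrinkage noise covariance
#'
#' Run-averaged residual covariance shrunk toward its diagonal,
#' \eqn{\Sigma_\lambda = (1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)}.
#'
#' @slot sigma voxel x voxel shrunk covariance.
#' @slot lambda shrinkage weight in [0, 1].
#' @slot sourceDof pooled residual degrees of freedom.
#' @export
setClass("NoiseCov",
  representation(sigma = "matrix", lambda = "numeric", sourceDof = "numeric"))

setValidity("NoiseCov", function(object) {
  msg <- character()
  if (!isSymmetric(object@sigma, tol = 1e-8))
    msg <- c(msg, "covariance must be symmetric")
  if (object@lambda < 0 || object@lambda > 1)
    msg <- c(msg, "lambda must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Condition x run x voxel pattern estimates
#'
#' Response-pattern estimates for a voxel set, one pattern per condition and
#' run, together with the run residuals (restricted to the same voxels) from
#' which the noise covariance is estimated.
#'
#' @slot patterns 3-d array, condition x run x voxel.
#' @slot conditions condition labels (dimension 1).
#' @slot residuals list of volume x voxel residual matrices, one per run.
#' @slot runDofs per-run residual dof.
#' @slot whitened logical; have patterns been noise-normalised?
#' @export
setClass("PatternSet",
  representation(patterns = "array", conditions = "character",
                 residuals = "list", runDofs = "numeric",
                 whitened = "logical"))

setValidity("PatternSet", function(object) {
  msg <- character()
  d <- dim(object@patterns)
  if (length(d) != 3L) msg <- c(msg, "patterns must be condition x run x voxel")
  else {
    if (d[1L] != length(object@conditions))
      msg <- c(msg, "condition labels must match dimension 1")
    if (anyNA(object@patterns)) msg <- c(msg, "patterns must have no missing cells")
  }
  if (length(msg)) msg else TRUE
})

#' Representational dissimilarity matrix
#'
#' Symmetric condition x condition matrix of cross-validated squared
#' Mahalanobis (crossnobis) dissimilarities, in arbitrary units normalised by
#' voxel count. The diagonal is exactly zero; off-diagonal cells may be
#' negative (the estimator is unbiased around zero under the null).
#'
#' @slot values symmetric numeric matrix with zero diagonal.
#' @slot estimator estimator tag, `"crossnobis"`.
#' @slot meta named list (subject, region/band ids, voxel count, ...).
#' @export
setClass("RDM",
  representation(values = "matrix", estimator = "character", meta = "list"))

setValidity("RDM", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v) || !isSymmetric(unname(v), tol = 1e-10))
    msg <- c(msg, "RDM must be square and symmetric")
  if (any(diag(v) != 0)) msg <- c(msg, "RDM diagonal must be exactly 0")
  if (length(msg)) msg else TRUE
})

#' Selectivity-defined regions of interest
#'
#' @slot rois named list of sorted voxel index vectors, each of size k.
#' @slot k ROI size (voxels).
#' @slot sourceContrast per-ROI name of the localizer contrast used.
#' @export
setClass("ROISet",
  representation(rois = "list", k = "integer", sourceContrast = "character"))

setValidity("ROISet", function(object) {
  if (!all(lengths(object@rois) == object@k))
    "every ROI must contain exactly k voxels" else TRUE
})

#' Equal-height band partition of a cortical strip
#'
#' @slot nBands number of bands.
#' @slot edgesMM band edges along the axis (length nBands + 1).
#' @slot bands list of voxel index vectors per band.
#' @slot excluded integer ids of excluded bands.
#' @slot exclusionReason character reasons, parallel to `excluded`.
#' @export
setClass("BandPartition",
  representation(nBands = "integer", edgesMM = "numeric", bands = "list",
                 excluded = "integer", exclusionReason = "character"))

setValidity("BandPartition", function(object) {
  msg <- character()
  h <- diff(object@edgesMM)
  if (length(h) != object@nBands) msg <- c(msg, "edges must bound nBands bands")
  if (max(h) - min(h) > 1e-9) msg <- c(msg, "bands must have equal height")
  if (length(msg)) msg else TRUE
})

#' Band-wise strip profile
#'
#' @slot bandIds retained band ids.
#' @slot meanZ retained-band x condition matrix of mean univariate z.
#' @slot rdms list of [RDM-class], one per retained band.
#' @slot voxelCounts voxels per retained band.
#' @slot excluded,exclusionReason excluded band ids and reasons.
#' @export
setClass("BandProfile",
  representation(bandIds = "integer", meanZ = "matrix", rdms = "list",
                 voxelCounts = "integer", excluded = "integer",
                 exclusionReason = "character"))
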