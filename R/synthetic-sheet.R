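## Ground-truth somatotopic sheet and BOLD time-series simulation.
##
## The sheet is one-dimensional along the medio-lateral axis: every analysis
## downstream (ROIs, bands) operates on axis intervals, so a 1-D geometry
## carries all the structure the pipeline exercises. Each condition
## contributes (i) a Gaussian mean-activation bump centred on its subpart's
## zone -- the classical homunculus -- and (ii) a mean-free distributed
## pattern present across the entire sheet, whose between-subpart correlation
## falls off as rho^(rank distance), so that adjacent subparts are more
## similar than non-adjacent ones everywhere on the sheet.

#' Default somatotopy configuration for a task
#'
#' Geometry and amplitudes of the synthetic medio-lateral sheet: 1500 voxels
#' over a 62.7 mm axis, Gaussian zones of width 4 mm centred at feet 8 mm,
#' hand 31 mm, lips 56 mm (face subparts 48-60 mm, digits D1..D5 at
#' 37..25 mm), peak mean amplitude 3, distributed amplitude 0.3, neighbour
#' correlation 0.6, action amplitude 0.3, AR(1) noise with phi = 0.3, a
#' 0.8 mm spatial noise kernel, per-voxel SD multipliers in [0.8, 1.2] and
#' overall noise scale 9, which puts peak fixed-effects z levels in the 5-8
#' range typical of block designs (see the methods vignette for the
#' calibration rationale).
#'
#' @param taskId `"body"`, `"face"`, or `"finger"`.
#' @param seed integer seed stored in the config.
#' @param ... named overrides for any [SomatotopyConfig-class] slot
#'   (`nVoxels`, `distributedAmplitude`, `noise`, ...).
#' @return a [SomatotopyConfig-class].
#' @export
defaultSomatotopy <- function(taskId, seed = 1L, ...) {
  centers <- switch(taskId,
    body   = c(feet = 8, hand = 31, lips = 56),
    face   = c(feet = 8, hand = 31, forehead = 48, nose = 52, lips = 56,
               tongue = 60),
    finger = c(feet = 8, lips = 56, D1 = 37, D2 = 34, D3 = 31, D4 = 28,
               D5 = 25, hand = 31),
    stop("unknown taskId: ", taskId, call. = FALSE))
  args <- list(Class = "SomatotopyConfig", nVoxels = 1500L,
               axisLengthMM = 62.7, zoneCenters = centers, tuningWidthMM = 4,
               primaryAmplitude = 3, distributedAmplitude = 0.3,
               neighborCorr = 0.6, actionAmplitude = 0.3,
               noise = new("NoiseConfig", temporalAR1 = 0.3,
                           spatialKernelMM = 0.8, voxelSdRange = c(0.8, 1.2),
                           scannerSd = 9),
               seed = as.integer(seed))
  dots <- list(...)
  if (length(dots)) {
    if (!is.null(dots$nVoxels)) dots$nVoxels <- as.integer(dots$nVoxels)
    if (!is.null(dots$seed)) dots$seed <- as.integer(dots$seed)
    args[names(dots)] <- dots
  }
  do.call(new, args)
}

## Sparse Gaussian smoothing operator along the axis, rows scaled to unit
## L2 norm so that (S z) has unit marginal variance for white z. The
## operator depends only on the grid and kernel, so it is memoised.
.smootherCache <- new.env(parent = emptyenv())

spatialSmoother <- function(coords, kernelMM) {
  key <- sprintf("%d_%.9g_%.9g_%.9g", length(coords), coords[1L],
                 coords[length(coords)], kernelMM)
  hit <- .smootherCache[[key]]
  if (!is.null(hit)) return(hit)
  S <- .buildSmoother(coords, kernelMM)
  .smootherCache[[key]] <- S
  S
}

.buildSmoother <- function(coords, kernelMM) {
  P <- length(coords)
  spacing <- if (P > 1L) coords[2L] - coords[1L] else 1
  hw <- min(P - 1L, max(1L, ceiling(4 * kernelMM / spacing)))
  offs <- -hw:hw
  w <- exp(-(offs * spacing)^2 / (2 * kernelMM^2))
  i <- rep(seq_len(P), each = length(offs))
  j <- i + rep(offs, times = P)
  keep <- j >= 1L & j <= P
  S <- Matrix::sparseMatrix(i = i[keep], j = j[keep],
                            x = rep(w, times = P)[keep], dims = c(P, P))
  rn <- sqrt(Matrix::rowSums(S^2))
  Matrix::Diagonal(x = 1 / rn) %*% S
}

## Mean-free AR(1)-correlated pattern stack: one row per subpart, corr
## between rows i,j equals rho^|i-j| exactly (before the final centering).
correlatedPatterns <- function(nSub, P, rho) {
  g <- matrix(0, nSub, P)
  g[1L, ] <- rnorm(P)
  if (nSub > 1L)
    for (s in 2L:nSub)
      g[s, ] <- rho * g[s - 1L, ] + sqrt(1 - rho^2) * rnorm(P)
  g
}

#' Build a participant's ground-truth cortical sheet
#'
#' Draws one participant's sheet under a [SomatotopyConfig-class]: mean maps
#' \eqn{a \exp(-(x-\mu_c)^2 / 2\sigma^2)} per condition, mean-free
#' distributed patterns with correlation \eqn{\rho^{|rank_i - rank_j|}}
#' between subparts, action components for the body task, heteroscedastic
#' per-voxel noise SDs and the spatial noise smoother. When a localizer set
#' is supplied its conditions (prefixed `loc.`) get their own independent
#' distributed patterns -- the localizer is a different set of movements, so
#' its fine-grained patterns share nothing with the task's beyond the zone
#' geometry.
#'
#' @param config a [SomatotopyConfig-class].
#' @param conditionSet the task [ConditionSet-class].
#' @param localizerSet optional localizer [ConditionSet-class].
#' @param seed integer seed (defaults to `config@seed`).
#' @return a [CorticalSheet-class].
#' @export
buildSheet <- function(config, conditionSet, localizerSet = NULL,
                       seed = config@seed) {
  validObject(config)
  if (config@distributedAmplitude < 0)
    stop("distributedAmplitude must be >= 0", call. = FALSE)
  if (config@tuningWidthMM <= 0)
    stop("tuningWidthMM must be > 0", call. = FALSE)
  P <- config@nVoxels
  L <- config@axisLengthMM
  coords <- (seq_len(P) - 0.5) * (L / P)
  sig <- config@tuningWidthMM
  a <- config@primaryAmplitude
  eps <- config@distributedAmplitude
  aa <- config@actionAmplitude

  hasActions <- nrow(conditionSet@actionFactor) > 0L
  condPart <- if (hasActions)
    setNames(conditionSet@actionFactor$part, conditionSet@actionFactor$condition)
  else setNames(conditionSet@conditions, conditionSet@conditions)
  condAction <- if (hasActions)
    setNames(conditionSet@actionFactor$action, conditionSet@actionFactor$condition)
  else NULL

  subparts <- conditionSet@subpartOrder
  needed <- unique(c(subparts,
                     if (!is.null(localizerSet)) localizerSet@subpartOrder))
  if (!all(needed %in% names(config@zoneCenters)))
    stop("zoneCenters lacks entries for: ",
         paste(setdiff(needed, names(config@zoneCenters)), collapse = ", "),
         call. = FALSE)

  conds <- conditionSet@conditions
  locConds <- character()
  allConds <- conds
  if (!is.null(localizerSet)) {
    locConds <- paste0("loc.", localizerSet@conditions)
    allConds <- c(conds, locConds)
  }

  bump <- function(mu) a * exp(-(coords - mu)^2 / (2 * sig^2))

  sheet <- withSeed(seed, {
    g <- correlatedPatterns(length(subparts), P, config@neighborCorr)
    rownames(g) <- subparts
    actions <- unique(condAction)
    u <- if (hasActions) {
      um <- matrix(rnorm(length(actions) * P), length(actions), P)
      rownames(um) <- actions
      um
    } else NULL

    meanMaps <- matrix(0, length(allConds), P,
                       dimnames = list(allConds, NULL))
    distMaps <- matrix(0, length(allConds), P,
                       dimnames = list(allConds, NULL))
    for (cn in conds) {
      part <- condPart[[cn]]
      gain <- 1
      d <- eps * g[part, ]
      if (hasActions) {
        actSign <- if (condAction[[cn]] == actions[1L]) -1 else 1
        gain <- 1 + actSign * aa / 2
        d <- d + aa * u[condAction[[cn]], ]
      }
      meanMaps[cn, ] <- gain * bump(config@zoneCenters[[part]])
      distMaps[cn, ] <- d
    }
    if (!is.null(localizerSet)) {
      gl <- correlatedPatterns(length(localizerSet@subpartOrder), P,
                               config@neighborCorr)
      rownames(gl) <- localizerSet@subpartOrder
      for (i in seq_along(locConds)) {
        part <- localizerSet@conditions[i]
        meanMaps[locConds[i], ] <- bump(config@zoneCenters[[part]])
        distMaps[locConds[i], ] <- eps * gl[part, ]
      }
    }
    distMaps <- distMaps - rowMeans(distMaps)
    voxelSd <- runif(P, config@noise@voxelSdRange[1L],
                     config@noise@voxelSdRange[2L])
    zones <- lapply(config@zoneCenters,
                    function(mu) which(abs(coords - mu) <= 2 * sig))
    new("CorticalSheet", coordsMM = coords, meanMaps = meanMaps,
        distMaps = distMaps, zoneMasks = zones, voxelSd = voxelSd,
        smoother = spatialSmoother(coords, config@noise@spatialKernelMM),
        conditionSet = conditionSet, localizerConditions = locConds,
        config = config)
  })
  validObject(sheet)
  sheet
}

#' Ground-truth noise covariance of a sheet
#'
#' Reconstructs the voxel-by-voxel covariance used by the noise generator,
#' \eqn{\Sigma = s^2 D (I + SS') D / 2} with per-voxel SD multipliers D,
#' spatial smoother S and overall scale s, optionally restricted to a voxel
#' subset.
#'
#' @param sheet a [CorticalSheet-class].
#' @param voxels optional integer voxel indices.
#' @return dense covariance matrix over the requested voxels.
#' @export
trueNoiseCov <- function(sheet, voxels = NULL) {
  if (is.null(voxels)) voxels <- seq_along(sheet@coordsMM)
  S <- sheet@smoother[voxels, , drop = FALSE]
  K <- as.matrix(Matrix::tcrossprod(S))
  D <- sheet@voxelSd[voxels]
  s2 <- sheet@config@noise@scannerSd^2
  s2 * (D %o% D) * (diag(length(voxels)) + K) / 2
}

#' Simulate one BOLD run
#'
#' The noise-free part is the boxcar design of the block schedule convolved
#' with the canonical double-gamma HRF, times the sheet's condition patterns
#' (mean plus distributed). Noise is AR(1) in time, spatially correlated
#' (white + smoothed components in equal parts), heteroscedastic across
#' voxels, and fully seeded.
#'
#' @param sheet a [CorticalSheet-class].
#' @param sequence character vector of movement block labels for this run.
#' @param recipe a [SessionRecipe-class].
#' @param seed integer seed for the noise draw.
#' @param noise optional [NoiseConfig-class] overriding the sheet's.
#' @param runIndex run number stored in the result.
#' @return a [RunData-class].
#' @export
simulateRun <- function(sheet, sequence, recipe, seed, noise = NULL,
                        runIndex = 1L) {
  conds <- rownames(sheet@meanMaps)
  if (!all(sequence %in% conds))
    stop("sequence contains conditions unknown to the sheet: ",
         paste(setdiff(sequence, conds), collapse = ", "), call. = FALSE)
  tab <- table(sequence)
  if (any(tab != recipe@blocksPerConditionPerRun))
    stop("sequence is inconsistent with the recipe: each condition must ",
         "appear exactly ", recipe@blocksPerConditionPerRun, " times",
         call. = FALSE)
  sched <- scheduleBlocks(sequence, recipe)
  T <- recipe@nVolumesPerRun
  if (max(sched$onsetS + sched$durationS) > T * recipe@trS + 1e-9)
    stop("block schedule exceeds the run duration", call. = FALSE)
  P <- nVoxels(sheet)

  uniq <- unique(sequence)
  X <- vapply(uniq, function(cn) {
    rows <- sched$condition == cn
    convolveRegressor(sched$onsetS[rows], sched$durationS[rows],
                      T, recipe@trS)
  }, numeric(T))
  Y <- X %*% (sheet@meanMaps[uniq, , drop = FALSE] +
              sheet@distMaps[uniq, , drop = FALSE])

  ncfg <- if (is.null(noise)) sheet@config@noise else noise
  if (ncfg@scannerSd > 0) {
    phi <- ncfg@temporalAR1
    ## burn-in long enough that initialisation transients are < 1e-8
    burn <- if (phi == 0) 0L else
      min(50L, max(10L, ceiling(log(1e-8) / log(abs(phi)))))
    Tb <- T + burn
    ## voxel-major (P x T) layout keeps the AR recursion and per-voxel
    ## scaling on contiguous memory
    E <- withSeed(seed, {
      Zw <- matrix(rnorm(P * Tb), P, Tb)
      Zs <- matrix(rnorm(P * Tb), P, Tb)
      (Zw + as.matrix(sheet@smoother %*% Zs)) / sqrt(2)
    })
    if (phi != 0) {
      for (t in 2L:Tb) E[, t] <- phi * E[, t - 1L] + E[, t]
      E <- E * sqrt(1 - phi^2)
    }
    E <- E[, (burn + 1L):Tb, drop = FALSE] * (sheet@voxelSd * ncfg@scannerSd)
    Y <- Y + t(E)
  }
  new("RunData", timeseries = unname(Y), sequence = sched$condition,
      onsetsS = sched$onsetS, durationsS = sched$durationS,
      runIndex = as.integer(runIndex))
}

#' Simulate one participant (sheet, task runs, localizer runs)
#'
#' @param taskId `"body"`, `"face"`, or `"finger"`.
#' @param config a [SomatotopyConfig-class].
#' @param recipe task [SessionRecipe-class].
#' @param seed integer subject seed; sheet, sequences and run noise all
#'   derive from it.
#' @param localizer simulate an independent localizer session?
#' @param localizerRecipe localizer [SessionRecipe-class].
#' @return list with elements `sheet`, `runs`, `locRuns`, `seed`.
#' @export
simulateSubject <- function(taskId, config, recipe, seed, localizer = TRUE,
                            localizerRecipe = defaultRecipe("localizer")) {
  task <- makeTask(taskId)
  loc <- if (localizer) makeLocalizer() else NULL
  sub <- deriveSeeds(seed, 4L + recipe@nRuns +
                       if (localizer) localizerRecipe@nRuns else 0L)
  sheet <- buildSheet(config, task, localizerSet = loc, seed = sub[1L])
  seqs <- balancedSequence(task, recipe, seed = sub[2L])
  runs <- lapply(seq_len(recipe@nRuns), function(m)
    simulateRun(sheet, seqs[[m]], recipe, seed = sub[4L + m], runIndex = m))
  locRuns <- list()
  if (localizer) {
    locSeqs <- balancedSequence(loc, localizerRecipe, seed = sub[3L])
    locSeqs <- lapply(locSeqs, function(s) paste0("loc.", s))
    locRuns <- lapply(seq_len(localizerRecipe@nRuns), function(m)
      simulateRun(sheet, locSeqs[[m]], localizerRecipe,
                  seed = sub[4L + recipe@nRuns + m], runIndex = m))
  }
  list(sheet = sheet, runs = runs, locRuns = locRuns, seed = seed)
}

#' Simulate a cohort of participants
#'
#' Each participant gets independent distributed patterns, voxel noise SDs
#' and scan noise; the zone geometry (config) is shared. All randomness
#' derives from the master seed via one documented `sample.int()` draw of
#' per-subject seeds, so a cohort regenerates bit-identically.
#'
#' @param taskId `"body"`, `"face"`, or `"finger"`.
#' @param nSubjects number of participants (>= 1).
#' @param seed master integer seed.
#' @param config a [SomatotopyConfig-class].
#' @param recipe task [SessionRecipe-class].
#' @param nHemispheres 1 or 2 sheets per subject (two hemispheres are two
#'   independent sheets sharing the zone geometry).
#' @param localizer simulate localizer sessions?
#' @param localizerRecipe localizer [SessionRecipe-class].
#' @return list with class `"somaCohort"`: `taskId`, `subjects` (each a list
#'   of hemisphere simulations as from [simulateSubject()]), `manifest` of
#'   seeds, and the generating configs.
#' @export
simulateCohort <- function(taskId, nSubjects, seed,
                           config = defaultSomatotopy(taskId, seed = seed),
                           recipe = defaultRecipe(taskId),
                           nHemispheres = 1L, localizer = TRUE,
                           localizerRecipe = defaultRecipe("localizer")) {
  stopifnot(nSubjects >= 1L, nHemispheres %in% c(1L, 2L))
  subjSeeds <- matrix(deriveSeeds(seed, nSubjects * nHemispheres),
                      nSubjects, nHemispheres)
  subjects <- lapply(seq_len(nSubjects), function(i) {
    hemis <- lapply(seq_len(nHemispheres), function(h)
      simulateSubject(taskId, config, recipe, seed = subjSeeds[i, h],
                      localizer = localizer,
                      localizerRecipe = localizerRecipe))
    names(hemis) <- c("L", "R")[seq_len(nHemispheres)]
    list(id = i, hemis = hemis)
  })
  structure(list(taskId = taskId, subjects = subjects, config = config,
                 recipe = recipe, localizerRecipe = localizerRecipe,
                 manifest = list(masterSeed = seed, subjectSeeds = subjSeeds)),
            class = "somaCohort")
}

#' Ground-truth whitened pattern distance
#'
#' The oracle against which estimated crossnobis distances are checked:
#' \eqn{(p_i - p_j)' \Sigma^{-1} (p_i - p_j) / P} over a voxel set, using the
#' sheet's true noise covariance.
#'
#' @param sheet a [CorticalSheet-class].
#' @param conditionPair character vector of two condition labels.
#' @param voxelSet non-empty integer voxel indices.
#' @return scalar squared distance per voxel (a.u.).
#' @export
truePatternDistance <- function(sheet, conditionPair, voxelSet) {
  if (length(voxelSet) == 0L) stop("voxelSet must be non-empty", call. = FALSE)
  conds <- rownames(sheet@meanMaps)
  if (!all(conditionPair %in% conds))
    stop("unknown condition labels: ",
         paste(setdiff(conditionPair, conds), collapse = ", "), call. = FALSE)
  p <- sheet@meanMaps + sheet@distMaps
  delta <- p[conditionPair[1L], voxelSet] - p[conditionPair[2L], voxelSet]
  if (all(delta == 0)) return(0)
  Sigma <- trueNoiseCov(sheet, voxelSet)
  drop(crossprod(delta, solve(Sigma, delta))) / length(voxelSet)
}
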