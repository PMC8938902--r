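# Shared fixtures: small configurations and independent oracles.

whiteNoise <- function(scannerSd = 9, phi = 0.3) {
  new("NoiseConfig", temporalAR1 = phi, spatialKernelMM = 0.8,
      voxelSdRange = c(0.8, 1.2), scannerSd = scannerSd)
}

tinySomatotopy <- function(taskId = "body", nVoxels = 200L, seed = 1L, ...) {
  defaultSomatotopy(taskId, seed = seed, nVoxels = nVoxels, ...)
}

# 2-voxel sheet with identity true noise covariance and hand-set patterns
toySheet <- function(meanMaps, distMaps = meanMaps * 0) {
  cfg <- new("SomatotopyConfig", nVoxels = 2L, axisLengthMM = 2,
             zoneCenters = c(a = 0.5, b = 1.5), tuningWidthMM = 1,
             primaryAmplitude = 1, distributedAmplitude = 0,
             neighborCorr = 0, actionAmplitude = 0,
             noise = new("NoiseConfig", temporalAR1 = 0,
                         spatialKernelMM = 0.1, voxelSdRange = c(1, 1),
                         scannerSd = 1),
             seed = 1L)
  new("CorticalSheet", coordsMM = c(0.5, 1.5), meanMaps = meanMaps,
      distMaps = distMaps, zoneMasks = list(a = 1L, b = 2L),
      voxelSd = c(1, 1), smoother = Matrix::Diagonal(2),
      conditionSet = new("ConditionSet", taskId = "body",
                         conditions = rownames(meanMaps),
                         subpartOrder = rownames(meanMaps),
                         actionFactor = data.frame()),
      localizerConditions = character(), config = cfg)
}

# pattern set straight from an array (condition x run x voxel)
psFromArray <- function(pat, conditions = dimnames(pat)[[1]],
                        whitened = TRUE) {
  if (is.null(conditions))
    conditions <- paste0("c", seq_len(dim(pat)[1]))
  new("PatternSet", patterns = pat, conditions = conditions,
      residuals = list(), runDofs = numeric(), whitened = whitened)
}

# independent crossnobis oracle: explicit double sum over ordered run pairs
crossnobisOracle <- function(pat) {
  C <- dim(pat)[1]; M <- dim(pat)[2]; P <- dim(pat)[3]
  out <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    if (i == j) next
    acc <- 0
    for (m in seq_len(M)) for (n in seq_len(M)) {
      if (m == n) next
      acc <- acc + sum((pat[i, m, ] - pat[j, m, ]) *
                       (pat[i, n, ] - pat[j, n, ]))
    }
    out[i, j] <- acc / (M * (M - 1) * P)
  }
  out
}

# Brute-force ANOVA sum of squares for one effect of a fully crossed,
# balanced design stored as an array (dim 1 = subject, dims 2.. = factors):
# inclusion-exclusion over marginal means, each squared effect weighted by
# its replication count. Independent of aov.
ssEffect <- function(arr, margins) {
  dims <- dim(arr)
  subsets <- list(integer(0))
  for (k in seq_along(margins))
    subsets <- c(subsets, if (length(margins) == 1L) list(margins)
                 else utils::combn(margins, k, simplify = FALSE))
  cells <- as.matrix(expand.grid(lapply(dims[margins], seq_len)))
  tot <- 0
  for (r in seq_len(nrow(cells))) {
    v <- 0
    for (s in subsets) {
      sgn <- (-1)^(length(margins) - length(s))
      if (length(s) == 0L) v <- v + sgn * mean(arr)
      else {
        ms <- apply(arr, s, mean)
        pos <- cells[r, match(s, margins)]
        v <- v + sgn * do.call(`[`, c(list(ms), as.list(pos)))
      }
    }
    tot <- tot + v^2
  }
  tot * prod(dims) / prod(dims[margins])
}

# full within-subject F oracle: effect tested against its subject interaction
bruteForceRmF <- function(arr, margins) {
  dims <- dim(arr)
  dfE <- prod(dims[margins] - 1L)
  dfErr <- dfE * (dims[1L] - 1L)
  ssE <- ssEffect(arr, margins)
  ssErr <- ssEffect(arr, c(1L, margins))
  list(ss = ssE, ssErr = ssErr, df1 = dfE, df2 = dfErr,
       F = (ssE / dfE) / (ssErr / dfErr))
}
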