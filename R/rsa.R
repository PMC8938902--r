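## Crossnobis RSA: shrinkage noise covariance, multivariate noise
## normalisation, cross-validated squared Mahalanobis distances, reductions
## and classical MDS.

#' Assemble a pattern set from run fits
#'
#' Extracts the condition regression coefficients and run residuals from a
#' list of run-level GLM fits, restricted to a voxel set.
#'
#' @param fits list of [GLMFit-class], one per run.
#' @param conditions condition labels to extract (must be condition
#'   regressors in every fit).
#' @param voxels integer voxel indices (default: all).
#' @return a [PatternSet-class] (unwhitened).
#' @export
patternSet <- function(fits, conditions,
                       voxels = seq_len(ncol(fits[[1L]]@betas))) {
  if (is(fits, "GLMFit")) fits <- list(fits)
  M <- length(fits)
  P <- length(voxels)
  pat <- array(NA_real_, c(length(conditions), M, P),
               dimnames = list(conditions, NULL, NULL))
  res <- vector("list", M)
  dofs <- numeric(M)
  for (m in seq_len(M)) {
    cc <- fits[[m]]@design@conditionCols
    if (!all(conditions %in% names(cc)))
      stop("conditions missing from fit ", m, call. = FALSE)
    pat[, m, ] <- fits[[m]]@betas[cc[conditions], voxels, drop = FALSE]
    res[[m]] <- fits[[m]]@residuals[, voxels, drop = FALSE]
    dofs[m] <- fits[[m]]@dof
  }
  ps <- new("PatternSet", patterns = pat, conditions = conditions,
            residuals = res, runDofs = dofs, whitened = FALSE)
  validObject(ps)
  ps
}

#' Restrict a pattern set to a voxel subset
#'
#' @param ps a [PatternSet-class].
#' @param voxels integer indices into the pattern set's voxel dimension.
#' @return a [PatternSet-class] over the requested voxels.
#' @export
subsetVoxels <- function(ps, voxels) {
  new("PatternSet", patterns = ps@patterns[, , voxels, drop = FALSE],
      conditions = ps@conditions,
      residuals = lapply(ps@residuals, function(r) r[, voxels, drop = FALSE]),
      runDofs = ps@runDofs, whitened = ps@whitened)
}

## Ledoit-Wolf / Schaefer-Strimmer analytic shrinkage intensity toward the
## diagonal target, computed from the stacked run residuals.
shrinkageLambda <- function(R) {
  n <- nrow(R)
  S <- crossprod(R) / n
  X2 <- R^2
  varS <- (crossprod(X2) / n - S^2) * n / (n - 1)^2
  off <- row(S) != col(S)
  num <- sum(varS[off])
  den <- sum(S[off]^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Shrinkage estimate of the voxel noise covariance
#'
#' Per-run residual covariances \eqn{R_m'R_m/\mathrm{dof}_m} are averaged
#' across runs and shrunk toward their diagonal, \eqn{\Sigma_\lambda =
#' (1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)}, which preserves the
#' down-weighting of noisy voxels while guaranteeing invertibility when
#' voxels outnumber time points. With `lambda = "auto"` the intensity comes
#' from the Ledoit-Wolf-style analytic formula on the stacked residuals.
#'
#' @param residualsByRun list of volume x voxel residual matrices.
#' @param dofs per-run residual degrees of freedom.
#' @param lambda `"auto"` or a fixed value in [0, 1].
#' @return a [NoiseCov-class].
#' @export
noiseCovariance <- function(residualsByRun, dofs, lambda = "auto") {
  if (is(residualsByRun, "PatternSet")) {
    dofs <- residualsByRun@runDofs
    residualsByRun <- residualsByRun@residuals
  }
  if (length(residualsByRun) < 1L)
    stop("need at least one run of residuals", call. = FALSE)
  if (length(dofs) != length(residualsByRun))
    stop("one dof per run required", call. = FALSE)
  if (all(vapply(residualsByRun, function(r) all(r == 0), logical(1L))))
    stop("degenerate: all residuals are zero", call. = FALSE)
  sigmas <- Map(function(r, d) crossprod(r) / d, residualsByRun, dofs)
  Sigma <- Reduce(`+`, sigmas) / length(sigmas)
  lam <- if (identical(lambda, "auto"))
    shrinkageLambda(do.call(rbind, residualsByRun)) else {
      if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
        stop("lambda must be 'auto' or in [0, 1]", call. = FALSE)
      lambda
    }
  SigmaL <- (1 - lam) * Sigma + lam * diag(diag(Sigma), nrow(Sigma))
  nc <- new("NoiseCov", sigma = SigmaL, lambda = lam, sourceDof = sum(dofs))
  validObject(nc)
  nc
}

## Symmetric inverse square root via eigendecomposition.
invSqrtm <- function(Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("noise covariance is not positive definite", call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Multivariate noise normalisation (prewhitening)
#'
#' Right-multiplies every pattern (and the stored residuals) by
#' \eqn{\Sigma_\lambda^{-1/2}}, the symmetric inverse square root of the
#' shrunk noise covariance, down-weighting noisy voxels and decorrelating
#' neighbours.
#'
#' @param ps a [PatternSet-class].
#' @param noiseCov a [NoiseCov-class] over the same voxels.
#' @return a whitened [PatternSet-class].
#' @export
prewhiten <- function(ps, noiseCov) {
  P <- nVoxels(ps)
  if (nrow(noiseCov@sigma) != P)
    stop("voxel sets of patterns and covariance differ", call. = FALSE)
  W <- invSqrtm(noiseCov@sigma)
  d <- dim(ps@patterns)
  flat <- matrix(ps@patterns, d[1L] * d[2L], d[3L]) %*% W
  new("PatternSet", patterns = array(flat, d), conditions = ps@conditions,
      residuals = lapply(ps@residuals, function(r) r %*% W),
      runDofs = ps@runDofs, whitened = TRUE)
}

#' Cross-validated squared Mahalanobis (crossnobis) dissimilarities
#'
#' For each condition pair (i, j), with per-run whitened patterns b and M
#' runs,
#' \deqn{d_{ij} = \frac{1}{M(M-1)\,P} \sum_{m \ne n}
#'   (b_{i,m} - b_{j,m})'(b_{i,n} - b_{j,n}),}
#' the unbiased double sum over ordered run pairs normalised by voxel count.
#' Because pattern differences from independent runs are multiplied, the
#' expected value is zero when two patterns differ only by noise; estimates
#' may legitimately be negative.
#'
#' @param ps a [PatternSet-class] with at least two runs (whitened patterns
#'   are expected; the estimator itself is agnostic).
#' @param meta named list stored in the RDM's metadata.
#' @return an [RDM-class].
#' @export
crossnobisRDM <- function(ps, meta = list()) {
  d <- dim(ps@patterns)
  M <- d[2L]
  if (M < 2L)
    stop("crossnobis requires at least 2 runs for cross-validation",
         call. = FALSE)
  C <- d[1L]
  P <- d[3L]
  vals <- matrix(0, C, C, dimnames = list(ps@conditions, ps@conditions))
  for (i in seq_len(C - 1L)) {
    Di <- matrix(ps@patterns[i, , ], M, P)
    for (j in (i + 1L):C) {
      Dd <- Di - matrix(ps@patterns[j, , ], M, P)
      G <- tcrossprod(Dd)
      vals[i, j] <- vals[j, i] <- (sum(G) - sum(diag(G))) / (M * (M - 1L) * P)
    }
  }
  meta$voxelCount <- P
  rdm <- new("RDM", values = vals, estimator = "crossnobis", meta = meta)
  validObject(rdm)
  rdm
}

#' Average RDM cells into named groups
#'
#' Reduces an RDM to a named vector of arithmetic means over cell groups --
#' the primitive behind averaging across actions, across hemispheres, and
#' across adjacency classes.
#'
#' @param rdm an [RDM-class].
#' @param groups named list; each element a 2-column matrix (or data.frame)
#'   of condition label pairs whose cells are averaged.
#' @return named numeric vector, one value per group.
#' @export
reduceRDM <- function(rdm, groups) {
  v <- rdm@values
  vapply(groups, function(g) {
    g <- as.matrix(g)
    if (nrow(g) == 0L) stop("empty cell group", call. = FALSE)
    if (!all(g %in% rownames(v)))
      stop("group references unknown conditions", call. = FALSE)
    mean(v[cbind(g[, 1L], g[, 2L])])
  }, numeric(1L))
}

#' Body-part pair groups averaged across actions
#'
#' For the whole-body task, the dissimilarity between two body parts is the
#' mean of the same-action cells: d(feet, lips) = mean over actions a of
#' d(feet.a, lips.a).
#'
#' @param conditionSet the body [ConditionSet-class] (needs an action
#'   factor).
#' @return named list of cell-pair matrices, one per body-part pair, for
#'   [reduceRDM()].
#' @export
actionAveragedGroups <- function(conditionSet) {
  af <- conditionSet@actionFactor
  if (nrow(af) == 0L)
    stop("conditionSet has no action factor", call. = FALSE)
  parts <- unique(af$part)
  actions <- unique(af$action)
  combs <- utils::combn(parts, 2L)
  groups <- lapply(seq_len(ncol(combs)), function(k) {
    cbind(vapply(actions, function(a)
            af$condition[af$part == combs[1L, k] & af$action == a],
            character(1L)),
          vapply(actions, function(a)
            af$condition[af$part == combs[2L, k] & af$action == a],
            character(1L)))
  })
  names(groups) <- paste(combs[1L, ], combs[2L, ], sep = "-")
  groups
}

#' Within-part action dissimilarity groups
#'
#' One group per body part containing the (squeeze, push) cell for that
#' part.
#'
#' @param conditionSet the body [ConditionSet-class].
#' @return named list of single-row cell matrices for [reduceRDM()].
#' @export
actionPairGroups <- function(conditionSet) {
  af <- conditionSet@actionFactor
  if (nrow(af) == 0L)
    stop("conditionSet has no action factor", call. = FALSE)
  parts <- unique(af$part)
  groups <- lapply(parts, function(p) {
    cs <- af$condition[af$part == p]
    matrix(cs, 1L, 2L)
  })
  names(groups) <- parts
  groups
}

#' Average a list of RDMs cell-wise
#'
#' Used to average the two hemispheres' RDMs within a participant.
#'
#' @param rdms list of [RDM-class] with identical conditions.
#' @return an [RDM-class] of cell-wise means.
#' @export
averageRDMs <- function(rdms) {
  if (length(rdms) == 1L) return(rdms[[1L]])
  v <- Reduce(`+`, lapply(rdms, rdmValues)) / length(rdms)
  new("RDM", values = v, estimator = rdms[[1L]]@estimator,
      meta = c(rdms[[1L]]@meta, list(averagedOver = length(rdms))))
}

#' Classical (Torgerson) multidimensional scaling of an RDM
#'
#' Crossnobis values are squared distances; negative cells (legitimate under
#' the unbiased estimator) are rectified to zero with a warning before
#' embedding. Double centering and eigendecomposition are delegated to
#' [stats::cmdscale()] on the rectified root-distance matrix; dimensions
#' beyond the positive-eigenvalue count are zero-filled with a warning. Sign
#' indeterminacy is resolved by flipping each dimension so its first nonzero
#' coordinate (in condition order) is positive.
#'
#' @param rdm an [RDM-class].
#' @param nDims number of embedding dimensions (>= 1).
#' @return condition x nDims coordinate matrix.
#' @export
classicalMDS <- function(rdm, nDims = 2L) {
  if (nDims < 1L) stop("nDims must be >= 1", call. = FALSE)
  v <- rdm@values
  if (any(v < 0)) {
    warning(sprintf("%d negative dissimilarities rectified to 0 for MDS",
                    sum(v < 0) / 2L))
    v[v < 0] <- 0
  }
  C <- nrow(v)
  kmax <- C - 1L
  fit <- cmdscale(sqrt(v), k = min(nDims, kmax), eig = TRUE)
  X <- fit$points
  if (ncol(X) < nDims) {
    warning(sprintf("only %d positive dimensions; zero-filling to %d",
                    ncol(X), nDims))
    X <- cbind(X, matrix(0, C, nDims - ncol(X)))
  }
  X <- X[, seq_len(nDims), drop = FALSE]
  for (k in seq_len(ncol(X))) {
    nz <- which(abs(X[, k]) > 1e-12)
    if (length(nz) && X[nz[1L], k] < 0) X[, k] <- -X[, k]
  }
  rownames(X) <- rownames(v)
  colnames(X) <- paste0("dim", seq_len(ncol(X)))
  X
}
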