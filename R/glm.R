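## Block-design GLM: canonical double-gamma HRF, boxcar convolution, DCT
## drift basis, per-run OLS, and run / fixed-effects contrast statistics.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities sampled at `dt_s`: a positive response
#' peaking at 6 s and an undershoot peaking at 16 s with peak:undershoot
#' ratio 6 (dispersion 1 s for both), the conventional parameterisation. The
#' kernel is scaled to maximum 1 and starts at exactly 0.
#'
#' @param dtS sampling interval (s), > 0.
#' @param durationS kernel support length (s).
#' @param peakDelayS,undershootDelayS gamma density means (s).
#' @param dispersionS gamma scale (s) for both components.
#' @param ratio peak:undershoot amplitude ratio.
#' @return numeric kernel vector of length `durationS/dtS + 1`.
#' @examples
#' h <- hrfDoubleGamma(0.1)
#' which.max(h)  # peak near 5 s
#' @export
hrfDoubleGamma <- function(dtS, durationS = 32, peakDelayS = 6,
                           undershootDelayS = 16, dispersionS = 1,
                           ratio = 6) {
  if (dtS <= 0) stop("dtS must be > 0", call. = FALSE)
  if (peakDelayS <= 0 || undershootDelayS <= 0 || dispersionS <= 0 ||
      ratio <= 0)
    stop("HRF shape parameters must be positive", call. = FALSE)
  t <- seq(0, durationS, by = dtS)
  h <- stats::dgamma(t, shape = peakDelayS / dispersionS,
                     scale = dispersionS) -
       stats::dgamma(t, shape = undershootDelayS / dispersionS,
                     scale = dispersionS) / ratio
  h / max(h)
}

#' Convolve a block boxcar with the canonical HRF
#'
#' Builds the boxcar of the given onsets/durations on a fine grid (50 ms),
#' convolves it with [hrfDoubleGamma()], and samples the result at volume
#' acquisition times. Used identically by the simulator and the design
#' builder, so a noiseless simulated run is exactly linear in the design.
#'
#' @param onsetsS,durationsS block onsets and durations (s).
#' @param nVolumes number of volumes.
#' @param trS repetition time (s).
#' @param dtS internal convolution grid (s).
#' @return numeric vector of length `nVolumes`.
#' @export
convolveRegressor <- function(onsetsS, durationsS, nVolumes, trS,
                              dtS = 0.05) {
  ## The boxcar * HRF convolution equals, per block, the difference of the
  ## HRF's running integral evaluated at (t - onset) and (t - onset - dur);
  ## sampling that closed form at volume times avoids an FFT per regressor.
  key <- sprintf("cumhrf_%.9g", dtS)
  cumh <- .smootherCache[[key]]
  if (is.null(cumh)) {
    cumh <- cumsum(hrfDoubleGamma(dtS, durationS = 40)) * dtS
    .smootherCache[[key]] <- cumh
  }
  C <- function(x) {             # running HRF integral at lag x (s)
    i <- floor(x / dtS) + 1L
    out <- numeric(length(x))
    pos <- i >= 1L
    out[pos] <- cumh[pmin(i[pos], length(cumh))]
    out
  }
  volT <- (seq_len(nVolumes) - 1L) * trS
  reg <- numeric(nVolumes)
  for (b in seq_along(onsetsS))
    reg <- reg + C(volT - onsetsS[b]) - C(volT - onsetsS[b] - durationsS[b])
  reg
}

## Discrete-cosine drift basis: k = 1..K, K = floor(2 * duration / cutoff),
## the standard high-pass parameterisation. The constant term is the
## intercept, counted separately.
dctDriftBasis <- function(nVolumes, trS, hpCutoffS) {
  K <- floor(2 * nVolumes * trS / hpCutoffS)
  if (K < 1L) return(matrix(numeric(0), nVolumes, 0L))
  t <- seq_len(nVolumes) - 0.5
  vapply(seq_len(K),
         function(k) cos(pi * k * t / nVolumes) * sqrt(2 / nVolumes),
         numeric(nVolumes))
}

#' Build a run design matrix
#'
#' One regressor per condition (block boxcar convolved with the double-gamma
#' HRF) plus its finite-difference temporal derivative, an intercept, a
#' discrete-cosine drift basis up to the high-pass cutoff, and optional
#' nuisance columns.
#'
#' @param runData a [RunData-class].
#' @param trS repetition time (s).
#' @param hpCutoffS high-pass cutoff (s); must exceed 2 TR.
#' @param nuisance optional volume x q matrix of nuisance regressors.
#' @param conditions condition order; defaults to order of appearance.
#' @return a [DesignMatrix-class].
#' @export
buildDesign <- function(runData, trS, hpCutoffS, nuisance = NULL,
                        conditions = unique(runData@sequence)) {
  T <- nrow(runData@timeseries)
  if (hpCutoffS < 2 * trS)
    stop("high-pass cutoff must be at least 2 TR", call. = FALSE)
  if (length(runData@onsetsS) && max(runData@onsetsS) >= T * trS)
    stop("onsets must fall within the run duration", call. = FALSE)
  condX <- matrix(numeric(0), T, 0L)
  if (length(conditions))
    condX <- vapply(conditions, function(cn) {
      rows <- runData@sequence == cn
      convolveRegressor(runData@onsetsS[rows], runData@durationsS[rows],
                        T, trS)
    }, numeric(T))
  derivX <- matrix(numeric(0), T, 0L)
  if (length(conditions)) {
    derivX <- apply(condX, 2L, function(x) c(0, diff(x)))
    colnames(derivX) <- paste0(conditions, ".deriv")
  }
  drift <- dctDriftBasis(T, trS, hpCutoffS)
  X <- cbind(condX, derivX, intercept = 1, drift,
             if (!is.null(nuisance)) nuisance)
  types <- c(rep("condition", length(conditions)),
             rep("derivative", length(conditions)), "intercept",
             rep("drift", ncol(drift)),
             rep("nuisance", if (is.null(nuisance)) 0L else ncol(nuisance)))
  colnames(X)[types == "drift"] <- paste0("drift", seq_len(ncol(drift)))
  dm <- new("DesignMatrix", X = X, regressorType = types,
            conditionCols = setNames(seq_along(conditions), conditions),
            hpCutoffS = hpCutoffS, trS = trS)
  validObject(dm)
  dm
}

#' Fit a run-level GLM by ordinary least squares
#'
#' @param runData a [RunData-class].
#' @param design a [DesignMatrix-class] with as many rows as the run has
#'   volumes.
#' @return a [GLMFit-class] with betas, residuals, residual dof and per-voxel
#'   residual variance.
#' @export
fitRun <- function(runData, design) {
  Y <- runData@timeseries
  X <- design@X
  if (nrow(X) != nrow(Y))
    stop("design rows must equal run volumes", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  betas <- qr.coef(qrX, Y)
  res <- Y - X %*% betas
  dof <- nrow(Y) - qrX$rank
  new("GLMFit", betas = betas, residuals = res, dof = dof,
      sigma2 = colSums(res^2) / dof, design = design)
}

#' Contrast weights over condition regressors
#'
#' `vs_rest` puts +1 on the target condition; `vs_all_others` puts +1 on the
#' target and -1/(k-1) on every other condition, summing to zero. Temporal
#' derivatives always get weight 0.
#'
#' @param conditions all condition labels of the design.
#' @param target the condition of interest.
#' @param mode `"vs_rest"` or `"vs_all_others"`.
#' @return a [ContrastSpec-class].
#' @export
makeContrast <- function(conditions, target,
                         mode = c("vs_rest", "vs_all_others")) {
  mode <- match.arg(mode)
  if (!target %in% conditions)
    stop("target is not among the conditions", call. = FALSE)
  w <- setNames(numeric(length(conditions)), conditions)
  w[target] <- 1
  if (mode == "vs_all_others")
    w[setdiff(conditions, target)] <- -1 / (length(conditions) - 1L)
  cs <- new("ContrastSpec", weights = w,
            name = paste0(target, "_", mode), mode = mode)
  validObject(cs)
  cs
}

## t -> z through the cumulative probability, with log-space tails so large
## t do not saturate prematurely; |z| clipped at 8.2 (count reported).
tToZ <- function(t, dof, clip = 8.2) {
  lp <- pt(abs(t), dof, lower.tail = FALSE, log.p = TRUE)
  z <- -sign(t) * qnorm(lp, log.p = TRUE)
  z[t == 0] <- 0
  nClipped <- sum(abs(z) > clip | is.infinite(t))
  z <- pmin(pmax(z, -clip), clip)
  list(z = z, nClipped = as.integer(nClipped))
}

#' Run-level or fixed-effects contrast statistics
#'
#' In `"run"` mode (a single fit), \eqn{t = c'\hat\beta / \sqrt{\hat\sigma^2
#' c'(X'X)^{-1}c}} per voxel. In `"fixed_effects"` mode the run effects are
#' averaged, the variance is the mean run variance divided by the number of
#' runs, and degrees of freedom are summed -- the within-subject
#' fixed-effects combination. z is the standard-normal quantile of the t
#' cumulative probability with sign preserved, clipped at |z| = 8.2;
#' zero-variance voxels yield infinite t, are counted in `nClipped`, and
#' raise a warning.
#'
#' @param fits list of [GLMFit-class] (or a single fit).
#' @param contrast a [ContrastSpec-class].
#' @param mode `"fixed_effects"` (default) or `"run"`.
#' @return a [StatMap-class].
#' @export
contrastStat <- function(fits, contrast,
                         mode = c("fixed_effects", "run")) {
  mode <- match.arg(mode)
  if (is(fits, "GLMFit")) fits <- list(fits)
  if (length(fits) == 0L) stop("need at least one fit", call. = FALSE)
  if (mode == "run" && length(fits) != 1L)
    stop("run mode takes exactly one fit", call. = FALSE)
  per <- lapply(fits, function(fit) {
    cc <- fit@design@conditionCols
    if (!all(names(contrast@weights) %in% names(cc)))
      stop("contrast conditions missing from the design: ",
           paste(setdiff(names(contrast@weights), names(cc)), collapse = ", "),
           call. = FALSE)
    cvec <- numeric(ncol(fit@design@X))
    cvec[cc[names(contrast@weights)]] <- contrast@weights
    XtXinv <- chol2inv(chol(crossprod(fit@design@X)))
    list(effect = drop(cvec %*% fit@betas),
         variance = fit@sigma2 * drop(cvec %*% XtXinv %*% cvec),
         dof = fit@dof)
  })
  effect <- rowMeans(do.call(cbind, lapply(per, `[[`, "effect")))
  variance <- rowMeans(do.call(cbind, lapply(per, `[[`, "variance"))) /
    length(per)
  dof <- sum(vapply(per, `[[`, numeric(1L), "dof"))
  t <- effect / sqrt(variance)
  t[effect == 0] <- 0
  zr <- tToZ(t, dof)
  if (zr$nClipped > 0L)
    warning(sprintf("%d voxel(s) clipped at |z| = 8.2", zr$nClipped))
  new("StatMap", t = t, z = zr$z, effect = effect, variance = variance,
      dof = dof, source = if (length(fits) > 1L) "fixed_effects" else mode,
      nClipped = zr$nClipped)
}
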