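test_that("double-gamma HRF has canonical shape", {
  h <- hrfDoubleGamma(0.01)
  tpk <- (which.max(h) - 1L) * 0.01
  expect_gte(tpk, 5)
  expect_lte(tpk, 6)
  expect_identical(h[1L], 0)
  expect_identical(max(h), 1)
  ## undershoot present and small
  expect_lt(min(h), 0)
  expect_gt(min(h), -0.3)
  expect_error(hrfDoubleGamma(0), "dtS")
  expect_error(hrfDoubleGamma(0.1, peakDelayS = -2), "positive")
})

test_that("design matrix carries HRF regressors, derivatives and DCT drift", {
  rec <- defaultRecipe("body")
  task <- makeTask("body")
  cfg <- tinySomatotopy("body", nVoxels = 40L, noise = whiteNoise(1, 0))
  sheet <- buildSheet(cfg, task, seed = 1)
  run <- simulateRun(sheet, balancedSequence(task, rec, seed = 2)[[1L]],
                     rec, seed = 3)
  des <- buildDesign(run, rec@trS, rec@hpCutoffS,
                     conditions = conditionLabels(task))
  ## drift column count: floor(2 * duration / cutoff)
  dur <- rec@nVolumesPerRun * rec@trS
  expect_identical(sum(des@regressorType == "drift"),
                   as.integer(floor(2 * dur / rec@hpCutoffS)))
  expect_identical(sum(des@regressorType == "condition"), 6L)
  expect_identical(sum(des@regressorType == "derivative"), 6L)
  expect_identical(sum(des@regressorType == "intercept"), 1L)
  ## derivative is not collinear with its regressor
  i <- des@conditionCols[1L]
  j <- which(colnames(des@X) == paste0(names(i), ".deriv"))
  expect_lt(abs(cor(des@X[, i], des@X[, j])), 1)
  expect_error(buildDesign(run, rec@trS, hpCutoffS = 2), "2 TR")
})

test_that("a design with no events contains only intercept and drift", {
  run <- new("RunData", timeseries = matrix(rnorm(200), 100, 2),
             sequence = character(), onsetsS = numeric(),
             durationsS = numeric(), runIndex = 1L)
  des <- buildDesign(run, 1.45, 150, conditions = character())
  expect_setequal(unique(des@regressorType), c("intercept", "drift"))
})

test_that("OLS solves a hand-computed toy system", {
  ## X = [(1,0),(0,1),(1,1)], y = (1,2,3) -> beta = (1,2), residuals 0
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))
  colnames(X) <- c("a", "b")
  des <- new("DesignMatrix", X = X, regressorType = rep("condition", 2L),
             conditionCols = c(a = 1L, b = 2L), hpCutoffS = Inf, trS = 1)
  run <- new("RunData", timeseries = matrix(c(1, 2, 3), 3L, 1L),
             sequence = "a", onsetsS = 0, durationsS = 1, runIndex = 1L)
  fit <- fitRun(run, des)
  expect_equal(unname(fit@betas[, 1L]), c(1, 2), tolerance = 1e-12)
  expect_equal(fit@dof, 1)
})

test_that("noiseless runs recover generating patterns exactly", {
  task <- makeTask("body")
  rec <- defaultRecipe("body")
  cfg <- tinySomatotopy("body", nVoxels = 100L, noise = whiteNoise(0, 0))
  sheet <- buildSheet(cfg, task, seed = 5)
  run <- simulateRun(sheet, balancedSequence(task, rec, seed = 6)[[1L]],
                     rec, seed = 7)
  fit <- fitRun(run, buildDesign(run, rec@trS, rec@hpCutoffS,
                                 conditions = conditionLabels(task)))
  truePat <- sheet@meanMaps[conditionLabels(task), ] +
    sheet@distMaps[conditionLabels(task), ]
  est <- fit@betas[fit@design@conditionCols, ]
  expect_lt(max(abs(est - truePat)) / max(abs(truePat)), 1e-8)
  ## residuals orthogonal to the design
  X <- fit@design@X
  expect_lt(max(abs(crossprod(X, fit@residuals))),
            1e-8 * norm(X, "F") * (norm(fit@residuals, "F") + 1))
})

test_that("extra orthogonal nuisance columns leave condition betas unchanged", {
  task <- makeTask("face")
  rec <- defaultRecipe("face")
  cfg <- tinySomatotopy("face", nVoxels = 50L, noise = whiteNoise(1, 0))
  sheet <- buildSheet(cfg, task, seed = 5)
  run <- simulateRun(sheet, balancedSequence(task, rec, seed = 6)[[1L]],
                     rec, seed = 7)
  des0 <- buildDesign(run, rec@trS, rec@hpCutoffS,
                      conditions = conditionLabels(task))
  ## nuisance orthogonal to everything already in the design
  q <- qr.Q(qr(des0@X))
  v <- rnorm(nrow(des0@X))
  nuis <- matrix(v - q %*% crossprod(q, v), ncol = 1L)
  desN <- buildDesign(run, rec@trS, rec@hpCutoffS, nuisance = nuis,
                      conditions = conditionLabels(task))
  f0 <- fitRun(run, des0)
  fN <- fitRun(run, desN)
  expect_equal(f0@betas[f0@design@conditionCols, ],
               fN@betas[fN@design@conditionCols, ], tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  X <- cbind(a = c(1, 0, 1), b = c(0, 1, 1))
  des <- new("DesignMatrix", X = X, regressorType = rep("condition", 2L),
             conditionCols = c(a = 1L, b = 2L), hpCutoffS = Inf, trS = 1)
  des@X <- cbind(des@X, dup = des@X[, 1L])  # bypass constructor validity
  des@regressorType <- c(des@regressorType, "nuisance")
  run <- new("RunData", timeseries = matrix(1:3, 3L, 1L), sequence = "a",
             onsetsS = 0, durationsS = 1, runIndex = 1L)
  expect_error(fitRun(run, des), "dup")
})

test_that("contrast statistics follow the run and fixed-effects formulas", {
  ## toy fit constructed directly: X orthonormal-ish, known sigma2
  X <- cbind(a = rep(c(1, 0), 10L), b = rep(c(0, 1), 10L))
  set.seed(1)
  Y <- matrix(rnorm(20L * 3L), 20L, 3L)
  des <- new("DesignMatrix", X = X, regressorType = rep("condition", 2L),
             conditionCols = c(a = 1L, b = 2L), hpCutoffS = Inf, trS = 1)
  run <- new("RunData", timeseries = Y, sequence = "a", onsetsS = 0,
             durationsS = 1, runIndex = 1L)
  fit <- fitRun(run, des)
  con <- makeContrast(c("a", "b"), "a", "vs_rest")
  sm1 <- contrastStat(fit, con, mode = "run")
  ## manual t
  XtXinv <- solve(crossprod(X))
  cvec <- c(1, 0)
  tManual <- drop(cvec %*% fit@betas) /
    sqrt(fit@sigma2 * drop(cvec %*% XtXinv %*% cvec))
  expect_equal(sm1@t, tManual, tolerance = 1e-12)
  ## z is the quantile transform of t
  expect_equal(sm1@z, qnorm(pt(sm1@t, sm1@dof)), tolerance = 1e-6)

  ## 4 identical runs: effect unchanged, variance / 4, t doubled
  sm4 <- contrastStat(list(fit, fit, fit, fit), con)
  expect_equal(sm4@effect, sm1@effect)
  expect_equal(sm4@variance, sm1@variance / 4)
  expect_equal(sm4@t, 2 * sm1@t, tolerance = 1e-12)
  expect_identical(sm4@source, "fixed_effects")
  expect_identical(sm4@dof, 4 * sm1@dof)

  ## fixed-effects of one run is the identity
  smFE1 <- contrastStat(list(fit), con)
  expect_equal(smFE1@t, sm1@t)

  ## zero effect -> t = 0, z = 0
  fit0 <- fit
  fit0@betas[] <- 0
  sm0 <- suppressWarnings(contrastStat(fit0, con, mode = "run"))
  expect_true(all(sm0@t == 0))
  expect_true(all(sm0@z == 0))
})

test_that("vs-all-others weights are +1 and -1/(k-1)", {
  conds <- paste0("D", 1:5)
  con <- makeContrast(conds, "D2", "vs_all_others")
  expect_equal(unname(con@weights), c(-0.25, 1, -0.25, -0.25, -0.25))
  expect_equal(sum(con@weights), 0)
  vr <- makeContrast(conds, "D2", "vs_rest")
  expect_equal(unname(vr@weights), c(0, 1, 0, 0, 0))
})

test_that("zero-variance voxels are clipped and counted with a warning", {
  X <- cbind(a = rep(c(1, 0), 8L))
  Y <- matrix(X %*% 2, ncol = 1L)          # perfect fit, zero residual
  des <- new("DesignMatrix", X = X, regressorType = "condition",
             conditionCols = c(a = 1L), hpCutoffS = Inf, trS = 1)
  run <- new("RunData", timeseries = Y, sequence = "a", onsetsS = 0,
             durationsS = 1, runIndex = 1L)
  fit <- fitRun(run, des)
  expect_warning(sm <- contrastStat(fit, makeContrast("a", "a", "vs_rest"),
                                    mode = "run"),
                 "clipped")
  expect_identical(sm@z, 8.2)
  expect_identical(sm@nClipped, 1L)
})
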