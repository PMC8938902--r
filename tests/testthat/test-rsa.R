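test_that("shrinkage covariance matches hand computations", {
  ## lambda = 0, toy residuals, dof 4 -> R'R/4 = diag(0.5, 0.5)
  R <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  nc <- noiseCovariance(list(R), dofs = 4, lambda = 0)
  expect_equal(nc@sigma, diag(c(0.5, 0.5)), tolerance = 1e-12)
  expect_identical(nc@lambda, 0)
  expect_equal(nc@sourceDof, 4)

  ## lambda = 1 -> exactly diagonal
  set.seed(2)
  R2 <- matrix(rnorm(60), 20, 3)
  nc1 <- noiseCovariance(list(R2), dofs = 17, lambda = 1)
  expect_true(all(nc1@sigma[row(nc1@sigma) != col(nc1@sigma)] == 0))

  expect_error(noiseCovariance(list(R * 0), dofs = 4), "degenerate")
  expect_error(noiseCovariance(list(R), dofs = c(1, 2)), "one dof per run")
})

test_that("white residuals give a near-diagonal estimate at large T", {
  set.seed(7)
  sig2 <- 2.5
  R <- matrix(rnorm(50000 * 4, sd = sqrt(sig2)), 50000, 4)
  nc <- noiseCovariance(list(R), dofs = 50000, lambda = "auto")
  off <- nc@sigma[row(nc@sigma) != col(nc@sigma)]
  expect_lt(max(abs(off)), 0.05 * sig2)
  expect_lt(max(abs(diag(nc@sigma) - sig2)), 0.1 * sig2)
  expect_gte(nc@lambda, 0)
  expect_lte(nc@lambda, 1)
})

test_that("averaging across runs and auto shrinkage keep positive definiteness", {
  set.seed(3)
  ## more voxels than time points: only shrinkage makes this invertible
  runs <- lapply(1:2, function(i) matrix(rnorm(15 * 40), 15, 40))
  nc <- noiseCovariance(runs, dofs = c(12, 12), lambda = "auto")
  expect_gt(nc@lambda, 0)
  expect_gt(min(eigen(nc@sigma, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("prewhitening applies the inverse square root of the covariance", {
  pat <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  ps <- psFromArray(pat, c("x", "y", "z"), whitened = FALSE)

  ncI <- new("NoiseCov", sigma = diag(2), lambda = 0, sourceDof = 10)
  expect_equal(prewhiten(ps, ncI)@patterns, pat, tolerance = 1e-12)

  ncD <- new("NoiseCov", sigma = diag(c(4, 1)), lambda = 0, sourceDof = 10)
  wh <- prewhiten(ps, ncD)
  expect_equal(wh@patterns[, , 1L], pat[, , 1L] / 2, tolerance = 1e-12)
  expect_equal(wh@patterns[, , 2L], pat[, , 2L], tolerance = 1e-12)
  expect_true(wh@whitened)

  ## whitened residual covariance is identity at large T
  set.seed(11)
  A <- matrix(c(1, 0.6, 0, 0.8), 2, 2)
  R <- matrix(rnorm(40000), 20000, 2) %*% t(A)
  nc <- noiseCovariance(list(R), dofs = 20000, lambda = 0)
  psR <- new("PatternSet", patterns = array(0, c(1, 2, 2)),
             conditions = "x", residuals = list(R), runDofs = 20000,
             whitened = FALSE)
  whR <- prewhiten(psR, nc)
  expect_equal(crossprod(whR@residuals[[1L]]) / 20000, diag(2),
               tolerance = 0.05)
})

test_that("crossnobis matches hand evaluation and the double-sum oracle", {
  ## M = 2, P = 2, b_i = (1,0), b_j = (0,1) in both runs -> d = 1
  pat <- array(0, c(2, 2, 2))
  pat[1, , ] <- rep(c(1, 0), each = 2)
  pat[2, , ] <- rep(c(0, 1), each = 2)
  rdm <- crossnobisRDM(psFromArray(pat, c("i", "j")))
  expect_identical(rdm@values[1L, 2L], 1)

  ## identical patterns in every run -> exactly 0
  pat[2, , ] <- pat[1, , ]
  expect_identical(crossnobisRDM(psFromArray(pat))@values[1L, 2L], 0)

  ## random small instances equal the explicit ordered-pair double sum
  set.seed(42)
  for (rep in 1:25) {
    C <- sample(2:4, 1L); M <- sample(2:4, 1L); P <- sample(2:6, 1L)
    pat <- array(rnorm(C * M * P), c(C, M, P))
    est <- crossnobisRDM(psFromArray(pat))@values
    expect_equal(unname(est), crossnobisOracle(pat), tolerance = 1e-10)
  }

  ## fewer than 2 runs is rejected
  expect_error(crossnobisRDM(psFromArray(array(1, c(2, 1, 3)))),
               "cross-validation")
})

test_that("crossnobis is unbiased under the null and permutation-equivariant", {
  set.seed(9)
  ds <- replicate(400, {
    base <- rnorm(8)
    pat <- array(NA_real_, c(2, 3, 8))
    for (m in 1:3) for (cc in 1:2) pat[cc, m, ] <- base + rnorm(8)
    crossnobisRDM(psFromArray(pat))@values[1L, 2L]
  })
  expect_lt(abs(mean(ds)), 3 * sd(ds) / sqrt(length(ds)))

  set.seed(10)
  pat <- array(rnorm(3 * 3 * 6), c(3, 3, 6))
  perm <- sample(6)
  d1 <- crossnobisRDM(psFromArray(pat))@values
  d2 <- crossnobisRDM(psFromArray(pat[, , perm]))@values
  expect_equal(d1, d2, tolerance = 1e-12)

  ## symmetry and zero diagonal always hold
  expect_true(isSymmetric(d1))
  expect_true(all(diag(d1) == 0))
})

test_that("RDM reductions average the named cells", {
  task <- makeTask("body")
  conds <- conditionLabels(task)
  v <- matrix(0, 6, 6, dimnames = list(conds, conds))
  v["feet.squeeze", "lips.squeeze"] <- v["lips.squeeze", "feet.squeeze"] <- 2
  v["feet.push", "lips.push"] <- v["lips.push", "feet.push"] <- 4
  rdm <- new("RDM", values = v, estimator = "crossnobis", meta = list())
  grp <- actionAveragedGroups(task)
  red <- reduceRDM(rdm, grp)
  expect_equal(unname(red["feet-lips"]), 3)   # mean of same-action cells
  ## single cell group is a passthrough
  one <- reduceRDM(rdm, list(x = rbind(c("feet.squeeze", "lips.squeeze"))))
  expect_equal(unname(one), 2)
  expect_error(reduceRDM(rdm, list(bad = v[0, 0])), "empty")
  expect_error(reduceRDM(rdm, list(bad = rbind(c("a", "b")))), "unknown")

  ## hemisphere averaging: cell-wise mean of two RDMs
  v2 <- v; v2[] <- v * 2
  r2 <- new("RDM", values = v2, estimator = "crossnobis", meta = list())
  avg <- averageRDMs(list(rdm, r2))
  expect_equal(avg@values["feet.push", "lips.push"], 6)  # (4 + 8) / 2
})

test_that("action pair groups pick the squeeze-push cell per body part", {
  task <- makeTask("body")
  grp <- actionPairGroups(task)
  expect_named(grp, c("feet", "hand", "lips"))
  expect_identical(unname(grp$hand[1, ]), c("hand.squeeze", "hand.push"))
  expect_error(actionPairGroups(makeTask("face")), "action factor")
})

test_that("classical MDS reproduces closed-form embeddings", {
  ## 2 conditions at squared distance 4 -> points 2 apart
  v <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  rdm <- new("RDM", values = v, estimator = "crossnobis", meta = list())
  X <- suppressWarnings(classicalMDS(rdm, 1L))
  expect_equal(abs(X[1L, 1L] - X[2L, 1L]), 2, tolerance = 1e-8)
  ## sign convention: first nonzero coordinate of dim 1 is positive
  expect_gte(X[1L, 1L], 0)

  ## 3 conditions, all pairwise equal -> equilateral triangle
  v3 <- matrix(1, 3, 3) - diag(3)
  dimnames(v3) <- list(letters[1:3], letters[1:3])
  r3 <- new("RDM", values = v3, estimator = "crossnobis", meta = list())
  X3 <- classicalMDS(r3, 2L)
  dd <- dist(X3)
  expect_lt(max(dd) - min(dd), 1e-8)

  ## negative cell is rectified with a warning
  vn <- v3; vn[1, 2] <- vn[2, 1] <- -0.01
  rn <- new("RDM", values = vn, estimator = "crossnobis", meta = list())
  expect_warning(classicalMDS(rn, 2L), "rectified")

  ## more dimensions than positive eigenvalues are zero-filled
  expect_warning(X2 <- classicalMDS(rdm, 2L), "zero-filling")
  expect_true(all(X2[, 2L] == 0))
})

test_that("estimated distances converge to the ground-truth whitened distance", {
  ## noise sd -> 0: full GLM + crossnobis chain recovers the oracle
  task <- makeTask("body")
  rec <- defaultRecipe("body")
  cfg <- tinySomatotopy("body", nVoxels = 150L,
                        noise = whiteNoise(1e-4, 0.2))
  sheet <- buildSheet(cfg, task, seed = 13)
  seqs <- balancedSequence(task, rec, seed = 14)
  fits <- lapply(seq_len(rec@nRuns), function(m) {
    run <- simulateRun(sheet, seqs[[m]], rec, seed = 100 + m, runIndex = m)
    fitRun(run, buildDesign(run, rec@trS, rec@hpCutoffS,
                            conditions = conditionLabels(task)))
  })
  vox <- sheet@zoneMasks$hand[1:30]
  ps <- patternSet(fits, conditionLabels(task), vox)
  ncTrue <- new("NoiseCov", sigma = trueNoiseCov(sheet, vox), lambda = 0,
                sourceDof = Inf)
  rdm <- crossnobisRDM(prewhiten(ps, ncTrue))
  for (pair in list(c("feet.squeeze", "hand.squeeze"),
                    c("hand.squeeze", "hand.push"))) {
    truth <- truePatternDistance(sheet, pair, vox)
    expect_lt(abs(rdm@values[pair[1L], pair[2L]] - truth) / truth, 1e-3)
  }
})
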