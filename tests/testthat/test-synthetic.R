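test_that("canonical task condition sets have the study structure", {
  body <- makeTask("body")
  expect_length(conditionLabels(body), 6L)
  expect_setequal(unique(body@actionFactor$part), c("feet", "hand", "lips"))
  expect_setequal(unique(body@actionFactor$action), c("squeeze", "push"))
  expect_identical(body@subpartOrder, c("feet", "hand", "lips"))

  face <- makeTask("face")
  expect_length(conditionLabels(face), 4L)
  expect_identical(face@subpartOrder, c("forehead", "nose", "lips", "tongue"))

  fing <- makeTask("finger")
  expect_length(conditionLabels(fing), 5L)
  expect_identical(fing@subpartOrder, paste0("D", 1:5))

  expect_error(makeTask("toes"), "unknown taskId")
})

test_that("block sequences are first-order counterbalanced across the session", {
  for (task in list(makeTask("body"), makeTask("face"), makeTask("finger"))) {
    rec <- defaultRecipe(task@taskId)
    seqs <- balancedSequence(task, rec, seed = 11)
    expect_length(seqs, rec@nRuns)
    for (s in seqs)
      expect_true(all(table(s) == rec@blocksPerConditionPerRun))
    tc <- transitionCounts(seqs, conditionLabels(task))
    off <- tc[row(tc) != col(tc)]
    expect_lte(max(off) - min(off), 1L)
    expect_true(all(diag(tc) == 0L))
  }
})

test_that("sequence generation is deterministic and degrades for one condition", {
  task <- makeTask("body")
  rec <- defaultRecipe("body")
  expect_identical(balancedSequence(task, rec, seed = 5),
                   balancedSequence(task, rec, seed = 5))
  expect_false(identical(balancedSequence(task, rec, seed = 5),
                         balancedSequence(task, rec, seed = 6)))
  solo <- new("ConditionSet", taskId = "finger", conditions = "D1",
              subpartOrder = "D1", actionFactor = data.frame())
  expect_warning(s1 <- balancedSequence(solo, rec, seed = 1),
                 "simple repetition")
  expect_true(all(unlist(s1) == "D1"))
})

test_that("distributed maps are mean-free and absent when epsilon is 0", {
  task <- makeTask("finger")
  cfg <- tinySomatotopy("finger", nVoxels = 400L)
  sheet <- buildSheet(cfg, task, seed = 3)
  expect_lt(max(abs(rowMeans(sheet@distMaps))),
            1e-10 * cfg@distributedAmplitude)

  cfg0 <- tinySomatotopy("finger", nVoxels = 400L, distributedAmplitude = 0)
  sheet0 <- buildSheet(cfg0, task, seed = 3)
  expect_true(all(sheet0@distMaps == 0))
  expect_error(tinySomatotopy("finger", distributedAmplitude = -1),
               "distributedAmplitude")
})

test_that("mean maps follow the Gaussian zone model and peak inside zones", {
  task <- makeTask("body")
  cfg <- tinySomatotopy("body", nVoxels = 500L)
  sheet <- buildSheet(cfg, task, seed = 9)
  x <- sheet@coordsMM
  a <- cfg@primaryAmplitude
  sig <- cfg@tuningWidthMM
  ## push condition carries gain 1 + actionAmplitude/2
  gain <- 1 + cfg@actionAmplitude / 2
  expect_equal(sheet@meanMaps["feet.push", ],
               gain * a * exp(-(x - cfg@zoneCenters[["feet"]])^2 /
                                (2 * sig^2)),
               tolerance = 1e-12)
  for (cn in conditionLabels(task)) {
    part <- task@actionFactor$part[task@actionFactor$condition == cn]
    expect_true(which.max(sheet@meanMaps[cn, ]) %in%
                  sheet@zoneMasks[[part]])
  }
})

test_that("adjacent subparts' distributed patterns reach the target correlation", {
  ## rho = 0.8 recovered at P = 2000, tolerance 0.1
  task <- makeTask("finger")
  cfg <- tinySomatotopy("finger", nVoxels = 2000L, neighborCorr = 0.8)
  sheet <- buildSheet(cfg, task, seed = 21)
  r12 <- cor(sheet@distMaps["D1", ], sheet@distMaps["D2", ])
  expect_lt(abs(r12 - 0.8), 0.1)

  ## default rho recovered at P = 5000, tolerance 0.05 (averaged over pairs)
  cfg2 <- tinySomatotopy("finger", nVoxels = 5000L)
  sheet2 <- buildSheet(cfg2, task, seed = 22)
  adj <- vapply(1:4, function(i)
    cor(sheet2@distMaps[paste0("D", i), ],
        sheet2@distMaps[paste0("D", i + 1L), ]), numeric(1L))
  expect_lt(abs(mean(adj) - cfg2@neighborCorr), 0.05)
})

test_that("zero-noise time series equal design times patterns exactly", {
  task <- makeTask("body")
  rec <- defaultRecipe("body")
  cfg <- tinySomatotopy("body", nVoxels = 80L, noise = whiteNoise(0, 0))
  sheet <- buildSheet(cfg, task, seed = 2)
  sq <- balancedSequence(task, rec, seed = 4)[[1L]]
  run <- simulateRun(sheet, sq, rec, seed = 8)
  X <- vapply(conditionLabels(task), function(cn) {
    rows <- run@sequence == cn
    convolveRegressor(run@onsetsS[rows], run@durationsS[rows],
                      rec@nVolumesPerRun, rec@trS)
  }, numeric(rec@nVolumesPerRun))
  Y0 <- X %*% (sheet@meanMaps[conditionLabels(task), ] +
               sheet@distMaps[conditionLabels(task), ])
  expect_equal(run@timeseries, unname(Y0), tolerance = 1e-12)
})

test_that("noise is seeded and does not touch the noise-free part", {
  task <- makeTask("body")
  rec <- defaultRecipe("body")
  cfg <- tinySomatotopy("body", nVoxels = 60L, noise = whiteNoise(2, 0.3))
  sheet <- buildSheet(cfg, task, seed = 2)
  sq <- balancedSequence(task, rec, seed = 4)[[1L]]
  r1 <- simulateRun(sheet, sq, rec, seed = 100)
  r1b <- simulateRun(sheet, sq, rec, seed = 100)
  r2 <- simulateRun(sheet, sq, rec, seed = 101)
  expect_identical(r1@timeseries, r1b@timeseries)
  expect_false(identical(r1@timeseries, r2@timeseries))
  ## both share the same noise-free part (noise override with sd = 0)
  r0 <- simulateRun(sheet, sq, rec, seed = 999, noise = whiteNoise(0, 0))
  n1 <- r1@timeseries - r0@timeseries
  n2 <- r2@timeseries - r0@timeseries
  expect_false(identical(n1, n2))
  expect_lt(abs(mean(n1)), 0.1)   # pure zero-mean noise remains
  expect_lt(abs(mean(n2)), 0.1)
})

test_that("simulated scan noise has the configured lag-1 autocorrelation", {
  task <- makeTask("body")
  cfg <- tinySomatotopy("body", nVoxels = 100L, noise = whiteNoise(1, 0.4))
  sheet <- buildSheet(cfg, task, seed = 11)
  rec <- new("SessionRecipe", trS = 1.45, blockS = 8,
             blocksPerConditionPerRun = 4L, restBlocksPerRun = 5L,
             nRuns = 1L, nVolumesPerRun = 10000L, hpCutoffS = 150)
  sq <- balancedSequence(task, rec, seed = 4)[[1L]]
  run <- simulateRun(sheet, sq, rec, seed = 33)
  E <- run@timeseries[2000:10000, ]   # past all stimulation + HRF tail
  ac <- mean(vapply(seq_len(50), function(v)
    cor(E[-1L, v], E[-nrow(E), v]), numeric(1L)))
  expect_lt(abs(ac - 0.4), 0.05)
})

test_that("runs reject sequences inconsistent with sheet or recipe", {
  task <- makeTask("body")
  rec <- defaultRecipe("body")
  cfg <- tinySomatotopy("body", nVoxels = 50L)
  sheet <- buildSheet(cfg, task, seed = 2)
  sq <- balancedSequence(task, rec, seed = 4)[[1L]]
  expect_error(simulateRun(sheet, c(sq, "elbow.push"), rec, seed = 1),
               "unknown")
  expect_error(simulateRun(sheet, sq[-1L], rec, seed = 1), "inconsistent")
})

test_that("cohorts regenerate bit-identically from the master seed", {
  c1 <- simulateCohort("face", nSubjects = 2L, seed = 77,
                       config = tinySomatotopy("face", nVoxels = 60L,
                                               noise = whiteNoise(1, 0.2)))
  c2 <- simulateCohort("face", nSubjects = 2L, seed = 77,
                       config = tinySomatotopy("face", nVoxels = 60L,
                                               noise = whiteNoise(1, 0.2)))
  expect_identical(c1$subjects[[1L]]$hemis$L$runs[[1L]]@timeseries,
                   c2$subjects[[1L]]$hemis$L$runs[[1L]]@timeseries)
  expect_identical(c1$manifest, c2$manifest)
  expect_length(c1$subjects, 2L)
  expect_length(c1$subjects[[1L]]$hemis$L$runs, 3L)  # face task: 3 runs
  single <- simulateCohort("face", nSubjects = 1L, seed = 5,
                           config = tinySomatotopy("face", nVoxels = 40L),
                           localizer = FALSE)
  expect_length(single$subjects, 1L)
})

test_that("ground-truth whitened distance matches hand computation", {
  mm <- rbind(a = c(1, 0), b = c(0, 1))
  sheet <- toySheet(mm)
  expect_equal(truePatternDistance(sheet, c("a", "b"), 1:2), 1.0)
  expect_identical(truePatternDistance(sheet, c("a", "a"), 1:2), 0)
  expect_error(truePatternDistance(sheet, c("a", "zz"), 1:2), "unknown")
  expect_error(truePatternDistance(sheet, c("a", "b"), integer()),
               "non-empty")

  ## epsilon = 0: no distributed signal, zero distance outside all zones
  task <- makeTask("body")
  cfg <- tinySomatotopy("body", nVoxels = 300L, distributedAmplitude = 0,
                        actionAmplitude = 0)
  sh <- buildSheet(cfg, task, seed = 6)
  ## window far (> 3.5 sigma) from both the feet and lips zones
  far <- which(sh@coordsMM > 22 & sh@coordsMM < 28)
  d <- truePatternDistance(sh, c("feet.squeeze", "lips.squeeze"), far)
  expect_lt(d, 1e-6)
})
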