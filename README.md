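# somarsa

Cross-validated multivariate pattern analysis of somatotopic maps, with a
fully specified synthetic generator for validation.

## The problem

The somatosensory homunculus is classically drawn as a sequence of discrete
territories: feet medial, hand central, face lateral. Univariate fMRI
selectivity (mean activation versus rest) supports that picture. But mean
activation is not the same thing as *information*: a region may carry
discriminable fine-grained patterns about a body part it is not "selective"
for. somarsa implements the analysis chain that separates the two
quantities — and shows, on synthetic cohorts with known ground truth, that
the chain draws the right conclusions:

* block-design **GLM** with a double-gamma HRF, temporal derivatives and
  discrete-cosine drift regressors (`hrfDoubleGamma`, `buildDesign`,
  `fitRun`, `contrastStat`);
* **multivariate noise normalisation** from GLM residuals with
  diagonal-target shrinkage (`noiseCovariance`, `prewhiten`);
* **crossnobis dissimilarities** — cross-validated squared Mahalanobis
  distances over runs, unbiased around zero, normalised by voxel count
  (`crossnobisRDM`), with reductions across actions, hemispheres and
  adjacency classes (`reduceRDM`) and classical MDS for visualisation
  (`classicalMDS`);
* **selectivity-based ROIs**: the 50 most activated voxels per body-part
  localizer contrast within disjoint anatomical masks (`defineROIs`), and
  **band-wise strip profiles** in 30 equal-height medio-lateral bands
  (`makeBands`, `bandProfiles`, `findPeakBands`);
* **group statistics**: Shapiro-Wilk-gated t / exact Wilcoxon tests,
  Bonferroni-corrected alphas (0.05/3 → 0.017, 0.05/4 → 0.013), Cohen's d
  with noncentral-t confidence intervals, trend flags at twice the
  corrected alpha, repeated-measures ANOVA with Greenhouse-Geisser
  correction (`oneSampleTest`, `pairedTest`, `bonferroniAlpha`,
  `rmAnovaGG`, `hemisphereAverage`);
* a **synthetic somatotopy generator**: a 1-D medio-lateral cortical sheet
  whose conditions carry Gaussian mean-activation zones plus mean-free
  distributed patterns correlated ρ^(rank distance) between neighbouring
  subparts, scanned with AR(1), spatially correlated, heteroscedastic
  noise under study-style block protocols (`makeTask`, `balancedSequence`,
  `buildSheet`, `simulateRun`, `simulateCohort`), with closed-form ground
  truth for oracle tests (`truePatternDistance`).

The central quantity is the crossnobis estimate for conditions *i, j*
over *M* runs and *P* voxels of prewhitened patterns *b*:

    d_ij = 1 / (M (M-1) P) * sum_{m != n} (b_im - b_jm)' (b_in - b_jn)

Cross-run products make the estimator unbiased: E[d] = 0 when patterns
differ only by noise (negative estimates are legitimate), so a one-tailed
group test of d > 0 is a valid test of information content.

## Worked example

```r
library(somarsa)
cfg <- experimentConfig("body", seed = 42, bands = FALSE)  # 22 subjects
exp <- runExperiment(cfg)
experimentSummary(exp)
```

```
Task 'body', 22 subjects, seed 42
  selectivity            leg: yes, hand: yes, face: yes
  remoteInformation      leg: yes, hand: yes, face: yes
  allPairsInformative    leg: yes, hand: yes, face: yes
```

`selectivity` says each ROI's univariate activity is significant only for
its primary body part (two-tailed one-sample t versus zero, α = 0.017);
`remoteInformation` says the crossnobis dissimilarity between the two
*non-primary* body parts is significantly above zero in every ROI
(one-tailed, α = 0.017) — information far beyond the classical territory.
The underlying numbers:

```r
subset(exp$stats$partDissim, roi == "leg",
       c(comparison, statistic, p, d, significant))
```

```
  comparison statistic            p        d significant
3  feet-hand  33.27636 5.903811e-20 7.094545        TRUE
6  feet-lips  28.25129 1.709400e-18 6.023195        TRUE
9  hand-lips  11.11843 1.467133e-10 2.370457        TRUE
```

In the leg ROI even the hand–lips pair — both parts remote — carries
t(21) ≈ 11.1. Setting `distributedAmplitude = 0` in the somatotopy config
(the package's negative control) abolishes exactly these remote-pair
effects while leaving primary selectivity intact. Long-format CSVs of
every table come from `writeExperimentCSVs(exp, dir)`; RDMs, ROI sets and
band partitions serialize with `writeRDMLong`, `writeRDMJson`,
`writeRegionsJson`; runs round-trip through NIfTI + events TSV with
`writeRun`/`readRun`, and externally estimated beta volumes enter through
`patternSetFromNifti`.

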