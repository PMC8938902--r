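---
title: "Distributed body-part information along a simulated somatosensory map"
author: "somarsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed body-part information along a simulated somatosensory map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somarsa)
```

## The question and the analysis

Classical somatotopic mapping assigns each body part a discrete territory in
primary somatosensory cortex (S1): feet medial, hand central, face lateral.
Univariate selectivity (mean activation versus rest) supports this picture.
Multivariate analyses ask a different question: even where a body part evokes
no net activation, do the fine-grained voxel patterns still *discriminate*
its movements? somarsa implements the full analysis chain needed to answer
that question and a generative model to exercise it with known ground truth:

1. **GLM estimation** of per-run condition patterns from block-design BOLD
   time series (double-gamma HRF, temporal derivatives, discrete-cosine
   drift regressors, ordinary least squares).
2. **Multivariate noise normalisation**: the voxel-by-voxel covariance of
   the GLM residuals, averaged over runs and shrunk toward its diagonal,
   whitens the patterns so noisy voxels are down-weighted.
3. **Crossnobis dissimilarities**: the cross-validated squared Mahalanobis
   distance between condition patterns,
   \deqn{d_{ij} = \frac{1}{M(M-1)P} \sum_{m \ne n}
   (b_{i,m}-b_{j,m})^\top (b_{i,n}-b_{j,n}),}
   with runs \eqn{m, n} as independent folds and \eqn{P} the voxel count.
   Because pattern differences from different runs are multiplied, noise
   does not inflate the estimate: its expectation is zero when two
   conditions differ only by noise, and estimates may legitimately be
   negative. A group test of \eqn{d > 0} is therefore a valid test of
   information content.
4. **Winner-takes-all ROIs**: the 50 most selective voxels per body part
   from an independent localizer contrast (each part versus all others),
   restricted to disjoint anatomical sub-regions of the strip.
5. **Band profiling**: the same univariate and multivariate quantities in
   30 equal-height medio-lateral bands, giving activity and information
   profiles along the whole strip.
6. **Group statistics**: Shapiro-Wilk-gated one-sample and paired tests
   (t or exact Wilcoxon signed-rank), Bonferroni-corrected alphas with the
   conventional 3-decimal reporting, Cohen's d with noncentral-t confidence
   intervals, a trend band at twice the corrected alpha, and
   repeated-measures ANOVA with Greenhouse-Geisser correction for the
   hemisphere-averaging gate.

## The generative model

No generative model of distributed somatotopic information exists in the
literature at the level of detail an implementation needs, so the package
states its own, chosen as the *minimal* structure that produces
"information without activation" together with a topographic gradient.

The cortical sheet is one-dimensional along the medio-lateral axis. Every
analysis in scope (ROIs, bands) consumes axis intervals, so a 1-D geometry
carries all the structure that matters; the strip treatment of BA3b as a
sequence of bands makes the same idealisation.

Each condition \eqn{c} (subpart \eqn{s(c)}, optionally action \eqn{a(c)})
contributes to voxel \eqn{x}:

* a **mean map** \eqn{g_c \cdot a \exp(-(x-\mu_{s(c)})^2/2\sigma^2)} —
  classical selectivity confined to the subpart's zone;
* a **distributed pattern** \eqn{\epsilon\, g_{s(c)}(x)} present across the
  whole sheet and mean-free over voxels, so it adds information but no net
  activation. The subpart patterns form an AR(1) chain over the cortical
  subpart order, \eqn{g_{s_k} = \rho\, g_{s_{k-1}} + \sqrt{1-\rho^2}\, z_k},
  giving corr \eqn{\rho^{|i-j|}} between subparts at rank distance
  \eqn{|i-j|}. This single parameter produces adjacent < non-adjacent
  dissimilarity *everywhere* on the sheet — the topographic gradient;
* for the whole-body task, an **action component**: a mean-free pattern
  \eqn{\alpha\, u_{a(c)}(x)} shared across body parts, plus a relative
  univariate gain \eqn{g_c = 1 \pm \alpha/2} between the two actions.
  Sharing \eqn{u_a} across body parts keeps same-action body-part contrasts
  free of action variance, so setting \eqn{\epsilon = 0} cleanly abolishes
  body-part information (the package's negative control), while squeeze
  versus push remains discriminable everywhere and evokes univariate
  differences only inside the mover's own zone. Body-part-specific action
  interactions are deliberately omitted — they would add realism but no
  qualitative structure the analyses consume.

Noise is Gaussian, AR(1) in time (\eqn{\phi}), heteroscedastic across
voxels, and spatially structured as the sum of a white and a smoothed
component of equal variance (thermal plus physiological noise). The equal
white share keeps the true covariance well conditioned; the smoother rows
are L2-normalised so marginal variances are exact. The true covariance is
available in closed form for oracle tests
(`trueNoiseCov()`, `truePatternDistance()`).

### Default parameters

| parameter | default | meaning |
|---|---|---|
| P | 1500 voxels | sheet resolution; 50 voxels per 2.09 mm band, matching the ~46 voxels/band of surface-sampled fMRI |
| L | 62.7 mm | strip length; 30 bands of 2.09 mm |
| zone centres | feet 8, hand 31, lips 56 mm (digits 37..25, face subparts 48..60) | medio-lateral homunculus order |
| \eqn{\sigma} | 4 mm | zone tuning width |
| a | 3 | peak mean amplitude (a.u.) |
| \eqn{\epsilon} | 0.3 | distributed amplitude |
| \eqn{\rho} | 0.6 | neighbour correlation |
| \eqn{\alpha} | 0.3 | action amplitude |
| \eqn{\phi} | 0.3 | temporal lag-1 autocorrelation |
| spatial kernel | 0.8 mm | noise smoothness |
| voxel SD range | 0.8–1.2 | heteroscedasticity |
| scanner SD | 9 | overall noise scale |

Block timing, run counts, cohort sizes (22 subjects for body/face, 19 for
fingers), TR (1.45 s), block durations (8 s; 9 s fingers; 12 s localizer),
repetitions (4 blocks/condition/run, 5 rest blocks) and high-pass cutoffs
(150/119/150 s; 280 s localizer) follow the study-style protocol the
generator emulates and are fixed in `defaultRecipe()`.

The amplitudes are calibrated to the qualitative result pattern, not to any
printed statistic: the scanner noise scale 9 puts peak fixed-effects z
levels in the 5–8 range typical of block-design localizers (comfortably
below the 8.2 z-clip, so group tests retain between-subject variance) while
leaving distributed information strong enough that remote-pair
dissimilarities carry group t values an order of magnitude above the
corrected significance threshold. These defaults were chosen once, against
that qualitative target, and are not tuned per analysis.

### What the generator does *not* emulate

Head motion, field inhomogeneity, cortical folding and surface geometry,
multi-session registration error, physiological nuisance structure beyond
AR(1) + spatial smoothness, and any deviation of the true HRF from the
canonical double gamma. Passing tests therefore certify the *analysis
machinery* — estimator correctness, unbiasedness, calibration, and the
logical chain from generative structure to statistical conclusion — not
robustness to the artefacts of real acquisitions.

## Numerical and design choices

* **Drift handling**: discrete-cosine regressors up to the cutoff frequency
  inside the GLM rather than a separate filtering pass; equivalent purpose,
  exactly reproducible, and the drift basis count `floor(2·duration/cutoff)`
  is the conventional one.
* **HRF**: canonical double gamma (6 s peak, 16 s undershoot, ratio 6,
  dispersion 1 s), kernel scaled to max 1; parameters are arguments, not
  constants. Boxcar convolution is evaluated through the HRF's running
  integral on a 50 ms grid — exact for block designs and cheap.
* **Derivatives** are included in every design and excluded (weight 0) from
  every contrast.
* **z from t** via the cumulative-probability quantile transform with
  log-space tails, clipped at |z| = 8.2; clip counts are reported on the
  StatMap.
* **Shrinkage target** is the diagonal of the run-averaged residual
  covariance (not a scaled identity): invertibility is guaranteed when
  voxels outnumber time points while per-voxel noise levels — the
  down-weighting that motivates noise normalisation — are preserved. The
  intensity comes from the Ledoit-Wolf-style analytic formula unless fixed.
* **Cross-validation folds** are runs (all ordered run pairs). Distances
  are divided by the voxel count so ROIs (fixed 50 voxels) and bands
  (variable) are comparable.
* **Negative distances** are retained everywhere except MDS, which
  rectifies them to zero (with a warning) before Torgerson double
  centering; embeddings resolve their sign indeterminacy by a fixed
  convention (first nonzero coordinate of each dimension positive).
* **Ties** in top-voxel selection break toward the lower voxel index;
  bands are half-open [start, end) with the last band closed; voxel
  indices are 1-based in R and 0-based in serialized output, stated in
  each file.
* **Band exclusion**: bands with fewer than 5 voxels are dropped and
  recorded. The number is a config knob; the published analysis excluded
  one band for sparse coverage without stating a count.
* **Peak detection** on band curves: the global maximum plus any local
  maximum at \eqn{\ge} 90% of it — a rule that captures multi-peaked
  profiles (e.g. a double hand peak) without reading values off a figure;
  the threshold is exposed.
* **Wilcoxon fallback** uses the exact null distribution for n \eqn{\le} 25
  and the continuity-corrected normal approximation above; the normality
  gate is Shapiro-Wilk at p < 0.05.
* **Band count**: the strip is segmented into 30 bands; the sparse-coverage
  exclusion typically leaves 29 analysed, consistent with published
  descriptions that mention both numbers.
* **Hemispheres**: cohorts can carry one or two hemispheres (two
  independent sheets sharing zone geometry). The hemisphere ANOVA gate is
  reported and averaging proceeds regardless, mirroring the
  published reasoning. Single-hemisphere cohorts are the default study
  condition for the acceptance analyses: hemisphere averaging only reduces
  noise and leaves every qualitative contrast unchanged.
* **Localizer independence**: the localizer conditions carry their own
  distributed patterns, independent of the task's, so winner-takes-all
  selection cannot bias the task statistics toward or away from zero.

## Problem sizes used in the test suite

Unit and property tests run on scaled-down sheets (60–600 voxels, 1–6
subjects) chosen to make every oracle exact or its Monte-Carlo error
negligible. The acceptance suite runs the full study conditions: 20
replicate 22-subject body cohorts (each with an \eqn{\epsilon = 0}
control), 50 replicate 19-subject finger cohorts, 1000-subject null
simulations for unbiasedness, 10,000 draws for type-I calibration, and
200 random instances for the estimator/oracle equivalence.

## Known limitations

* The sheet is 1-D; analyses that depend on 2-D topology (consistency
  maps, surface registration) are out of scope.
* The GLM is OLS; serial correlation is handled in the generative model
  and by the downstream noise normalisation, not by prewhitening the
  time-series fit itself.
* Effect magnitudes are in arbitrary units calibrated to the qualitative
  pattern; printed statistics from any real cohort are not reproduction
  targets at desk scale.
* The rmANOVA is fully within-subject and balanced only (no missing cells,
  no between-subject factors, no covariates).

## A worked example

```{r example, eval = FALSE}
library(somarsa)

## a scaled-down cohort for illustration (the defaults run the full study
## conditions and take a few minutes)
cfg <- experimentConfig("body", seed = 7, nSubjects = 8,
                        somatotopy = defaultSomatotopy("body", seed = 7,
                                                       nVoxels = 500))
exp <- runExperiment(cfg)
experimentSummary(exp)
exp$stats$partDissim          # crossnobis > 0 tests per ROI and pair
exp$stats$selectivity         # univariate activity per ROI and body part
exp$mds$leg                   # 2-D embedding of the leg-ROI group RDM
writeExperimentCSVs(exp, "results")
```

See the README for a complete worked example with printed output.
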