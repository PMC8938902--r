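Package: somarsa
Title: Crossnobis Representational Similarity Analysis of Simulated Somatotopic Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how body-part information is distributed across the
    somatosensory homunculus. Provides a generator for synthetic somatotopic
    cortical sheets and block-design BOLD time series with known ground truth,
    voxel-wise GLM estimation with a double-gamma haemodynamic response,
    multivariate noise normalisation with shrinkage covariance estimation,
    cross-validated Mahalanobis (crossnobis) dissimilarities, winner-takes-all
    region-of-interest definition from localizer contrasts, band-wise profiling
    of a cortical strip, and the group-level statistics (one-sample and paired
    tests with normality gating, Bonferroni correction, Cohen's d with
    noncentral-t confidence intervals, repeated-measures ANOVA with
    Greenhouse-Geisser correction) needed to assess univariate selectivity and
    multivariate information content along a somatotopic axis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
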