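## Group-level inference: univariate information content, adjacency
## grouping, normality-gated one-sample/paired tests with Cohen's d and
## noncentral-t confidence intervals, Bonferroni correction, and
## repeated-measures ANOVA with Greenhouse-Geisser correction.

#' Mean univariate activity of an ROI
#'
#' The arithmetic mean of the per-voxel z statistic over the ROI's voxels --
#' the classical mapping quantity.
#'
#' @param statMap a [StatMap-class] (or bare z vector).
#' @param roi non-empty integer voxel indices.
#' @return scalar mean z (a.u.).
#' @export
univariateLevel <- function(statMap, roi) {
  if (length(roi) == 0L) stop("ROI is empty", call. = FALSE)
  z <- if (is(statMap, "StatMap")) statMap@z else statMap
  mean(z[roi])
}

#' Adjacent and non-adjacent subpart pairs
#'
#' Consecutive subparts in cortical order are adjacent; all other pairs are
#' non-adjacent. With n subparts there are n-1 adjacent and
#' choose(n,2)-(n-1) non-adjacent pairs.
#'
#' @param subpartOrder character vector of subparts in cortical order (or a
#'   [ConditionSet-class]).
#' @return list with 2-column character matrices `adjacent` and
#'   `nonAdjacent`.
#' @export
adjacencyPairs <- function(subpartOrder) {
  if (is(subpartOrder, "ConditionSet"))
    subpartOrder <- subpartOrder@subpartOrder
  n <- length(subpartOrder)
  if (n < 3L)
    stop("adjacency grouping needs at least 3 subparts ",
         "(no non-adjacent class otherwise)", call. = FALSE)
  combs <- t(utils::combn(subpartOrder, 2L))
  rankDist <- abs(match(combs[, 1L], subpartOrder) -
                  match(combs[, 2L], subpartOrder))
  list(adjacent = combs[rankDist == 1L, , drop = FALSE],
       nonAdjacent = combs[rankDist > 1L, , drop = FALSE])
}

#' Univariate information content between conditions
#'
#' The absolute difference between the mean univariate activity levels
#' evoked by two movements, averaged within the requested pair groups (e.g.
#' the two same-action differences of a body-part pair, or all pairs of an
#' adjacency class).
#'
#' @param levels named numeric vector of univariate levels per condition.
#' @param groups named list of 2-column label matrices (as produced by
#'   [adjacencyPairs()], [actionAveragedGroups()], ...).
#' @return named numeric vector of mean absolute differences per group.
#' @export
univariateContent <- function(levels, groups) {
  vapply(groups, function(g) {
    g <- as.matrix(g)
    if (!all(g %in% names(levels)))
      stop("unknown condition labels in pair group", call. = FALSE)
    mean(abs(levels[g[, 1L]] - levels[g[, 2L]]))
  }, numeric(1L))
}

#' Bonferroni-corrected alpha level
#'
#' `familyAlpha / m`, with the conventional 3-decimal rounding used for
#' reporting (0.05/3 -> 0.017); the unrounded value is kept for decisions.
#'
#' @param familyAlpha family-wise alpha.
#' @param m number of tests (>= 1).
#' @return the corrected alpha with attribute `"reported"` (3-decimal).
#' @export
bonferroniAlpha <- function(familyAlpha = 0.05, m) {
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  a <- familyAlpha / m
  structure(a, reported = round(a, 3L))
}

## Cohen's d confidence interval by noncentral-t inversion: the ncp values
## whose noncentral-t distribution puts the observed t at the requested
## quantiles, divided by sqrt(n).
cohensDCI <- function(tObs, n, level = 0.95, tail = "two") {
  df <- n - 1L
  solveNcp <- function(prob) {
    f <- function(ncp) suppressWarnings(pt(tObs, df, ncp)) - prob
    lim <- max(20, abs(tObs) * 3 + 20)
    out <- try(uniroot(f, c(-lim, lim), tol = 1e-8)$root, silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }
  ci <- switch(tail,
    two = c(lo = solveNcp(1 - (1 - level) / 2),
            hi = solveNcp((1 - level) / 2)),
    greater = c(lo = solveNcp(level), hi = Inf),
    c(lo = -Inf, hi = solveNcp(1 - level)))
  ci / sqrt(n)
}

testResultRow <- function(testUsed, statistic, p, tail, n, d, ci, alpha,
                          shapiroP, degenerate = FALSE) {
  alphaRaw <- as.numeric(alpha)
  sig <- !degenerate && !is.na(p) && p < alphaRaw
  trend <- !degenerate && !is.na(p) && p >= alphaRaw && p < 2 * alphaRaw
  data.frame(test_used = testUsed, statistic = statistic, p = p, tail = tail,
             n = n, d = d, d_ci_lo = ci[[1L]], d_ci_hi = ci[[2L]],
             alpha = alphaRaw,
             alpha_reported = round(alphaRaw, 3L),
             significant = sig, trend = trend, degenerate = degenerate,
             shapiro_p = shapiroP, stringsAsFactors = FALSE)
}

#' One-sample test versus zero with normality gating
#'
#' Shapiro-Wilk is applied first; if its p-value falls below 0.05 the
#' Wilcoxon signed-rank test replaces the one-sample t-test (exact null
#' distribution for n <= 25, normal approximation with continuity
#' correction above). Cohen's d = mean/SD with a confidence interval from
#' noncentral-t inversion. A result is significant when p < alpha and a
#' trend when alpha <= p < 2 alpha.
#'
#' @param values numeric vector, n >= 3.
#' @param tail `"two"`, `"greater"`, or `"less"`.
#' @param alpha corrected alpha level for the decision flags.
#' @param mu null value (default 0).
#' @return one-row data.frame (statistic, p, n, d with CI, alpha, flags).
#' @export
oneSampleTest <- function(values, tail = c("two", "greater", "less"),
                          alpha = 0.05, mu = 0) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  centered <- values - mu
  if (sd(centered) == 0) {
    if (all(centered == 0)) {
      ## exactly the null everywhere: no evidence either way
      p0 <- if (tail == "two") 1 else 0.5
      return(testResultRow("t", 0, p0, tail, n, 0,
                           c(NA_real_, NA_real_), alpha, NA_real_))
    }
    ## constant nonzero offset: zero variance, effect size undefined
    return(testResultRow("degenerate", NA_real_, NA_real_, tail, n,
                         NA_real_, c(NA_real_, NA_real_), alpha, NA_real_,
                         degenerate = TRUE))
  }
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  swP <- shapiro.test(centered)$p.value
  d <- mean(centered) / sd(centered)
  tObs <- d * sqrt(n)
  ci <- cohensDCI(tObs, n, tail = tail)
  if (swP < 0.05) {
    wt <- suppressWarnings(
      wilcox.test(centered, mu = 0, alternative = alt,
                  exact = n <= 25L, correct = TRUE))
    testResultRow("wilcoxon", unname(wt$statistic), wt$p.value, tail, n, d,
                  ci, alpha, swP)
  } else {
    tt <- t.test(centered, mu = 0, alternative = alt)
    testResultRow("t", unname(tt$statistic), tt$p.value, tail, n, d, ci,
                  alpha, swP)
  }
}

#' Paired test via the one-sample machinery on differences
#'
#' @param a,b equal-length numeric vectors (n >= 3).
#' @param tail,alpha as in [oneSampleTest()].
#' @return one-row data.frame as from [oneSampleTest()].
#' @export
pairedTest <- function(a, b, tail = c("two", "greater", "less"),
                       alpha = 0.05) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  oneSampleTest(a - b, tail = match.arg(tail), alpha = alpha)
}

## Orthonormal within-factor contrast basis ((l-1) x l).
orthoContrasts <- function(l) {
  if (l < 2L) stop("factor needs >= 2 levels", call. = FALSE)
  C <- stats::contr.helmert(l)
  t(qr.Q(qr(C)))
}

## Greenhouse-Geisser epsilon for one within-subject effect, from the
## covariance of the subjects' scores on the effect's orthonormal contrasts.
ggEpsilon <- function(scores) {
  q <- ncol(scores)
  if (q == 1L) return(1)
  S <- cov(scores)
  tr <- sum(diag(S))
  if (tr <= 0) return(1)
  eps <- tr^2 / (q * sum(S * S))
  min(1, max(1 / q, eps))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject factorial ANOVA (1-3 factors) on a complete balanced
#' long-format table. Sums of squares, F and uncorrected p come from the
#' classical subject-stratified decomposition (each effect tested against
#' its interaction with subjects); the Greenhouse-Geisser epsilon of each
#' effect is computed from the covariance of the subjects' orthonormal
#' contrast scores, and the corrected p uses epsilon-scaled degrees of
#' freedom. Effects with a single degree of freedom have epsilon 1 exactly.
#'
#' @param data long-format data.frame.
#' @param dv name of the value column.
#' @param subject name of the subject id column.
#' @param factors character vector of 1-3 within-subject factor columns.
#' @return data.frame with one row per effect: `effect`, `ss`, `ss_error`,
#'   `df1`, `df2`, `F`, `p`, `epsilon`, `p_gg`.
#' @export
rmAnovaGG <- function(data, dv, subject, factors) {
  stopifnot(length(factors) >= 1L, length(factors) <= 3L)
  data[[subject]] <- factor(data[[subject]])
  for (f in factors) data[[f]] <- factor(data[[f]])
  levs <- lapply(data[factors], levels)
  cells <- do.call(expand.grid, c(levs, stringsAsFactors = FALSE))
  counts <- table(data[c(subject, factors)])
  if (any(counts != 1L))
    stop("design must be complete and balanced: exactly one observation ",
         "per subject and cell (no imputation)", call. = FALSE)

  fml <- stats::as.formula(sprintf(
    "%s ~ %s + Error(%s/(%s))", dv, paste(factors, collapse = "*"),
    subject, paste(factors, collapse = "*")))
  fit <- aov(fml, data = data)
  sm <- summary(fit)

  ## per-subject cell means in a fixed cell order
  wide <- tapply(data[[dv]],
                 c(data[subject], lapply(data[factors], identity)), mean)
  n <- dim(wide)[1L]
  subjCells <- matrix(wide, n, prod(vapply(levs, length, integer(1L))))

  effects <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, paste, collapse = ":", simplify = FALSE)))
  out <- lapply(effects, function(eff) {
    fs <- strsplit(eff, ":", fixed = TRUE)[[1L]]
    ## locate the aov stratum for this effect
    stratum <- sm[[paste0("Error: ", subject, ":",
                          paste(fs, collapse = ":"))]]
    if (is.null(stratum) && length(fs) == length(factors) &&
        !is.null(sm[["Error: Within"]]))
      stratum <- sm[["Error: Within"]]
    tab <- stratum[[1L]]
    rn <- trimws(rownames(tab))
    row <- which(rn == eff)
    ss <- tab[row, "Sum Sq"]
    ssErr <- tab[rn == "Residuals", "Sum Sq"]
    df1 <- tab[row, "Df"]
    df2 <- tab[rn == "Residuals", "Df"]
    Fv <- tab[row, "F value"]
    p <- tab[row, "Pr(>F)"]
    ## epsilon from contrast scores: average over uninvolved factors,
    ## then apply the Kronecker contrast of the involved ones
    Cmats <- lapply(factors, function(f)
      if (f %in% fs) orthoContrasts(length(levs[[f]]))
      else matrix(1 / length(levs[[f]]), 1L, length(levs[[f]])))
    Ck <- Reduce(kronecker, rev(Cmats))
    scores <- subjCells %*% t(Ck)
    eps <- ggEpsilon(scores)
    pgg <- pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    data.frame(effect = eff, ss = ss, ss_error = ssErr, df1 = df1,
               df2 = df2, F = Fv, p = p, epsilon = eps, p_gg = pgg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average values across hemispheres, gated by a hemisphere ANOVA
#'
#' Runs the repeated-measures ANOVA including the hemisphere factor first,
#' records whether any hemisphere effect or interaction is significant, and
#' averages across hemispheres regardless -- mirroring the reasoning of
#' averaging only after confirming no major hemisphere differences (the
#' gate outcome is reported, not enforced).
#'
#' @param data long-format data.frame with a hemisphere column.
#' @param dv value column name.
#' @param subject subject column name.
#' @param hemisphere hemisphere column name.
#' @param factors additional within-subject factor names (may be empty).
#' @param alpha significance level for the gate report.
#' @return list with `values` (data averaged across hemispheres), `gate`
#'   (the hemisphere ANOVA rows, or NULL), and `note`.
#' @export
hemisphereAverage <- function(data, dv, subject, hemisphere = "hemisphere",
                              factors = character(), alpha = 0.05) {
  hemis <- unique(data[[hemisphere]])
  if (length(hemis) == 1L) {
    return(list(values = data[setdiff(names(data), hemisphere)],
                gate = NULL, note = "single hemisphere: passthrough"))
  }
  hrows <- tryCatch({
    an <- rmAnovaGG(data, dv, subject, c(hemisphere, factors))
    an[grepl(hemisphere, an$effect), , drop = FALSE]
  }, error = function(e) NULL)
  flagged <- isTRUE(any(hrows$p_gg < alpha, na.rm = TRUE))
  aggFactors <- c(subject, factors)
  agg <- stats::aggregate(data[[dv]], by = data[aggFactors], FUN = mean)
  names(agg) <- c(aggFactors, dv)
  list(values = agg, gate = hrows,
       note = if (is.null(hrows)) "hemisphere gate unavailable; averaged"
              else if (flagged)
                "hemisphere effect flagged; averaged regardless"
              else "no hemisphere effect; averaged")
}
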