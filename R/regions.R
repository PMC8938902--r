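## Selectivity-based ROI definition and band-wise strip profiling.

#' Anatomical sub-region masks along the axis
#'
#' Splits the sheet into medial (leg), central (hand) and lateral (face)
#' axis intervals: the central interval spans the hand zone (centre +/- 2
#' tuning widths) and a gap is left above and below it before the medial and
#' lateral intervals begin -- the axis-interval analogue of the anatomical
#' sub-regions with a 1 cm exclusion gap used to keep the masks disjoint.
#'
#' @param sheet a [CorticalSheet-class] whose zones include feet, hand, lips.
#' @param gapMM gap (mm) between the central interval and its neighbours.
#' @return named list (`medial`, `central`, `lateral`) of voxel index
#'   vectors; attribute `"intervalsMM"` holds the axis intervals.
#' @export
anatomicalMasks <- function(sheet, gapMM = 10) {
  centers <- sheet@config@zoneCenters
  if (!all(c("feet", "hand", "lips") %in% names(centers)))
    stop("sheet must define feet, hand and lips zones", call. = FALSE)
  x <- sheet@coordsMM
  halfw <- 2 * sheet@config@tuningWidthMM
  hand <- c(centers[["hand"]] - halfw, centers[["hand"]] + halfw)
  iv <- list(medial = c(0, hand[1L] - gapMM), central = hand,
             lateral = c(hand[2L] + gapMM, sheet@config@axisLengthMM))
  if (iv$medial[2L] <= 0 || iv$lateral[1L] >= iv$lateral[2L])
    stop("gap leaves an empty anatomical mask", call. = FALSE)
  masks <- lapply(iv, function(b) which(x >= b[1L] & x < b[2L]))
  attr(masks, "intervalsMM") <- iv
  masks
}

#' Select the k most activated voxels of a mask
#'
#' The k mask voxels with highest z; ties are broken toward the lower voxel
#' index, so the selection is deterministic. Indices are returned sorted.
#'
#' @param statMap a [StatMap-class] (or a bare numeric z vector).
#' @param mask integer voxel indices to select within.
#' @param k number of voxels to keep.
#' @return sorted integer vector of k voxel indices.
#' @export
selectTopVoxels <- function(statMap, mask, k) {
  z <- if (is(statMap, "StatMap")) statMap@z else statMap
  if (length(mask) < k)
    stop(sprintf("mask has %d voxels but k = %d requested", length(mask), k),
         call. = FALSE)
  mask <- sort(mask)
  ord <- order(-z[mask], mask)   # ties -> lower index
  sort(mask[ord[seq_len(k)]])
}

#' Define selectivity-based ROIs from localizer contrasts
#'
#' Winner-takes-all ROI definition: the leg ROI is the top-k voxels of the
#' feet-vs-others localizer contrast within the medial mask, the hand ROI
#' the top-k of the hand contrast within the central mask, and the face ROI
#' the top-k of the lips contrast within the lateral mask.
#'
#' @param localizerStatMaps named list of [StatMap-class] with elements
#'   `feet`, `hand`, `lips` (each a vs-all-others contrast).
#' @param masks named list as returned by [anatomicalMasks()].
#' @param k ROI size in voxels (default 50).
#' @return an [ROISet-class] with ROIs `leg`, `hand`, `face`.
#' @export
defineROIs <- function(localizerStatMaps, masks, k = 50L) {
  wiring <- list(leg = c("feet", "medial"), hand = c("hand", "central"),
                 face = c("lips", "lateral"))
  rois <- lapply(wiring, function(w)
    selectTopVoxels(localizerStatMaps[[w[1L]]], masks[[w[2L]]], k))
  rs <- new("ROISet", rois = rois, k = as.integer(k),
            sourceContrast = setNames(
              vapply(wiring, `[`, character(1L), 1L), names(wiring)))
  validObject(rs)
  rs
}

#' Partition a strip interval into equal-height bands
#'
#' Half-open intervals [e_i, e_{i+1}) of equal height partitioning the
#' strip; the last band is closed so the union covers the strip exactly.
#'
#' @param stripIntervalMM length-2 numeric, strip start and end (mm).
#' @param coords per-voxel axis coordinates (mm).
#' @param nBands number of bands (>= 2).
#' @return a [BandPartition-class] (no exclusions yet).
#' @export
makeBands <- function(stripIntervalMM, coords, nBands = 30L) {
  if (nBands < 2L) stop("nBands must be >= 2", call. = FALSE)
  if (diff(stripIntervalMM) <= 0) stop("empty strip", call. = FALSE)
  edges <- seq(stripIntervalMM[1L], stripIntervalMM[2L],
               length.out = nBands + 1L)
  bands <- lapply(seq_len(nBands), function(i) {
    if (i < nBands) which(coords >= edges[i] & coords < edges[i + 1L])
    else which(coords >= edges[i] & coords <= edges[i + 1L])
  })
  bp <- new("BandPartition", nBands = as.integer(nBands), edgesMM = edges,
            bands = bands, excluded = integer(),
            exclusionReason = character())
  validObject(bp)
  bp
}

#' Univariate and multivariate profiles along the strip
#'
#' For every band with at least `minVoxels` voxels: the mean univariate z
#' per condition and the crossnobis RDM, computed exactly as for the ROIs
#' (band-wise shrinkage noise covariance, prewhitening, cross-validated
#' distances). Bands below the voxel threshold are excluded and recorded
#' with a reason.
#'
#' @param ps full-sheet unwhitened [PatternSet-class].
#' @param statMaps named list of [StatMap-class], one per condition.
#' @param partition a [BandPartition-class].
#' @param minVoxels minimum voxels for a band to be retained (default 5).
#' @param lambda shrinkage mode passed to [noiseCovariance()].
#' @return a [BandProfile-class].
#' @export
bandProfiles <- function(ps, statMaps, partition, minVoxels = 5L,
                         lambda = "auto") {
  counts <- lengths(partition@bands)
  keep <- which(counts >= minVoxels)
  if (length(keep) == 0L)
    stop("all bands excluded: no band has >= ", minVoxels, " voxels",
         call. = FALSE)
  drop <- setdiff(seq_len(partition@nBands), keep)
  conds <- names(statMaps)
  meanZ <- matrix(NA_real_, length(keep), length(conds),
                  dimnames = list(keep, conds))
  rdms <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    vox <- partition@bands[[keep[ii]]]
    meanZ[ii, ] <- vapply(statMaps, function(sm) mean(sm@z[vox]), numeric(1L))
    sub <- subsetVoxels(ps, vox)
    nc <- noiseCovariance(sub@residuals, sub@runDofs, lambda)
    rdms[[ii]] <- crossnobisRDM(prewhiten(sub, nc),
                                meta = list(band = keep[ii]))
  }
  new("BandProfile", bandIds = as.integer(keep), meanZ = meanZ, rdms = rdms,
      voxelCounts = as.integer(counts[keep]), excluded = as.integer(drop),
      exclusionReason = rep(sprintf("fewer than %d voxels", minVoxels),
                            length(drop)))
}

#' Locate peak bands of a group-mean profile curve
#'
#' Returns the global maximum within the restricted interval plus every
#' local maximum (strictly greater than both retained neighbours) reaching
#' at least `relThreshold` times the global maximum -- the rule that
#' captures multi-peaked profiles such as a double hand peak.
#'
#' @param curve named numeric vector over retained bands (names = band ids).
#' @param restrict optional integer band ids delimiting the search.
#' @param relThreshold relative height for secondary peaks (default 0.9).
#' @return integer band ids of the peaks, global peak first.
#' @export
findPeakBands <- function(curve, restrict = NULL, relThreshold = 0.9) {
  ids <- if (is.null(names(curve))) seq_along(curve)
         else as.integer(names(curve))
  if (!is.null(restrict)) {
    sel <- ids %in% restrict
    if (!any(sel)) stop("empty restriction interval", call. = FALSE)
    curve <- curve[sel]
    ids <- ids[sel]
  }
  gmax <- which.max(curve)
  peaks <- gmax
  n <- length(curve)
  if (n >= 3L) {
    for (i in 2L:(n - 1L)) {
      if (i != gmax && curve[i] > curve[i - 1L] && curve[i] > curve[i + 1L] &&
          curve[i] >= relThreshold * curve[gmax])
        peaks <- c(peaks, i)
    }
  }
  ids[peaks]
}
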