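#' Compose per-station cDWI volumes into a whole-body stack
#'
#' Stacks station volumes superior to inferior on a regular slice grid.
#' Slices acquired at the same position by two stations resolve to the
#' more superior station. Returns the composed volume together with the
#' boundary indices (first composed slice of each non-reference station)
#' and the station index of every composed slice.
#'
#' @param study the source [DWIStudy] (for geometry).
#' @param cdwiList list of per-station 3-D cDWI arrays.
#' @return list with `volume`, `positions`, `boundaries`, `stationIndex`.
#' @export
composeStations <- function(study, cdwiList) {
  stopifnot(is(study, "DWIStudy"), length(cdwiList) == length(study@stations))
  grid <- composedGrid(study)
  posList <- lapply(study@stations, slot, "slicePositions")
  vol <- assembleOnGrid(cdwiList, posList, grid)
  tol <- grid$thickness / 100
  stationIndex <- rep(NA_integer_, length(grid$positions))
  for (i in seq_along(posList))
    for (z in seq_along(posList[[i]])) {
      j <- which(abs(grid$positions - posList[[i]][z]) < tol)
      if (length(j) == 1L && is.na(stationIndex[j])) stationIndex[j] <- i
    }
  # grid slices with no acquired position inherit the station above
  for (j in seq_along(stationIndex))
    if (is.na(stationIndex[j]))
      stationIndex[j] <- if (j > 1) stationIndex[j - 1] else 1L
  boundaries <- which(diff(stationIndex) > 0) + 1L
  list(volume = vol, positions = grid$positions,
       boundaries = as.integer(boundaries),
       stationIndex = stationIndex, thickness = grid$thickness)
}

#' Inter-station scale factor from CDF matching
#'
#' Finds the linear scale s that best matches the signal distribution of
#' the slices just inferior to a station boundary to the distribution
#' just superior to it: s minimises the summed squared difference
#' between the empirical cumulative frequency curves of the two sides,
#' with the lower side's intensities multiplied by s, evaluated on a
#' common grid of `nLevels` intensity levels spanning the pooled range
#' of the two curves being compared. The grid is fine (16384 levels) so
#' that large spikes of near-constant background signal localise the
#' factor sharply; a coarse log-spaced scan over s in [0.1, 10] brackets
#' the global minimum before a bounded refinement to tolerance 1e-4.
#' Background (zero or negative) voxels are excluded so padding does not
#' bias the factor.
#'
#' @param upperSlices,lowerSlices intensity arrays from the adjacent
#'   slices on either side of the boundary.
#' @param nLevels number of intensity levels of the common CDF grid.
#' @return scalar scale factor; 1 with a warning if either side has no
#'   positive voxels.
#' @export
stationScaleFactor <- function(upperSlices, lowerSlices, nLevels = 16384) {
  u <- upperSlices[upperSlices > 0]
  l <- lowerSlices[lowerSlices > 0]
  if (length(u) == 0 || length(l) == 0) {
    warning("one boundary side has no positive voxels: factor 1")
    return(1)
  }
  Fu <- ecdf(u); Fl <- ecdf(l)
  obj <- function(s) {
    grid <- seq(min(u, l * s), max(u, l * s), length.out = nLevels)
    sum((Fu(grid) - Fl(grid / s))^2)
  }
  sGrid <- exp(seq(log(0.1), log(10), length.out = 200))
  k <- which.min(vapply(sGrid, obj, numeric(1)))
  optimize(obj, c(sGrid[max(1, k - 1)], sGrid[min(length(sGrid), k + 1)]),
           tol = 1e-4)$minimum
}

#' Harmonise signal across station boundaries
#'
#' Walks the composed volume superior to inferior; at each boundary the
#' scale factor matching the lower station to the (already harmonised)
#' upper side is estimated with [stationScaleFactor()] and applied to
#' the lower station, so factors accumulate downward. The most superior
#' station is the reference (factor exactly 1). Within a station only a
#' single multiplicative factor is applied, so intra-station contrast is
#' untouched.
#'
#' @param composed result of [composeStations()].
#' @param nAdjacent slices used on each side of a boundary.
#' @return list with `volume` (harmonised) and `stationFactors`
#'   (cumulative per-station factors, reference first).
#' @export
harmoniseStations <- function(composed, nAdjacent = 3) {
  vol <- composed$volume
  sIdx <- composed$stationIndex
  nStations <- max(sIdx)
  factors <- rep(1, nStations)
  for (k in seq_len(nStations)[-1]) {
    upper <- which(sIdx == k - 1)
    lower <- which(sIdx == k)
    up <- vol[tail(upper, min(nAdjacent, length(upper))), , , drop = FALSE]
    lo <- vol[head(lower, min(nAdjacent, length(lower))), , , drop = FALSE]
    s <- stationScaleFactor(up, lo)
    # the upper side is already harmonised, so s is the cumulative factor
    # of station k relative to its raw signal
    vol[lower, , ] <- vol[lower, , , drop = FALSE] * s
    factors[k] <- s
  }
  list(volume = vol, stationFactors = factors)
}

#' Standardise a harmonised volume to the in-canal 90th percentile
#'
#' Divides the whole volume by the 90th percentile (linear-interpolation
#' definition) of its values inside the spinal-canal mask, so that the
#' canal's bright signal maps to 1 and a fixed display window becomes
#' meaningful across scans.
#'
#' @param composed result of [composeStations()] (raw composed cDWI).
#' @param harmonised result of [harmoniseStations()].
#' @param canalMask binary mask on the composed grid (non-empty).
#' @param percentile percentile of in-canal signal used as reference.
#' @param inPlane in-plane voxel spacing (row, col) in mm, recorded in
#'   the result's geometry.
#' @return a [NormalisedStudy].
#' @export
normaliseToCanal <- function(composed, harmonised, canalMask,
                             percentile = 90,
                             inPlane = c(NA_real_, NA_real_)) {
  stopifnot(identical(dim(harmonised$volume), dim(canalMask)),
            percentile > 0, percentile < 100)
  inCanal <- harmonised$volume[canalMask > 0]
  if (length(inCanal) == 0) stop("empty canal mask: normalisation impossible")
  ref <- as.numeric(quantile(inCanal, percentile / 100, type = 7))
  if (ref <= 0) stop("canal reference percentile is not positive")
  new("NormalisedStudy",
      composedCdwi = composed$volume,
      harmonised = harmonised$volume,
      normalised = harmonised$volume / ref,
      stationScaleFactors = harmonised$stationFactors,
      canalReference = ref,
      boundaries = composed$boundaries,
      slicePositions = composed$positions,
      spacing = c(composed$thickness, inPlane))
}

#' Maximum-intensity projection
#'
#' Projects a composed axial volume (slice, row, col) along one in-plane
#' axis: `coronal` collapses the row (anterior-posterior) axis,
#' `sagittal` the column (left-right) axis. The result is the 2-D image
#' used for whole-body review.
#'
#' @param volume 3-D array (slice, row, col).
#' @param axis `"coronal"` or `"sagittal"`.
#' @return 2-D array of voxel-wise maxima.
#' @export
mip <- function(volume, axis = c("coronal", "sagittal")) {
  stopifnot(length(dim(volume)) == 3L)
  axis <- match.arg(axis)
  apply(volume, if (axis == "coronal") c(1, 3) else c(1, 2), max)
}
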