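#' @import methods
#' @importFrom stats dnorm ecdf kmeans optimize quantile rnorm runif sd var
#' @importFrom utils write.csv head tail
#' @useDynLib wbdwiNorm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' StationVolume: one anatomical acquisition station
#'
#' Holds the acquired diffusion-weighted signal of a single station as a
#' 4-D array indexed (b-index, slice, row, col), together with its
#' b-values (s/mm^2), voxel spacing and slice positions along the patient
#' axis (mm, increasing superior to inferior).
#'
#' @slot signal 4-D numeric array, arbitrary units >= 0.
#' @slot bValues numeric vector of diffusion weightings in s/mm^2.
#' @slot spacing numeric length 3: slice thickness, row and column size (mm).
#' @slot slicePositions numeric, strictly monotonic slice centres (mm).
#' @export
setClass("StationVolume",
  representation(signal = "array", bValues = "numeric",
                 spacing = "numeric", slicePositions = "numeric"))

setValidity("StationVolume", function(object) {
  d <- dim(object@signal)
  msg <- character()
  if (length(d) != 4L)
    msg <- c(msg, "signal must be a 4-D array (b, slice, row, col)")
  else {
    if (d[1] != length(object@bValues))
      msg <- c(msg, "first dimension of signal must match number of b-values")
    if (d[2] != length(object@slicePositions))
      msg <- c(msg, "second dimension of signal must match slicePositions")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (any(object@signal < 0))
    msg <- c(msg, "signal intensities must be non-negative")
  dp <- diff(object@slicePositions)
  if (length(dp) && !(all(dp > 0) || all(dp < 0)))
    msg <- c(msg, "slicePositions must be strictly monotonic")
  if (length(msg)) msg else TRUE
})

#' @describeIn StationVolume constructor
#' @param signal,bValues,spacing,slicePositions see slots.
#' @export
StationVolume <- function(signal, bValues, spacing, slicePositions) {
  new("StationVolume", signal = signal, bValues = as.numeric(bValues),
      spacing = as.numeric(spacing),
      slicePositions = as.numeric(slicePositions))
}

#' DWIStudy: a whole-body acquisition
#'
#' An ordered collection of [StationVolume] objects covering the body
#' superior to inferior. All stations must share in-plane geometry and
#' list the same b-values in the same order.
#'
#' @slot stations list of StationVolume, superior first.
#' @slot patientId,scanLabel character identifiers.
#' @export
setClass("DWIStudy",
  representation(stations = "list", patientId = "character",
                 scanLabel = "character"))

setValidity("DWIStudy", function(object) {
  st <- object@stations
  msg <- character()
  if (length(st) < 1L || length(st) > 8L)
    msg <- c(msg, "between 1 and 8 stations required")
  if (!all(vapply(st, is, logical(1), "StationVolume")))
    msg <- c(msg, "stations must all be StationVolume objects")
  else {
    if (any(vapply(st, function(s) dim(s@signal)[2] < 2L, logical(1))))
      msg <- c(msg, "each station needs at least 2 slices")
    b1 <- st[[1]]@bValues
    if (!all(vapply(st, function(s) identical(s@bValues, b1), logical(1))))
      msg <- c(msg, "all stations must list the same b-values in the same order")
    g1 <- c(dim(st[[1]]@signal)[3:4], st[[1]]@spacing[2:3])
    same <- vapply(st, function(s)
      all(abs(c(dim(s@signal)[3:4], s@spacing[2:3]) - g1) < 1e-9), logical(1))
    if (!all(same))
      msg <- c(msg, "all stations must share in-plane matrix size and spacing")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DWIStudy constructor
#' @param stations,patientId,scanLabel see slots.
#' @export
DWIStudy <- function(stations, patientId = "anon", scanLabel = "scan1") {
  new("DWIStudy", stations = stations, patientId = patientId,
      scanLabel = scanLabel)
}

#' ParametricMaps: voxel-wise ADC and S0 for one station
#'
#' @slot adc 3-D array (slice, row, col), mm^2/s; negative values are
#'   retained so that fitting noise does not create artificial boundaries.
#' @slot s0 3-D array, arbitrary units, strictly positive (floored).
#' @slot spacing,slicePositions geometry inherited from the source station.
#' @export
setClass("ParametricMaps",
  representation(adc = "array", s0 = "array", spacing = "numeric",
                 slicePositions = "numeric"))

setValidity("ParametricMaps", function(object) {
  msg <- character()
  if (!identical(dim(object@adc), dim(object@s0)))
    msg <- c(msg, "adc and s0 must have identical shape")
  if (any(object@s0 <= 0))
    msg <- c(msg, "s0 must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' NetworkInput: scaled two-channel slices for the segmentation network
#'
#' Channel 1 is ADC / 3.5e-3 mm^2/s (dimensionless, negatives preserved);
#' channel 2 is log(S0) divided by the study-wide maximum of log(S0), in
#' [0, 1]. Both are resampled in-plane to a square matrix at a fixed
#' resolution (1.6 mm by default).
#'
#' @slot scaledAdc,scaledS0 3-D arrays (slice, row, col).
#' @slot spacing target voxel spacing (mm).
#' @export
setClass("NetworkInput",
  representation(scaledAdc = "array", scaledS0 = "array",
                 spacing = "numeric"))

#' CanalSegmentation: spinal-canal probability and binary mask
#'
#' @slot probability 3-D array in [0, 1] on the composed whole-body grid.
#' @slot mask 3-D binary array, probability >= threshold.
#' @slot threshold scalar decision threshold.
#' @slot slicePositions,spacing composed-grid geometry.
#' @export
setClass("CanalSegmentation",
  representation(probability = "array", mask = "array",
                 threshold = "numeric", slicePositions = "numeric",
                 spacing = "numeric"))

setValidity("CanalSegmentation", function(object) {
  msg <- character()
  if (!identical(dim(object@probability), dim(object@mask)))
    msg <- c(msg, "probability and mask must share shape")
  if (any(object@probability < 0 | object@probability > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must be binary")
  if (length(msg)) msg else TRUE
})

#' GMMResult: two-component Gaussian mixture of in-canal ADC
#'
#' Component 1 is the spinal cord (lower mean), component 2 the CSF.
#' Means and variances are expressed in units of 1e-3 mm^2/s (and its
#' square), the scale on which the EM is run.
#'
#' @slot weights,means,variances numeric length 2, ordered by mean.
#' @slot logLik final log-likelihood of the fit.
#' @export
setClass("GMMResult",
  representation(weights = "numeric", means = "numeric",
                 variances = "numeric", logLik = "numeric"))

setValidity("GMMResult", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1")
  if (!(object@means[1] < object@means[2]))
    msg <- c(msg, "means must be strictly increasing (cord first)")
  if (any(object@variances <= 0))
    msg <- c(msg, "variances must be positive")
  if (length(msg)) msg else TRUE
})

#' SubSegmentation: cord/CSF partition of the canal
#'
#' @slot cordMask,csfMask binary 3-D arrays; their union is the canal
#'   mask and their intersection empty.
#' @export
setClass("SubSegmentation",
  representation(cordMask = "array", csfMask = "array"))

setValidity("SubSegmentation", function(object) {
  if (any(object@cordMask * object@csfMask != 0))
    "cord and CSF masks must be disjoint" else TRUE
})

#' NormalisedStudy: harmonised and canal-standardised whole-body cDWI
#'
#' @slot composedCdwi raw composed cDWI on the whole-body grid.
#' @slot harmonised cDWI after inter-station scale harmonisation.
#' @slot normalised harmonised volume divided by `canalReference`.
#' @slot stationScaleFactors cumulative per-station factors (reference
#'   station, the most superior, is exactly 1).
#' @slot canalReference the 90th-percentile in-canal value used.
#' @slot boundaries composed-grid indices of the first slice of each
#'   non-reference station.
#' @slot slicePositions,spacing composed-grid geometry.
#' @export
setClass("NormalisedStudy",
  representation(composedCdwi = "array", harmonised = "array",
                 normalised = "array", stationScaleFactors = "numeric",
                 canalReference = "numeric", boundaries = "integer",
                 slicePositions = "numeric", spacing = "numeric"))

setValidity("NormalisedStudy", function(object) {
  msg <- character()
  if (abs(object@stationScaleFactors[1] - 1) > 0)
    msg <- c(msg, "reference station factor must be exactly 1")
  if (any(object@stationScaleFactors <= 0))
    msg <- c(msg, "scale factors must be positive")
  if (length(object@canalReference) != 1L || object@canalReference <= 0)
    msg <- c(msg, "canalReference must be a positive scalar")
  if (length(msg)) msg else TRUE
})
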