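#' @name accessors
#' @title Accessors for wbdwiNorm data classes
#' @param object a wbdwiNorm S4 object.
#' @description Slot access for the package's containers. Use these rather
#'   than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("stations", function(object) standardGeneric("stations"))
#' @rdname accessors
#' @export
setMethod("stations", "DWIStudy", function(object) object@stations)

#' @rdname accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setMethod("bValues", "StationVolume", function(object) object@bValues)
#' @rdname accessors
#' @export
setMethod("bValues", "DWIStudy",
          function(object) object@stations[[1]]@bValues)

#' @rdname accessors
#' @export
setGeneric("adcMap", function(object) standardGeneric("adcMap"))
#' @rdname accessors
#' @export
setMethod("adcMap", "ParametricMaps", function(object) object@adc)

#' @rdname accessors
#' @export
setGeneric("s0Map", function(object) standardGeneric("s0Map"))
#' @rdname accessors
#' @export
setMethod("s0Map", "ParametricMaps", function(object) object@s0)

#' @rdname accessors
#' @export
setGeneric("probabilityMap", function(object) standardGeneric("probabilityMap"))
#' @rdname accessors
#' @export
setMethod("probabilityMap", "CanalSegmentation",
          function(object) object@probability)

#' @rdname accessors
#' @export
setGeneric("canalMask", function(object) standardGeneric("canalMask"))
#' @rdname accessors
#' @export
setMethod("canalMask", "CanalSegmentation", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("gmmWeights", function(object) standardGeneric("gmmWeights"))
#' @rdname accessors
#' @export
setMethod("gmmWeights", "GMMResult", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("gmmMeans", function(object) standardGeneric("gmmMeans"))
#' @rdname accessors
#' @export
setMethod("gmmMeans", "GMMResult", function(object) object@means)

#' @rdname accessors
#' @export
setGeneric("gmmVariances", function(object) standardGeneric("gmmVariances"))
#' @rdname accessors
#' @export
setMethod("gmmVariances", "GMMResult", function(object) object@variances)

#' @rdname accessors
#' @export
setGeneric("cordMask", function(object) standardGeneric("cordMask"))
#' @rdname accessors
#' @export
setMethod("cordMask", "SubSegmentation", function(object) object@cordMask)

#' @rdname accessors
#' @export
setGeneric("csfMask", function(object) standardGeneric("csfMask"))
#' @rdname accessors
#' @export
setMethod("csfMask", "SubSegmentation", function(object) object@csfMask)

#' @rdname accessors
#' @export
setGeneric("stationScaleFactors",
           function(object) standardGeneric("stationScaleFactors"))
#' @rdname accessors
#' @export
setMethod("stationScaleFactors", "NormalisedStudy",
          function(object) object@stationScaleFactors)

#' @rdname accessors
#' @export
setGeneric("canalReference", function(object) standardGeneric("canalReference"))
#' @rdname accessors
#' @export
setMethod("canalReference", "NormalisedStudy",
          function(object) object@canalReference)

#' @rdname accessors
#' @export
setGeneric("normalisedVolume",
           function(object) standardGeneric("normalisedVolume"))
#' @rdname accessors
#' @export
setMethod("normalisedVolume", "NormalisedStudy",
          function(object) object@normalised)

setMethod("show", "DWIStudy", function(object) {
  ns <- length(object@stations)
  nz <- sum(vapply(object@stations, function(s) dim(s@signal)[2], integer(1)))
  cat(sprintf("DWIStudy '%s' / '%s': %d station%s, %d slices, b = %s s/mm^2\n",
              object@patientId, object@scanLabel, ns,
              if (ns == 1) "" else "s", nz,
              paste(bValues(object), collapse = "/")))
})

setMethod("show", "StationVolume", function(object) {
  d <- dim(object@signal)
  cat(sprintf("StationVolume: %d b-values, %d slices of %dx%d, spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(object@spacing, 3), collapse = "x")))
})

setMethod("show", "ParametricMaps", function(object) {
  d <- dim(object@adc)
  cat(sprintf("ParametricMaps: %d slices of %dx%d; ADC range [%.2e, %.2e] mm^2/s\n",
              d[1], d[2], d[3], min(object@adc), max(object@adc)))
})

setMethod("show", "CanalSegmentation", function(object) {
  cat(sprintf("CanalSegmentation: %d slices, %d canal voxels (threshold %.2f)\n",
              dim(object@mask)[1], sum(object@mask), object@threshold))
})

setMethod("show", "GMMResult", function(object) {
  cat("2-component ADC mixture (units 1e-3 mm^2/s):\n")
  cat(sprintf("  cord: weight %.3f, mean %.3f, variance %.3f\n",
              object@weights[1], object@means[1], object@variances[1]))
  cat(sprintf("  CSF : weight %.3f, mean %.3f, variance %.3f\n",
              object@weights[2], object@means[2], object@variances[2]))
})

setMethod("show", "NormalisedStudy", function(object) {
  cat(sprintf(
    "NormalisedStudy: %d slices; station factors %s; canal reference %.4g\n",
    dim(object@normalised)[1],
    paste(signif(object@stationScaleFactors, 4), collapse = ", "),
    object@canalReference))
})
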