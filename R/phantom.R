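#' Specification of a synthetic multi-station WBDWI phantom
#'
#' The phantom emulates a whole-body diffusion acquisition: 4 stations of
#' 40 axial slices (reducible for fast tests), a spinal canal modelled as
#' a tube at a fixed in-plane position through all slices with an inner
#' cord core and an outer CSF ring, per-station multiplicative gain
#' offsets, optional low-ADC hyperintense lesions, and Rician noise.
#'
#' Tissue defaults follow the values observed in patient cohorts: cord
#' ADC ~ N(1.7, 0.35) and CSF ADC ~ N(3.2, 0.60) in 1e-3 mm^2/s units
#' (variance in the squared unit), with the cord occupying ~60% of the
#' canal cross-section (canal radius 8 mm, giving an area near 200 mm^2).
#' ADC values are drawn i.i.d. per voxel, which is sufficient for
#' mixture-model and normalisation testing but carries no spatial
#' texture. S0 levels make CSF the brightest structure, as at low
#' b-value.
#'
#' @param nStations number of stations (1-8).
#' @param slicesPerStation axial slices per station.
#' @param matrixSize square in-plane matrix (64 for CPU-scale tests, up
#'   to 256).
#' @param inPlaneMm,thicknessMm voxel spacing (mm).
#' @param bValues acquisition b-values (s/mm^2).
#' @param stationGains per-station multiplicative gains (recycled or
#'   truncated to `nStations`).
#' @param cordAdcMean,cordAdcVar,csfAdcMean,csfAdcVar mixture parameters
#'   in 1e-3 mm^2/s (variance in its square).
#' @param cordWeight cord fraction of the canal; sets the default cord
#'   radius `canalRadiusMm * sqrt(cordWeight)`.
#' @param canalRadiusMm,cordRadiusMm canal/cord tube radii (mm).
#' @param backgroundAdc background ADC (1e-3 mm^2/s).
#' @param s0Levels named S0 levels (a.u.) for background, cord, csf,
#'   lesion.
#' @param nLesions,lesionRadiusMm,lesionAdc low-ADC lesion count,
#'   radius, and ADC (1e-3 mm^2/s); lesions are placed outside the canal.
#' @param noiseSigma Rician noise level in a.u. (0 = noiseless).
#' @param centerJitterMm uniform jitter of the canal centre per phantom.
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(nStations = 4, slicesPerStation = 40,
                        matrixSize = 64, inPlaneMm = 1.6, thicknessMm = 5,
                        bValues = c(50, 600, 900),
                        stationGains = c(1, 1.3, 0.8, 1.1),
                        cordAdcMean = 1.7, cordAdcVar = 0.35,
                        csfAdcMean = 3.2, csfAdcVar = 0.60,
                        cordWeight = 0.6, canalRadiusMm = 8,
                        cordRadiusMm = canalRadiusMm * sqrt(cordWeight),
                        backgroundAdc = 1.0,
                        s0Levels = c(background = 100, cord = 400,
                                     csf = 800, lesion = 600),
                        nLesions = 2, lesionRadiusMm = 6, lesionAdc = 0.7,
                        noiseSigma = 10, centerJitterMm = 8, seed = 1) {
  stopifnot(nStations >= 1, nStations <= 8, slicesPerStation >= 2,
            cordRadiusMm < canalRadiusMm, length(bValues) >= 2,
            noiseSigma >= 0, canalRadiusMm > 0)
  gains <- rep_len(stationGains, nStations)
  stopifnot(all(gains > 0))
  if (canalRadiusMm + centerJitterMm >= matrixSize * inPlaneMm / 2)
    stop("canal does not fit inside the field of view")
  structure(list(nStations = nStations, slicesPerStation = slicesPerStation,
                 matrixSize = matrixSize, inPlaneMm = inPlaneMm,
                 thicknessMm = thicknessMm, bValues = bValues,
                 stationGains = gains, cordAdcMean = cordAdcMean,
                 cordAdcVar = cordAdcVar, csfAdcMean = csfAdcMean,
                 csfAdcVar = csfAdcVar, cordWeight = cordWeight,
                 canalRadiusMm = canalRadiusMm, cordRadiusMm = cordRadiusMm,
                 backgroundAdc = backgroundAdc, s0Levels = s0Levels,
                 nLesions = nLesions, lesionRadiusMm = lesionRadiusMm,
                 lesionAdc = lesionAdc, noiseSigma = noiseSigma,
                 centerJitterMm = centerJitterMm, seed = seed),
            class = "PhantomSpec")
}

#' Generate a synthetic WBDWI study with ground truth
#'
#' Builds the true ADC (mm^2/s) and S0 maps voxel-by-voxel from the
#' phantom geometry, synthesises the signal at every acquired b-value
#' via the monoexponential decay, applies the per-station gain, and
#' corrupts the result with Rician noise (magnitude of a complex
#' Gaussian perturbation) when `noiseSigma > 0`.
#'
#' @param spec a [phantomSpec()].
#' @return list with `study` (a [DWIStudy]), `truth` (binary canal,
#'   cord, csf, lesion masks on the whole-body grid), `adcTrue` and
#'   `s0True` maps (whole-body grid, ADC in mm^2/s), `gains`, and
#'   `positions`.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  M <- spec$matrixSize
  Z <- spec$nStations * spec$slicesPerStation
  dx <- spec$inPlaneMm
  centre <- (M + 1) / 2 * dx + runif(2, -spec$centerJitterMm,
                                     spec$centerJitterMm)
  coords <- (seq_len(M)) * dx
  dist2 <- outer((coords - centre[1])^2, (coords - centre[2])^2, "+")
  canal2d <- dist2 <= spec$canalRadiusMm^2
  cord2d <- dist2 <= spec$cordRadiusMm^2
  canal <- array(rep(canal2d, each = Z), c(Z, M, M))
  cord <- array(rep(cord2d, each = Z), c(Z, M, M))
  csf <- canal & !cord
  # lesions: spheres fully outside the canal tube
  lesion <- array(FALSE, c(Z, M, M))
  zPos <- (seq_len(Z) - 0.5) * spec$thicknessMm
  for (i in seq_len(spec$nLesions)) {
    repeat {
      cz <- runif(1, min(zPos), max(zPos))
      cxy <- runif(2, spec$lesionRadiusMm, M * dx - spec$lesionRadiusMm)
      if (sqrt(sum((cxy - centre)^2)) >
          spec$canalRadiusMm + spec$lesionRadiusMm) break
    }
    d2xy <- outer((coords - cxy[1])^2, (coords - cxy[2])^2, "+")
    for (z in seq_len(Z)) {
      rz2 <- spec$lesionRadiusMm^2 - (zPos[z] - cz)^2
      if (rz2 > 0) lesion[z, , ] <- lesion[z, , ] | (d2xy <= rz2)
    }
  }
  lesion <- lesion & !canal
  # true parameter maps (ADC drawn i.i.d. per voxel inside the canal)
  adc <- array(spec$backgroundAdc, c(Z, M, M))
  adc[cord] <- rnorm(sum(cord), spec$cordAdcMean, sqrt(spec$cordAdcVar))
  adc[csf] <- rnorm(sum(csf), spec$csfAdcMean, sqrt(spec$csfAdcVar))
  adc[lesion] <- spec$lesionAdc
  s0 <- array(spec$s0Levels[["background"]], c(Z, M, M))
  s0[cord] <- spec$s0Levels[["cord"]]
  s0[csf] <- spec$s0Levels[["csf"]]
  s0[lesion] <- spec$s0Levels[["lesion"]]
  # signal per station per b-value, gain then Rician corruption
  stationsList <- vector("list", spec$nStations)
  for (k in seq_len(spec$nStations)) {
    zIdx <- (k - 1) * spec$slicesPerStation + seq_len(spec$slicesPerStation)
    sig <- array(0, c(length(spec$bValues), length(zIdx), M, M))
    for (bi in seq_along(spec$bValues)) {
      clean <- s0[zIdx, , , drop = FALSE] *
        exp(-spec$bValues[bi] * adc[zIdx, , , drop = FALSE] * 1e-3) *
        spec$stationGains[k]
      if (spec$noiseSigma > 0) {
        n1 <- array(rnorm(length(clean), 0, spec$noiseSigma), dim(clean))
        n2 <- array(rnorm(length(clean), 0, spec$noiseSigma), dim(clean))
        clean <- sqrt((clean + n1)^2 + n2^2)
      }
      sig[bi, , , ] <- clean
    }
    stationsList[[k]] <- StationVolume(
      signal = sig, bValues = spec$bValues,
      spacing = c(spec$thicknessMm, dx, dx),
      slicePositions = zPos[zIdx])
  }
  study <- DWIStudy(stationsList,
                    patientId = sprintf("phantom%03d", spec$seed),
                    scanLabel = "synthetic")
  list(study = study,
       truth = list(canal = canal * 1, cord = cord * 1, csf = csf * 1,
                    lesion = lesion * 1),
       adcTrue = adc * 1e-3, s0True = s0,
       gains = spec$stationGains, positions = zPos)
}

#' Sample ADC values from the phantom's canal mixture
#'
#' Draws from the two-component Gaussian mixture that the phantom uses
#' inside the spinal canal (cord component with probability
#' `cordWeight`, CSF otherwise). Useful for mixture-recovery
#' experiments without building image volumes.
#'
#' @param n number of draws.
#' @param spec a [phantomSpec()] supplying the mixture parameters.
#' @param seed RNG seed.
#' @return numeric vector of ADC values in mm^2/s.
#' @export
sampleCanalADC <- function(n, spec = phantomSpec(), seed = 1) {
  set.seed(seed)
  isCord <- runif(n) < spec$cordWeight
  x <- numeric(n)
  x[isCord] <- rnorm(sum(isCord), spec$cordAdcMean, sqrt(spec$cordAdcVar))
  x[!isCord] <- rnorm(sum(!isCord), spec$csfAdcMean, sqrt(spec$csfAdcVar))
  x * 1e-3
}
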