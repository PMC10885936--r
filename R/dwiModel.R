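#' Fit the monoexponential diffusion model per voxel
#'
#' Estimates S0 and the apparent diffusion coefficient (ADC) in every
#' voxel of a station by ordinary least squares on the log-signal,
#' `ln S(b) = ln S0 - b * ADC`. With exactly two b-values this reduces to
#' the closed form `ADC = ln(S(b1)/S(b2)) / (b2 - b1)`. Negative ADC
#' estimates (noise voxels) are retained in the map so that no artificial
#' boundaries are introduced; they are only clamped later, inside cDWI
#' synthesis.
#'
#' Signals at or below zero are floored at `eps` (arbitrary units) before
#' the log, so all-zero voxels come out with ADC 0 and a floored S0.
#'
#' @param station a [StationVolume].
#' @param eps positive floor applied to the signal before taking logs.
#' @return a [ParametricMaps] with `adc` in mm^2/s and strictly positive
#'   `s0`.
#' @export
fitMonoexponential <- function(station, eps = 1e-3) {
  stopifnot(is(station, "StationVolume"))
  b <- station@bValues
  if (length(unique(b)) < 2L)
    stop("at least 2 distinct b-values are required to fit the model")
  sig <- station@signal
  d <- dim(sig)                       # (B, Z, H, W)
  nvox <- prod(d[2:4])
  ls <- log(pmax(matrix(sig, nrow = d[1]), eps))   # B x nvox
  nzero <- sum(colSums(matrix(sig, nrow = d[1]) > 0) == 0)
  if (nzero > 0)
    warning(sprintf("%d all-zero voxels: S0 floored, ADC set to 0", nzero))
  bc <- b - mean(b)
  slope <- colSums(bc * ls) / sum(bc^2)
  intercept <- colMeans(ls) - slope * mean(b)
  adc <- array(-slope, dim = d[2:4])
  s0 <- array(exp(intercept), dim = d[2:4])
  new("ParametricMaps", adc = adc, s0 = s0, spacing = station@spacing,
      slicePositions = station@slicePositions)
}

#' Synthesise computed DWI (cDWI) at an arbitrary b-value
#'
#' Computes `S(b_c) = S0 * exp(-b_c * ADC)` voxel-wise from fitted maps.
#' Negative ADC values are clamped to zero inside this synthesis only,
#' otherwise noise voxels would be amplified above S0; the ADC map itself
#' is left untouched.
#'
#' @param maps a [ParametricMaps].
#' @param bC target b-value in s/mm^2 (>= 0); 900 is the whole-body
#'   high-b-value convention.
#' @return 3-D intensity array, non-negative and voxel-wise <= S0.
#' @export
computeCDWI <- function(maps, bC = 900) {
  stopifnot(is(maps, "ParametricMaps"), length(bC) == 1L, bC >= 0)
  maps@s0 * exp(-bC * pmax(maps@adc, 0))
}

# Bilinear in-plane resampling of one slice from `fromSpacing` (row, col,
# mm) onto an outSize x outSize grid at `toSpacing`, both grids centred on
# the image centre; values outside the source extent are zero.
resampleSlice <- function(mat, fromSpacing, toSpacing, outSize) {
  interpMatrix <- function(nIn, nOut, sIn, sOut) {
    # fractional source index of each target pixel centre
    pos <- (seq_len(nOut) - (nOut + 1) / 2) * sOut / sIn + (nIn + 1) / 2
    A <- matrix(0, nOut, nIn)
    lo <- floor(pos); f <- pos - lo
    for (k in seq_len(nOut)) {
      if (lo[k] >= 1 && lo[k] <= nIn) A[k, lo[k]] <- 1 - f[k]
      if (lo[k] + 1 >= 1 && lo[k] + 1 <= nIn) A[k, lo[k] + 1] <- A[k, lo[k] + 1] + f[k]
    }
    A
  }
  A <- interpMatrix(nrow(mat), outSize, fromSpacing[1], toSpacing)
  B <- interpMatrix(ncol(mat), outSize, fromSpacing[2], toSpacing)
  A %*% mat %*% t(B)
}

#' Scale ADC/S0 maps into the two-channel network input
#'
#' Channel 1 is the ADC map divided by 3.5e-3 mm^2/s (negatives
#' preserved). Channel 2 is `log(S0) / max(log(S0))`, with S0 floored at
#' 1 before the log; the maximum is taken over the whole study (all
#' stations pooled) so both channels stay consistent across stations --
#' pass `logS0Max` from [studyLogS0Max()] when scaling one station of a
#' multi-station study. Both channels are resampled in-plane to
#' `matrixSize` x `matrixSize` at `resolution` mm by bilinear
#' interpolation, centre-cropped/padded with zeros.
#'
#' @param maps a [ParametricMaps].
#' @param logS0Max scaling denominator for channel 2; `NULL` computes it
#'   from `maps` alone.
#' @param matrixSize,resolution target in-plane grid (default 256 at
#'   1.6 mm).
#' @return a [NetworkInput].
#' @export
scaleNetworkInput <- function(maps, logS0Max = NULL, matrixSize = 256,
                              resolution = 1.6) {
  stopifnot(is(maps, "ParametricMaps"))
  if (is.null(logS0Max)) logS0Max <- max(log(pmax(maps@s0, 1)))
  ch1 <- maps@adc / 3.5e-3
  ch2 <- log(pmax(maps@s0, 1))
  if (logS0Max <= 0) {
    warning("max(log(S0)) <= 0: S0 channel set to zero")
    ch2[] <- 0
  } else ch2 <- ch2 / logS0Max
  d <- dim(maps@adc)
  sameGrid <- d[2] == matrixSize && d[3] == matrixSize &&
    all(abs(maps@spacing[2:3] - resolution) < 1e-9)
  if (!sameGrid) {
    out1 <- array(0, c(d[1], matrixSize, matrixSize))
    out2 <- out1
    for (z in seq_len(d[1])) {
      out1[z, , ] <- resampleSlice(ch1[z, , ], maps@spacing[2:3], resolution,
                                   matrixSize)
      out2[z, , ] <- resampleSlice(ch2[z, , ], maps@spacing[2:3], resolution,
                                   matrixSize)
    }
    ch1 <- out1; ch2 <- out2
  }
  new("NetworkInput", scaledAdc = ch1, scaledS0 = ch2,
      spacing = c(maps@spacing[1], resolution, resolution))
}

#' Study-wide maximum of log(S0)
#'
#' The S0 channel of the network input is scaled by the maximum of
#' log(S0) over the whole study, not per slice or per station, so that
#' inter-station contrast is preserved.
#'
#' @param mapsList list of [ParametricMaps], one per station.
#' @return scalar max of `log(pmax(s0, 1))` over all stations.
#' @export
studyLogS0Max <- function(mapsList) {
  max(vapply(mapsList, function(m) max(log(pmax(m@s0, 1))), numeric(1)))
}
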