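# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small noiseless 3-station phantom with the benchmark gains.
noiselessPhantom <- function() {
  if (is.null(.fixtures$noiseless)) {
    .fixtures$noiseless <- generatePhantom(
      phantomSpec(nStations = 3, slicesPerStation = 12,
                  stationGains = c(1, 1.3, 0.8), noiseSigma = 0,
                  nLesions = 0, seed = 7))
  }
  .fixtures$noiseless
}

# A station whose signal follows the monoexponential model exactly.
exactStation <- function(s0 = 500, adc = 1.2e-3, b = c(50, 600, 900),
                         nz = 3, m = 8) {
  sig <- array(0, c(length(b), nz, m, m))
  for (i in seq_along(b)) sig[i, , , ] <- s0 * exp(-b[i] * adc)
  StationVolume(sig, b, c(5, 1.6, 1.6), seq(2.5, by = 5, length.out = nz))
}

# The scaled-down segmentation benchmark is expensive; train it once and
# share the result between the training-quality and determinism checks.
benchmarkFixture <- function() {
  if (is.null(.fixtures$benchmark)) {
    .fixtures$benchmark <- segmentationBenchmark(nPhantoms = 15, epochs = 30,
                                                 seed = 1)
  }
  .fixtures$benchmark
}

# Cheap trained model for structural pipeline tests (not accuracy tests):
# a few phantoms, few epochs; over-segments but yields a non-empty mask.
quickModel <- function() {
  if (is.null(.fixtures$quick)) {
    data <- phantomTrainingData(3, phantomSpec(nStations = 2,
                                               slicesPerStation = 7),
                                seedStart = 900)
    m <- buildUNet(unetConfig(encoderFilters = c(8, 16, 32, 64),
                              bottleneckFilters = 128, inputSize = 64),
                   seed = 3)
    .fixtures$quick <- trainUNet(m, data$x, data$y,
                                 cfg = trainConfig(epochs = 15, seed = 3))
  }
  .fixtures$quick
}

# Model trained on empty masks only: predicts background everywhere.
emptyModel <- function() {
  if (is.null(.fixtures$empty)) {
    data <- phantomTrainingData(1, phantomSpec(nStations = 1,
                                               slicesPerStation = 8),
                                seedStart = 950)
    m <- buildUNet(unetConfig(encoderFilters = c(8, 16, 32, 64),
                              bottleneckFilters = 128, inputSize = 64),
                   seed = 4)
    .fixtures$empty <- trainUNet(m, data$x, data$y * 0,
                                 cfg = trainConfig(epochs = 15, batchSize = 2,
                                                   initialLR = 0.03,
                                                   seed = 4),
                                 loss = lossConfig("combo"))
  }
  .fixtures$empty
}
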