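test_that("flat signal across b-values fits ADC 0 and S0 equal to the signal", {
  st <- exactStation(s0 = 37, adc = 0)
  maps <- fitMonoexponential(st)
  expect_equal(max(abs(adcMap(maps))), 0, tolerance = 1e-12)
  expect_equal(s0Map(maps)[1, 1, 1], 37, tolerance = 1e-9)
})

test_that("noiseless monoexponential signal is recovered to machine precision", {
  st <- exactStation(s0 = 500, adc = 1.2e-3)
  maps <- fitMonoexponential(st)
  expect_equal(adcMap(maps)[2, 3, 4], 1.2e-3, tolerance = 1e-12)
  expect_equal(s0Map(maps)[2, 3, 4], 500, tolerance = 1e-9)
})

test_that("two-point fit matches an independent grid-search oracle", {
  # S(50) = 900, S(900) = 380: minimise the squared log-residual over a
  # dense ADC grid as an independent check of the closed form
  b <- c(50, 900); s <- c(900, 380)
  adcGrid <- seq(-1e-3, 5e-3, by = 1e-8)
  rss <- vapply(adcGrid, function(a) {
    ls0 <- mean(log(s) + b * a)
    sum((log(s) - (ls0 - b * a))^2)
  }, numeric(1))
  adcOracle <- adcGrid[which.min(rss)]
  expect_equal(adcOracle, log(900 / 380) / 850, tolerance = 1e-4)

  sig <- array(0, c(2, 2, 2, 2))
  sig[1, , , ] <- s[1]; sig[2, , , ] <- s[2]
  st <- StationVolume(sig, b, c(5, 1.6, 1.6), c(2.5, 7.5))
  maps <- fitMonoexponential(st)
  expect_equal(adcMap(maps)[1, 1, 1], log(900 / 380) / 850, tolerance = 1e-12)
  expect_equal(s0Map(maps)[1, 1, 1], 900 * exp(50 * log(900 / 380) / 850),
               tolerance = 1e-9)
})

test_that("fitting requires two distinct b-values and flags all-zero voxels", {
  sig <- array(1, c(2, 2, 4, 4))
  st <- StationVolume(sig, c(600, 600), c(5, 1.6, 1.6), c(0, 5))
  expect_error(fitMonoexponential(st), "distinct b-values")

  sig2 <- array(100, c(2, 2, 4, 4))
  sig2[, 1, 1, 1] <- 0
  st2 <- StationVolume(sig2, c(50, 900), c(5, 1.6, 1.6), c(0, 5))
  expect_warning(maps <- fitMonoexponential(st2), "all-zero")
  expect_equal(adcMap(maps)[1, 1, 1], 0)
  expect_gt(s0Map(maps)[1, 1, 1], 0)
})

test_that("cDWI reproduces S0 at b = 0 and the exponential decay elsewhere", {
  st <- exactStation(s0 = 1000, adc = 1.0e-3)
  maps <- fitMonoexponential(st)
  expect_equal(computeCDWI(maps, bC = 0), s0Map(maps), tolerance = 1e-12)
  expect_equal(computeCDWI(maps, bC = 900)[1, 1, 1], 1000 * exp(-0.9),
               tolerance = 1e-9)
})

test_that("negative ADC voxels are clamped inside cDWI synthesis only", {
  maps <- new("ParametricMaps", adc = array(-0.5e-3, c(1, 2, 2)),
              s0 = array(200, c(1, 2, 2)), spacing = c(5, 1.6, 1.6),
              slicePositions = 0)
  # oracle: max(ADC, 0) then S0 * exp(-b * ADC)
  expect_equal(computeCDWI(maps, 900), array(200, c(1, 2, 2)))
  expect_equal(adcMap(maps)[1, 1, 1], -0.5e-3)   # the map keeps the negative
})

test_that("round trip fit -> cDWI reproduces a noiseless phantom signal", {
  ph <- noiselessPhantom()
  st <- stations(ph$study)[[1]]
  maps <- fitMonoexponential(st)
  for (bi in seq_along(bValues(st))) {
    pred <- computeCDWI(maps, bC = bValues(st)[bi])
    obs <- st@signal[bi, , , ]
    expect_lt(max(abs(pred - obs) / pmax(obs, 1e-9)), 1e-6)
  }
})

test_that("cDWI is strictly decreasing in b for positive ADC and scale-equivariant", {
  st <- exactStation(s0 = 800, adc = 2e-3)
  maps <- fitMonoexponential(st)
  vals <- vapply(c(0, 100, 400, 900, 1500),
                 function(b) computeCDWI(maps, b)[1, 1, 1], numeric(1))
  expect_true(all(diff(vals) < 0))

  stK <- st; stK@signal <- st@signal * 3.7
  mapsK <- fitMonoexponential(stK)
  expect_equal(adcMap(mapsK), adcMap(maps), tolerance = 1e-10)
  expect_equal(s0Map(mapsK), s0Map(maps) * 3.7, tolerance = 1e-8)
})

test_that("network input scaling follows the fixed ADC divisor and study S0 max", {
  adc <- array(c(3.5e-3, 0, -0.5e-3, 1e-3), c(1, 2, 2))
  s0 <- array(exp(2), c(1, 2, 2))
  maps <- new("ParametricMaps", adc = adc, s0 = s0,
              spacing = c(5, 1.6, 1.6), slicePositions = 0)
  ni <- scaleNetworkInput(maps, matrixSize = 2)
  expect_equal(ni@scaledAdc[1, 1, 1], 1.0)
  expect_equal(ni@scaledAdc[1, 2, 1], 0)
  expect_equal(ni@scaledAdc[1, 1, 2], -0.5 / 3.5, tolerance = 1e-12)
  # constant S0 > 1 everywhere scales to exactly 1
  expect_true(all(ni@scaledS0 == 1))
})

test_that("all S0 at or below 1 zeroes the S0 channel with a warning", {
  maps <- new("ParametricMaps", adc = array(1e-3, c(1, 2, 2)),
              s0 = array(0.5, c(1, 2, 2)), spacing = c(5, 1.6, 1.6),
              slicePositions = 0)
  expect_warning(ni <- scaleNetworkInput(maps, matrixSize = 2), "S0")
  expect_true(all(ni@scaledS0 == 0))
})

test_that("in-plane resampling preserves a constant image and recentres scale", {
  m <- matrix(5, 10, 10)
  out <- wbdwiNorm:::resampleSlice(m, c(1.6, 1.6), 1.6, 10)
  expect_equal(out, m)
  # upsampling a centred constant patch keeps interior values
  out2 <- wbdwiNorm:::resampleSlice(m, c(3.2, 3.2), 1.6, 20)
  expect_equal(out2[10, 10], 5)
})
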