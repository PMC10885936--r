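twoStationStudy <- function(scaleLower = 1, nz = 4, m = 6) {
  mk <- function(pos, gain) {
    sig <- array(0, c(2, nz, m, m))
    base <- matrix(seq_len(m * m), m, m) * 2
    for (z in seq_len(nz)) {
      sig[1, z, , ] <- base * gain
      sig[2, z, , ] <- base * 0.5 * gain
    }
    StationVolume(sig, c(50, 900), c(5, 1.6, 1.6), pos)
  }
  DWIStudy(list(mk(seq(2.5, by = 5, length.out = nz), 1),
                mk(seq(2.5 + 5 * nz, by = 5, length.out = nz), scaleLower)))
}

test_that("station composition concatenates and marks boundaries", {
  study <- twoStationStudy()
  cdwi <- lapply(stations(study), function(s) s@signal[2, , , ])
  comp <- composeStations(study, cdwi)
  expect_equal(dim(comp$volume)[1], 8)
  expect_equal(comp$boundaries, 5L)
  expect_equal(comp$stationIndex, rep(1:2, each = 4))
  # single station: no boundaries
  one <- DWIStudy(stations(study)[1])
  comp1 <- composeStations(one, cdwi[1])
  expect_length(comp1$boundaries, 0)
})

test_that("overlapping slice positions resolve to the more superior station", {
  study <- twoStationStudy()
  # shift station 2 up so its first slice coincides with station 1's last
  st2 <- stations(study)[[2]]
  st2@slicePositions <- st2@slicePositions - 5
  st2@signal <- st2@signal * 100
  study2 <- DWIStudy(list(stations(study)[[1]], st2))
  cdwi <- lapply(stations(study2), function(s) s@signal[2, , , ])
  comp <- composeStations(study2, cdwi)
  expect_equal(dim(comp$volume)[1], 7)
  # position-matching oracle: the shared position keeps station 1's values
  expect_equal(comp$volume[4, , ], cdwi[[1]][4, , ])
})

test_that("identical distributions give factor 1; known scalings invert", {
  x <- array(runif(3 * 8 * 8, 10, 100), c(3, 8, 8))
  expect_equal(stationScaleFactor(x, x), 1, tolerance = 1e-3)
  # dense grid-search oracle over s in [0.5, 1.5] for the 1.3x case
  lower <- x * 1.3
  sGrid <- seq(0.5, 1.5, by = 1e-4)
  u <- as.vector(x); l <- as.vector(lower)
  oracleObj <- vapply(sGrid, function(s) {
    grid <- seq(min(u, l * s), max(u, l * s), length.out = 1024)
    sum((ecdf(u)(grid) - ecdf(l * s)(grid))^2)
  }, numeric(1))
  oracle <- sGrid[which.min(oracleObj)]
  expect_equal(oracle, 1 / 1.3, tolerance = 5e-3)
  expect_equal(stationScaleFactor(x, lower), 1 / 1.3, tolerance = 5e-3)
  expect_equal(stationScaleFactor(x, x * 0.5), 2.0, tolerance = 5e-3)
  expect_warning(f <- stationScaleFactor(x, x * 0), "positive")
  expect_equal(f, 1)
})

test_that("harmonisation recovers known station gains on a noiseless phantom", {
  ph <- noiselessPhantom()     # gains (1, 1.3, 0.8), no Rician noise
  maps <- lapply(stations(ph$study), fitMonoexponential)
  comp <- composeStations(ph$study, lapply(maps, computeCDWI, bC = 900))
  harm <- harmoniseStations(comp)
  expect_equal(harm$stationFactors[1], 1)
  expect_true(all(abs(harm$stationFactors * ph$gains - 1) < 0.02))
  # per-station medians of the harmonised volume agree with the gain-free
  # ground truth within 2%
  truthCdwi <- ph$s0True * exp(-900 * pmax(ph$adcTrue, 0))
  for (k in 1:3) {
    idx <- which(comp$stationIndex == k)
    expect_equal(median(harm$volume[idx, , ]) /
                   median(truthCdwi[idx, , ]), 1, tolerance = 0.02)
  }
  # idempotence: a second pass moves factors by less than 1e-3
  comp2 <- comp; comp2$volume <- harm$volume
  harm2 <- harmoniseStations(comp2)
  expect_true(all(abs(harm2$stationFactors - 1) < 1e-3))
})

test_that("trivial factors leave the volume unchanged and scalings are exact", {
  study <- twoStationStudy()
  cdwi <- lapply(stations(study), function(s) s@signal[2, , , ])
  comp <- composeStations(study, cdwi)
  harm <- harmoniseStations(comp)   # identical stations: factors ~1
  expect_equal(harm$stationFactors, c(1, 1), tolerance = 2e-3)
  expect_equal(harm$volume[5:8, , ],
               comp$volume[5:8, , ] * harm$stationFactors[2])
})

test_that("normalisation maps the in-canal 90th percentile to exactly 1", {
  ph <- noiselessPhantom()
  maps <- lapply(stations(ph$study), fitMonoexponential)
  comp <- composeStations(ph$study, lapply(maps, computeCDWI, bC = 900))
  harm <- harmoniseStations(comp)
  norm <- normaliseToCanal(comp, harm, ph$truth$canal)
  v <- normalisedVolume(norm)[ph$truth$canal > 0]
  expect_equal(as.numeric(quantile(v, 0.9, type = 7)), 1, tolerance = 1e-6)
  # doubling the input leaves the normalised output unchanged
  comp2 <- comp; comp2$volume <- comp$volume * 2
  harm2 <- harm; harm2$volume <- harm$volume * 2
  norm2 <- normaliseToCanal(comp2, harm2, ph$truth$canal)
  expect_equal(normalisedVolume(norm2), normalisedVolume(norm),
               tolerance = 1e-12)
  expect_error(normaliseToCanal(comp, harm, ph$truth$canal * 0), "empty canal")
})

test_that("the percentile follows the linear-interpolation definition", {
  vol <- array(0, c(1, 10, 10)); vol[1, , ] <- 1:100
  mask <- array(1, c(1, 10, 10))
  comp <- list(volume = vol, positions = 0, boundaries = integer(0),
               thickness = 5)
  harm <- list(volume = vol, stationFactors = 1)
  norm <- normaliseToCanal(comp, harm, mask)
  expect_equal(canalReference(norm), 90.1)   # sorted-values oracle
  expect_equal(max(abs(normalisedVolume(norm) - vol / 90.1)), 0)
  # constant canal: everything maps to 1
  harmC <- list(volume = vol * 0 + 7, stationFactors = 1)
  compC <- comp; compC$volume <- harmC$volume
  normC <- normaliseToCanal(compC, harmC, mask)
  expect_true(all(normalisedVolume(normC) == 1))
})

test_that("station-wise intensity ratios survive the whole pipeline", {
  # all operations are linear within a station, so voxel ratios are fixed
  ph <- noiselessPhantom()
  maps <- lapply(stations(ph$study), fitMonoexponential)
  comp <- composeStations(ph$study, lapply(maps, computeCDWI, bC = 900))
  harm <- harmoniseStations(comp)
  norm <- normaliseToCanal(comp, harm, ph$truth$canal)
  out <- normalisedVolume(norm)
  idx <- which(comp$stationIndex == 2)
  a <- comp$volume[idx[1], 3, 4]; b <- comp$volume[idx[2], 10, 11]
  expect_equal(out[idx[1], 3, 4] / out[idx[2], 10, 11], a / b,
               tolerance = 1e-9)
})

test_that("maximum-intensity projections project voxel-wise maxima", {
  vol <- array(0, c(3, 4, 5))
  vol[2, 3, 4] <- 9
  expect_equal(mip(vol, "coronal"), {
    m <- matrix(0, 3, 5); m[2, 4] <- 9; m
  })
  expect_equal(mip(vol, "sagittal"), {
    m <- matrix(0, 3, 4); m[2, 3] <- 9; m
  })
  expect_true(all(mip(vol * 0, "coronal") == 0))
  # max-distributivity over random small volumes
  set.seed(3)
  for (i in 1:5) {
    a <- array(runif(60), c(3, 4, 5)); b <- array(runif(60), c(3, 4, 5))
    expect_equal(mip(pmax(a, b), "coronal"),
                 pmax(mip(a, "coronal"), mip(b, "coronal")))
  }
})
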