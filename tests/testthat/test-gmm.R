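test_that("well-separated point clusters are recovered exactly", {
  x <- c(rep(1.0e-3, 50), rep(4.0e-3, 50)) + rnorm(100, 0, 1e-6)
  g <- fitCanalGMM(x, seed = 1)
  expect_equal(gmmWeights(g), c(0.5, 0.5), tolerance = 0.01)
  expect_equal(gmmMeans(g), c(1.0, 4.0), tolerance = 0.01)
  expect_lt(gmmVariances(g)[1], 0.01)
})

test_that("insufficient or degenerate input is handled", {
  expect_error(fitCanalGMM(rep(1e-3, 10)), "at least 50")
  expect_error(fitCanalGMM(c(rep(1e-3, 60), NA)), "finite")
  # all values identical: variance floor keeps the fit defined
  expect_warning(g <- fitCanalGMM(rep(2e-3, 100), seed = 1), "degenerate")
  expect_true(all(gmmVariances(g) >= 1e-4 - 1e-12))
})

test_that("mixture parameters are recovered within Monte-Carlo tolerance", {
  # default canal mixture: weights 0.6/0.4, means 1.7/3.2, variances
  # 0.35/0.60 in 1e-3 units
  errM <- matrix(0, 5, 2)
  for (s in 1:5) {
    x <- sampleCanalADC(10000, seed = s)
    g <- fitCanalGMM(x, seed = s)
    errM[s, ] <- abs(gmmMeans(g) - c(1.7, 3.2))
    expect_equal(gmmWeights(g)[1], 0.6, tolerance = 0.05)
  }
  expect_lt(mean(errM), 0.05)
})

test_that("the EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  x <- sampleCanalADC(5000, seed = 3)
  g <- fitCanalGMM(x, seed = 3)
  mc <- mclust::Mclust(x * 1e3, G = 2, modelNames = "V", verbose = FALSE,
                       control = mclust::emControl(tol = 1e-8,
                                                   itmax = 5000))
  ord <- order(mc$parameters$mean)
  expect_equal(gmmMeans(g), as.numeric(mc$parameters$mean[ord]),
               tolerance = 0.02)
  expect_equal(gmmWeights(g), as.numeric(mc$parameters$pro[ord]),
               tolerance = 0.02)
  expect_equal(gmmVariances(g),
               as.numeric(mc$parameters$variance$sigmasq[ord]),
               tolerance = 0.05)
})

test_that("cord/CSF assignment matches a brute-force posterior sweep", {
  x <- sampleCanalADC(5000, seed = 8)
  g <- fitCanalGMM(x, seed = 8)
  # oracle: scan a fine ADC grid for the posterior crossing point
  gridAdc <- seq(0.5, 4.5, by = 1e-4)
  p1 <- gmmWeights(g)[1] * dnorm(gridAdc, gmmMeans(g)[1],
                                 sqrt(gmmVariances(g)[1]))
  p2 <- gmmWeights(g)[2] * dnorm(gridAdc, gmmMeans(g)[2],
                                 sqrt(gmmVariances(g)[2]))
  crossings <- which(diff(sign(p1 - p2)) != 0)
  boundary <- gridAdc[crossings[which.min(abs(gridAdc[crossings] -
                                              mean(gmmMeans(g))))]]
  adcMapArr <- array(c(gmmMeans(g)[1], gmmMeans(g)[2],
                       boundary - 0.01, boundary + 0.01) * 1e-3, c(1, 2, 2))
  sub <- splitCordCSF(array(1, c(1, 2, 2)), adcMapArr, g)
  expect_equal(cordMask(sub)[1, 1, 1], 1)   # voxel at cord mean
  expect_equal(csfMask(sub)[1, 2, 1], 1)    # voxel at CSF mean
  expect_equal(cordMask(sub)[1, 1, 2], 1)   # just below the boundary
  expect_equal(csfMask(sub)[1, 2, 2], 1)    # just above the boundary
})

test_that("the cord/CSF split partitions the canal exactly", {
  ph <- noiselessPhantom()
  canal <- ph$truth$canal
  vals <- ph$adcTrue[canal > 0]
  g <- fitCanalGMM(vals, seed = 2)
  expect_lt(gmmMeans(g)[1], gmmMeans(g)[2])   # cord below CSF on every fit
  sub <- splitCordCSF(canal, ph$adcTrue, g)
  expect_equal(cordMask(sub) + csfMask(sub), canal)
  expect_true(all(cordMask(sub) * csfMask(sub) == 0))
})

test_that("shape statistics follow the voxel arithmetic", {
  mask <- array(0, c(10, 20, 20))
  mask[, 1:10, 1:10] <- 1    # 10 slices x 100 voxels
  st <- shapeStats(mask, c(5, 1.6, 1.6))
  expect_equal(st$volume, 1000 * 12.8 / 1000)
  expect_equal(st$averageCrossSectionArea, 100 * 2.56)
  expect_warning(empty <- shapeStats(array(0, c(2, 2, 2)), c(5, 1.6, 1.6)),
                 "empty")
  expect_equal(empty$volume, 0)
  expect_equal(empty$averageCrossSectionArea, 0)
})

test_that("overlap metrics evaluate the standard confusion formulas", {
  a <- array(0, c(2, 4, 4)); b <- a
  a[1, 1:3, 1:4] <- 1                       # 12 predicted
  b[1, 1:3, 1:4] <- 1
  expect_equal(overlapMetrics(a, b), c(dice = 1, precision = 1, recall = 1))
  # TP = 8, FP = 2, FN = 4
  pred <- array(0, c(1, 1, 14)); truth <- array(0, c(1, 1, 14))
  pred[1, 1, 1:10] <- 1; truth[1, 1, c(1:8, 11:14)] <- 1
  expect_equal(overlapMetrics(pred, truth),
               c(dice = 16 / 22, precision = 8 / 10, recall = 8 / 12))
  d <- array(0, c(1, 2, 2)); d[1, 1, 1] <- 1
  e <- array(0, c(1, 2, 2)); e[1, 2, 2] <- 1
  expect_equal(unname(overlapMetrics(d, e)), c(0, 0, 0))
  expect_message(m <- overlapMetrics(d * 0, e * 0), "empty")
  expect_equal(unname(m), c(1, 1, 1))
})
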