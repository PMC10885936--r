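tinyConfig <- function(size = 16)
  unetConfig(encoderFilters = c(2, 3, 4, 5), bottleneckFilters = 6,
             inputSize = size)

test_that("the network maps 2-channel slices to probabilities of the same size", {
  model <- buildUNet(tinyConfig(), seed = 4)
  x <- array(rnorm(16 * 16 * 2 * 3), c(16, 16, 2, 3))
  fw <- wbdwiNorm:::unetForward(model, x, training = FALSE)
  expect_equal(dim(fw$prob), c(16L, 16L, 1L, 3L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # all-zero input still yields finite probabilities in (0, 1)
  fw0 <- wbdwiNorm:::unetForward(model, x * 0, training = FALSE)
  expect_true(all(is.finite(fw0$prob)))
  expect_true(all(fw0$prob > 0 & fw0$prob < 1))
})

test_that("parameter count is deterministic given the configuration", {
  m1 <- buildUNet(tinyConfig(), seed = 1)
  m2 <- buildUNet(tinyConfig(), seed = 99)
  expect_identical(lapply(m1$params, dim), lapply(m2$params, dim))
  m3 <- buildUNet(tinyConfig(), seed = 1)
  expect_identical(m1$params, m3$params)   # same seed, same weights
  expect_error(unetConfig(inputSize = 50), "divisible")
})

test_that("full backpropagation matches numerical gradients", {
  cfg <- unetConfig(encoderFilters = c(2, 3, 4, 5), bottleneckFilters = 6,
                    inputSize = 16, dropoutRate = 0)
  model <- buildUNet(cfg, seed = 3)
  set.seed(42)
  x <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2))
  loss <- lossConfig("focal_tversky")
  lossOf <- function(m) {
    fw <- wbdwiNorm:::unetForward(m, x, training = TRUE)
    mean(sapply(1:2, function(k)
      wbdwiNorm:::lossWithGrad(y[, , k], fw$prob[, , 1, k], loss)$loss))
  }
  fw <- wbdwiNorm:::unetForward(model, x, training = TRUE)
  dP <- array(0, dim(fw$prob))
  for (k in 1:2)
    dP[, , 1, k] <- wbdwiNorm:::lossWithGrad(y[, , k], fw$prob[, , 1, k],
                                             loss)$grad / 2
  grads <- wbdwiNorm:::unetBackward(model, fw, dP * fw$prob * (1 - fw$prob))
  eps <- 1e-5
  for (nm in c("enc1.conv1.W", "enc3.bn2.gamma", "dec2.up.W", "dec1.conv1.W",
               "final.W")) {
    set.seed(7)
    ii <- sample(length(model$params[[nm]]), min(2, length(model$params[[nm]])))
    for (i in ii) {
      m1 <- model; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
      m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
      num <- (lossOf(m1) - lossOf(m2)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 5e-3)
    }
  }
})

test_that("training drives the loss to ~0 on trivial empty-mask slices", {
  # the Combo loss carries a cross-entropy term whose gradient stays
  # strong on empty masks, so the degenerate task collapses quickly
  model <- buildUNet(tinyConfig(), seed = 2)
  x <- array(rnorm(16 * 16 * 2 * 10, sd = 0.1), c(16, 16, 2, 10))
  y <- array(0, c(16, 16, 10))
  model <- trainUNet(model, x, y,
                     cfg = trainConfig(epochs = 15, batchSize = 2,
                                       initialLR = 0.03, seed = 2),
                     loss = lossConfig("combo"))
  expect_lt(tail(model$history$trainLoss, 1), 0.05)
  expect_error(trainUNet(model, x[, , , 0, drop = FALSE],
                         y[, , 0, drop = FALSE]), "empty")
})

test_that("the plateau schedule halves the rate after patience and floors it", {
  model <- buildUNet(tinyConfig(), seed = 2)
  x <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  y <- array(rbinom(16 * 16 * 4, 1, 0.2), c(16, 16, 4))
  # an infinite improvement threshold makes every epoch count as stagnant,
  # so the schedule is exercised deterministically
  cfg <- trainConfig(epochs = 16, batchSize = 4, lrPatience = 2,
                     improveTol = Inf, initialLR = 1e-3, minLR = 1.25e-4,
                     seed = 9)
  model <- trainUNet(model, x, y, cfg = cfg)
  lr <- model$history$lr
  expect_true(all(diff(lr) <= 0))
  expect_equal(sort(unique(lr), decreasing = TRUE),
               c(1e-3, 5e-4, 2.5e-4, 1.25e-4))
  expect_equal(min(lr), 1.25e-4)   # floored, never below minLR
})

test_that("training with a fixed seed is bit-reproducible", {
  x <- array(rnorm(16 * 16 * 2 * 6), c(16, 16, 2, 6))
  y <- array(rbinom(16 * 16 * 6, 1, 0.2), c(16, 16, 6))
  run <- function() {
    m <- buildUNet(tinyConfig(), seed = 5)
    trainUNet(m, x, y, cfg = trainConfig(epochs = 3, seed = 5))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("probabilities interpolate linearly across slice gaps before thresholding", {
  # two predicted slices with probabilities 0.4 and 0.8 at a voxel and one
  # missing slice midway interpolate to 0.6, which crosses the 0.5 threshold
  stacks <- list(array(0.4, c(1, 2, 2)), array(0.8, c(1, 2, 2)))
  grid <- list(positions = c(0, 5, 10), thickness = 5)
  out <- wbdwiNorm:::assembleOnGrid(stacks, list(0, 10), grid)
  expect_equal(out[2, 1, 1], 0.6)
  expect_true(out[2, 1, 1] >= 0.5)
})

test_that("an untrained model refuses to predict", {
  model <- buildUNet(tinyConfig(64))
  ph <- noiselessPhantom()
  expect_error(predictCanal(model, ph$study), "not been trained")
})
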