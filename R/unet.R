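#' U-Net architecture configuration
#'
#' A symmetric encoder/decoder segmentation network with skip
#' connections. Each level applies two 3x3 convolutions, each followed by
#' batch normalisation and ReLU; encoder levels end in 2x2 max pooling
#' and dropout; decoder levels upsample with a 3x3 stride-2 transposed
#' convolution, concatenate the matching encoder features, and apply
#' dropout before their convolution pair. A 1x1 convolution with sigmoid
#' produces the per-pixel canal probability.
#'
#' The full-scale network uses encoder filters 32/64/128/256 with a
#' bottleneck of 512 on 256x256 inputs; the architecture is
#' size-parametric, and a reduced configuration (8/16/32/64, bottleneck
#' 128, 64x64 inputs) runs comfortably on a CPU.
#'
#' @param encoderFilters four strictly increasing filter counts.
#' @param bottleneckFilters bottleneck width.
#' @param dropoutRate dropout fraction in (0, 1).
#' @param inputSize square input size; must be divisible by 2^4.
#' @param inputChannels input channels (2: scaled ADC + scaled S0).
#' @param resolution in-plane resolution (mm) the network expects.
#' @return a `UNetConfig` list.
#' @export
unetConfig <- function(encoderFilters = c(32, 64, 128, 256),
                       bottleneckFilters = 512, dropoutRate = 0.2,
                       inputSize = 256, inputChannels = 2,
                       resolution = 1.6) {
  stopifnot(length(encoderFilters) == 4L, all(diff(encoderFilters) > 0),
            bottleneckFilters > encoderFilters[4],
            dropoutRate >= 0, dropoutRate < 1)
  if (inputSize %% 16 != 0)
    stop("inputSize must be divisible by 2^4 (four pooling stages)")
  structure(list(encoderFilters = as.integer(encoderFilters),
                 bottleneckFilters = as.integer(bottleneckFilters),
                 dropoutRate = dropoutRate, inputSize = as.integer(inputSize),
                 inputChannels = as.integer(inputChannels),
                 resolution = resolution),
            class = "UNetConfig")
}

#' Training configuration
#'
#' Adam optimisation with a plateau learning-rate schedule: the rate
#' starts at `initialLR` and is halved whenever the monitored loss fails
#' to improve (by more than `improveTol`) for `lrPatience` consecutive
#' epochs, floored at `minLR`.
#'
#' @param epochs training epochs (150 at full scale).
#' @param batchSize slices per batch.
#' @param initialLR,minLR,lrPatience learning-rate schedule parameters.
#' @param improveTol absolute improvement below which an epoch counts as
#'   stagnant.
#' @param seed RNG seed for weight initialisation, shuffling and dropout.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(epochs = 150, batchSize = 8, initialLR = 1e-3,
                        minLR = 1e-5, lrPatience = 10, improveTol = 1e-4,
                        seed = 1) {
  stopifnot(epochs >= 1, batchSize >= 1, initialLR > 0, minLR > 0,
            minLR <= initialLR, lrPatience >= 1)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 initialLR = initialLR, minLR = minLR,
                 lrPatience = as.integer(lrPatience), improveTol = improveTol,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

initConv <- function(k, cin, cout) {
  list(W = matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = rep(0, cout))
}

#' Build an untrained U-Net
#'
#' Initialises all weights (He initialisation, seeded) and batch-norm
#' state for the given configuration. The parameter count is
#' deterministic given the configuration.
#'
#' @param cfg a [unetConfig()].
#' @param seed seed for weight initialisation.
#' @return a `UNet` model object.
#' @export
buildUNet <- function(cfg = unetConfig(), seed = 1) {
  set.seed(seed)
  Fs <- cfg$encoderFilters; B <- cfg$bottleneckFilters
  cin <- c(cfg$inputChannels, Fs[1:3])
  params <- list(); bn <- list()
  addConv <- function(name, k, ci, co) {
    p <- initConv(k, ci, co)
    params[[paste0(name, ".W")]] <<- p$W
    params[[paste0(name, ".b")]] <<- p$b
  }
  addBN <- function(name, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- rep(0, c)
    bn[[name]] <<- list(mean = rep(0, c), var = rep(1, c))
  }
  for (l in 1:4) {
    addConv(sprintf("enc%d.conv1", l), 3, cin[l], Fs[l])
    addBN(sprintf("enc%d.bn1", l), Fs[l])
    addConv(sprintf("enc%d.conv2", l), 3, Fs[l], Fs[l])
    addBN(sprintf("enc%d.bn2", l), Fs[l])
  }
  addConv("bott.conv1", 3, Fs[4], B); addBN("bott.bn1", B)
  addConv("bott.conv2", 3, B, B); addBN("bott.bn2", B)
  up <- c(Fs[2:4], B)                  # channels entering each decoder level
  for (l in 4:1) {
    addConv(sprintf("dec%d.up", l), 3, up[l], Fs[l])
    addConv(sprintf("dec%d.conv1", l), 3, 2 * Fs[l], Fs[l])
    addBN(sprintf("dec%d.bn1", l), Fs[l])
    addConv(sprintf("dec%d.conv2", l), 3, Fs[l], Fs[l])
    addBN(sprintf("dec%d.bn2", l), Fs[l])
  }
  addConv("final", 1, Fs[1], 1)
  structure(list(cfg = cfg, params = params, bn = bn, trained = FALSE,
                 history = NULL, seed = seed),
            class = "UNet")
}

#' @export
print.UNet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("U-Net: filters %s, bottleneck %d, %dx%d input, %s parameters%s\n",
              paste(x$cfg$encoderFilters, collapse = "/"),
              x$cfg$bottleneckFilters, x$cfg$inputSize, x$cfg$inputSize,
              format(np, big.mark = ","),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# ---- layer forward/backward helpers -----------------------------------

bnForward <- function(x, gamma, beta, state, training, momentum = 0.9,
                      eps = 1e-5) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- aperm(x, c(1, 2, 4, 3)); dim(xp) <- c(H * W * N, C)
  if (training) {
    mu <- colMeans(xp)
    v <- colMeans(xp^2) - mu^2
    newState <- list(mean = momentum * state$mean + (1 - momentum) * mu,
                     var = momentum * state$var + (1 - momentum) * v)
  } else {
    mu <- state$mean; v <- state$var; newState <- state
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xp, 2, mu), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- c(H, W, N, C)
  list(y = aperm(y, c(1, 2, 4, 3)), xhat = xhat, invstd = invstd,
       dims = d, state = newState)
}

bnBackward <- function(dy, cache, gamma) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  M <- H * W * N
  dyp <- aperm(dy, c(1, 2, 4, 3)); dim(dyp) <- c(M, C)
  dgamma <- colSums(dyp * cache$xhat)
  dbeta <- colSums(dyp)
  dxhat <- sweep(dyp, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$invstd, "*")
  dim(dx) <- c(H, W, N, C)
  list(dx = aperm(dx, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

# zero-stuff x (H,W,C,N) onto a 2H x 2W grid (stride-2 transposed conv)
zeroStuff <- function(x) {
  d <- dim(x)
  z <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  z[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
  z
}

unStuff <- function(dz) {
  d <- dim(dz)
  dz[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE]
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Full forward pass. Returns probabilities plus (when training) every
# intermediate needed for backprop and the updated batch-norm state.
unetForward <- function(model, x, training = FALSE) {
  p <- model$params; bn <- model$bn; cfg <- model$cfg
  cache <- if (training) new.env(parent = emptyenv()) else NULL
  bnNew <- bn
  rate <- if (training) cfg$dropoutRate else 0
  convBN <- function(name, bnName, xin) {
    z <- .conv_fw(xin, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]], 1L)
    f <- bnForward(z, p[[paste0(bnName, ".gamma")]],
                   p[[paste0(bnName, ".beta")]], bn[[bnName]], training)
    bnNew[[bnName]] <<- f$state
    a <- pmax(f$y, 0)
    if (training) {
      assign(paste0(name, ".x"), xin, envir = cache)
      assign(paste0(bnName, ".cache"),
             list(xhat = f$xhat, invstd = f$invstd, dims = f$dims),
             envir = cache)
      assign(paste0(bnName, ".mask"), f$y > 0, envir = cache)
    }
    a
  }
  dropoutFw <- function(name, xin) {
    if (rate <= 0) return(xin)
    mask <- array((runif(length(xin)) >= rate) / (1 - rate), dim(xin))
    assign(paste0(name, ".mask"), mask, envir = cache)
    xin * mask
  }
  skips <- vector("list", 4)
  cur <- x
  for (l in 1:4) {
    a <- convBN(sprintf("enc%d.conv1", l), sprintf("enc%d.bn1", l), cur)
    a <- convBN(sprintf("enc%d.conv2", l), sprintf("enc%d.bn2", l), a)
    skips[[l]] <- a
    mp <- .maxpool_fw(a)
    if (training) assign(sprintf("pool%d.idx", l), mp$idx, envir = cache)
    cur <- dropoutFw(sprintf("drop.enc%d", l), mp$y)
  }
  cur <- convBN("bott.conv1", "bott.bn1", cur)
  cur <- convBN("bott.conv2", "bott.bn2", cur)
  for (l in 4:1) {
    nm <- sprintf("dec%d.up", l)
    z <- zeroStuff(cur)
    if (training) assign(paste0(nm, ".x"), z, envir = cache)
    upc <- .conv_fw(z, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]], 1L)
    cat_ <- catChannels(upc, skips[[l]])
    cat_ <- dropoutFw(sprintf("drop.dec%d", l), cat_)
    cur <- convBN(sprintf("dec%d.conv1", l), sprintf("dec%d.bn1", l), cat_)
    cur <- convBN(sprintf("dec%d.conv2", l), sprintf("dec%d.bn2", l), cur)
  }
  if (training) assign("final.x", cur, envir = cache)
  logits <- .conv_fw(cur, p[["final.W"]], p[["final.b"]], 0L)
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits, cache = cache, bnNew = bnNew)
}

# Backward pass from d(loss)/d(logits); mirrors unetForward exactly.
unetBackward <- function(model, fw, dlogits) {
  p <- model$params; cfg <- model$cfg; cache <- fw$cache
  grads <- list()
  convBN_bw <- function(name, bnName, dy) {
    mask <- get(paste0(bnName, ".mask"), envir = cache)
    bb <- bnBackward(dy * mask, get(paste0(bnName, ".cache"), envir = cache),
                     p[[paste0(bnName, ".gamma")]])
    grads[[paste0(bnName, ".gamma")]] <<- bb$dgamma
    grads[[paste0(bnName, ".beta")]] <<- bb$dbeta
    cb <- .conv_bw(get(paste0(name, ".x"), envir = cache),
                   p[[paste0(name, ".W")]], bb$dx, 1L)
    grads[[paste0(name, ".W")]] <<- cb$dW
    grads[[paste0(name, ".b")]] <<- cb$db
    cb$dx
  }
  dropoutBw <- function(name, dy) {
    key <- paste0(name, ".mask")
    if (!exists(key, envir = cache)) return(dy)
    dy * get(key, envir = cache)
  }
  cb <- .conv_bw(get("final.x", envir = cache), p[["final.W"]], dlogits, 0L)
  grads[["final.W"]] <- cb$dW; grads[["final.b"]] <- cb$db
  dcur <- cb$dx
  dskip <- vector("list", 4)
  for (l in 1:4) {
    dcur <- convBN_bw(sprintf("dec%d.conv2", l), sprintf("dec%d.bn2", l), dcur)
    dcat <- convBN_bw(sprintf("dec%d.conv1", l), sprintf("dec%d.bn1", l), dcur)
    dcat <- dropoutBw(sprintf("drop.dec%d", l), dcat)
    Fl <- cfg$encoderFilters[l]
    dup <- dcat[, , seq_len(Fl), , drop = FALSE]
    dskip[[l]] <- dcat[, , Fl + seq_len(Fl), , drop = FALSE]
    nm <- sprintf("dec%d.up", l)
    ub <- .conv_bw(get(paste0(nm, ".x"), envir = cache),
                   p[[paste0(nm, ".W")]], dup, 1L)
    grads[[paste0(nm, ".W")]] <- ub$dW; grads[[paste0(nm, ".b")]] <- ub$db
    dcur <- unStuff(ub$dx)
  }
  dcur <- convBN_bw("bott.conv2", "bott.bn2", dcur)
  dcur <- convBN_bw("bott.conv1", "bott.bn1", dcur)
  for (l in 4:1) {
    dcur <- dropoutBw(sprintf("drop.enc%d", l), dcur)
    skipDim <- dim(dskip[[l]])
    dpool <- .maxpool_bw(dcur, get(sprintf("pool%d.idx", l), envir = cache),
                         skipDim[1], skipDim[2])
    dcur <- dpool + dskip[[l]]
    dcur <- convBN_bw(sprintf("enc%d.conv2", l), sprintf("enc%d.bn2", l), dcur)
    dcur <- convBN_bw(sprintf("enc%d.conv1", l), sprintf("enc%d.bn1", l), dcur)
  }
  grads
}

#' Train the U-Net segmenter
#'
#' Minimises the configured loss with Adam over mini-batches of slices.
#' The learning rate is halved after `lrPatience` consecutive epochs
#' without improvement of the monitored loss (validation loss when a
#' validation set is given, else training loss) and floored at `minLR`.
#' All randomness (initial shuffling, dropout) is governed by the
#' training seed, so runs are reproducible on the same machine.
#'
#' @param model a [buildUNet()] model.
#' @param x training slices, array (H, W, channels, N).
#' @param y binary truth masks, array (H, W, N).
#' @param valX,valY optional validation slices/masks.
#' @param cfg a [trainConfig()].
#' @param loss a [lossConfig()].
#' @param verbose print one line per epoch.
#' @return the trained model; `$history` holds per-epoch training loss,
#'   validation loss and learning rate.
#' @export
trainUNet <- function(model, x, y, valX = NULL, valY = NULL,
                      cfg = trainConfig(), loss = lossConfig(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "UNet"))
  N <- dim(x)[4]
  if (N == 0) stop("empty training set")
  stopifnot(identical(dim(y), c(dim(x)[1:2], N)))
  set.seed(cfg$seed)
  adamM <- lapply(model$params, function(p) p * 0)
  adamV <- adamM; adamT <- 0
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8
  lr <- cfg$initialLR
  best <- Inf; stagnant <- 0
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), lr = numeric())
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(N)
    epochLoss <- 0; nb <- 0
    for (start in seq(1, N, by = cfg$batchSize)) {
      idx <- perm[start:min(start + cfg$batchSize - 1, N)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[, , idx, drop = FALSE]
      fw <- unetForward(model, xb, training = TRUE)
      nbatch <- length(idx)
      dP <- array(0, dim(fw$prob))
      bl <- 0
      for (k in seq_len(nbatch)) {
        lw <- lossWithGrad(yb[, , k], fw$prob[, , 1, k], loss)
        bl <- bl + lw$loss / nbatch
        dP[, , 1, k] <- lw$grad / nbatch
      }
      if (!is.finite(bl))
        stop(sprintf("non-finite loss at epoch %d; aborting", epoch))
      dlogits <- dP * fw$prob * (1 - fw$prob)
      grads <- unetBackward(model, fw, dlogits)
      model$bn <- fw$bnNew
      adamT <- adamT + 1
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g
        adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g^2
        mhat <- adamM[[nm]] / (1 - b1^adamT)
        vhat <- adamV[[nm]] / (1 - b2^adamT)
        model$params[[nm]] <- model$params[[nm]] -
          lr * mhat / (sqrt(vhat) + adamEps)
      }
      epochLoss <- epochLoss + bl; nb <- nb + 1
    }
    epochLoss <- epochLoss / nb
    valLoss <- if (!is.null(valX))
      evalLoss(model, valX, valY, loss, cfg$batchSize) else NA_real_
    monitored <- if (is.na(valLoss)) epochLoss else valLoss
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = epochLoss,
                                   valLoss = valLoss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s  lr %.1e", epoch,
                      epochLoss,
                      if (is.na(valLoss)) "-" else sprintf("%.4f", valLoss),
                      lr))
    if (isTRUE(monitored < best - cfg$improveTol)) {
      best <- monitored; stagnant <- 0
    } else {
      stagnant <- stagnant + 1
      if (stagnant >= cfg$lrPatience && lr > cfg$minLR) {
        lr <- max(lr / 2, cfg$minLR)
        stagnant <- 0
      }
    }
  }
  model$trained <- TRUE
  model$history <- hist
  model
}

# Mean per-slice (smoothed) loss in inference mode.
evalLoss <- function(model, x, y, loss, batchSize = 8) {
  N <- dim(x)[4]
  tot <- 0
  for (start in seq(1, N, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, N)
    fw <- unetForward(model, x[, , , idx, drop = FALSE], training = FALSE)
    for (k in seq_along(idx))
      tot <- tot + lossWithGrad(y[, , idx[k]], fw$prob[, , 1, k], loss)$loss
  }
  tot / N
}

# Inference-mode probabilities for a stack of slices (H, W, C, N).
predictSlices <- function(model, x, batchSize = 8) {
  N <- dim(x)[4]
  out <- array(0, c(dim(x)[1:2], N))
  for (start in seq(1, N, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, N)
    fw <- unetForward(model, x[, , , idx, drop = FALSE], training = FALSE)
    out[, , idx] <- fw$prob[, , 1, ]
  }
  out
}

#' Segment the spinal canal of a whole-body study
#'
#' Fits ADC/S0 per station, builds the two-channel network input (with
#' the study-wide S0 scaling), runs the trained network slice-by-slice,
#' assembles per-slice probabilities onto the composed whole-body slice
#' grid -- linearly interpolating along the patient axis at grid
#' positions not covered by an acquired slice -- and thresholds at
#' `threshold` to obtain the binary canal mask.
#'
#' @param model a trained [buildUNet()] model.
#' @param study a [DWIStudy].
#' @param threshold probability threshold for the binary mask.
#' @param mapsList optional precomputed list of [ParametricMaps] (one per
#'   station) to avoid refitting.
#' @return a [CanalSegmentation] on the composed grid.
#' @export
predictCanal <- function(model, study, threshold = 0.5, mapsList = NULL) {
  stopifnot(inherits(model, "UNet"), is(study, "DWIStudy"))
  if (!model$trained) stop("model has not been trained")
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(mapsList)) mapsList <- lapply(study@stations, fitMonoexponential)
  lmax <- studyLogS0Max(mapsList)
  cfg <- model$cfg
  probStations <- vector("list", length(mapsList))
  for (i in seq_along(mapsList)) {
    ni <- scaleNetworkInput(mapsList[[i]], logS0Max = lmax,
                            matrixSize = cfg$inputSize,
                            resolution = cfg$resolution)
    nz <- dim(ni@scaledAdc)[1]
    xs <- array(0, c(cfg$inputSize, cfg$inputSize, 2, nz))
    xs[, , 1, ] <- aperm(ni@scaledAdc, c(2, 3, 1))
    xs[, , 2, ] <- aperm(ni@scaledS0, c(2, 3, 1))
    pr <- predictSlices(model, xs)
    # map probabilities back onto the station's native in-plane grid
    st <- mapsList[[i]]
    d <- dim(st@adc)
    native <- array(0, d)
    same <- d[2] == cfg$inputSize && d[3] == cfg$inputSize &&
      all(abs(st@spacing[2:3] - cfg$resolution) < 1e-9)
    for (z in seq_len(nz)) {
      native[z, , ] <- if (same) pr[, , z] else
        resampleSlice2(pr[, , z], c(cfg$resolution, cfg$resolution),
                       st@spacing[2:3], d[2:3])
    }
    probStations[[i]] <- native
  }
  grid <- composedGrid(study)
  prob <- assembleOnGrid(probStations,
                         lapply(study@stations, slot, "slicePositions"), grid)
  prob <- pmin(pmax(prob, 0), 1)
  mask <- (prob >= threshold) * 1
  new("CanalSegmentation", probability = prob, mask = mask,
      threshold = threshold, slicePositions = grid$positions,
      spacing = c(grid$thickness, study@stations[[1]]@spacing[2:3]))
}

# rectangular variant of resampleSlice (used for the inverse mapping)
resampleSlice2 <- function(mat, fromSpacing, toSpacing, outDim) {
  interp1 <- function(nIn, nOut, sIn, sOut) {
    pos <- (seq_len(nOut) - (nOut + 1) / 2) * sOut / sIn + (nIn + 1) / 2
    A <- matrix(0, nOut, nIn)
    lo <- floor(pos); f <- pos - lo
    for (k in seq_len(nOut)) {
      if (lo[k] >= 1 && lo[k] <= nIn) A[k, lo[k]] <- 1 - f[k]
      if (lo[k] + 1 >= 1 && lo[k] + 1 <= nIn)
        A[k, lo[k] + 1] <- A[k, lo[k] + 1] + f[k]
    }
    A
  }
  A <- interp1(nrow(mat), outDim[1], fromSpacing[1], toSpacing[1])
  B <- interp1(ncol(mat), outDim[2], fromSpacing[2], toSpacing[2])
  A %*% mat %*% t(B)
}

# Regular composed slice grid spanning the study superior -> inferior.
composedGrid <- function(study) {
  pos <- sort(unique(unlist(lapply(study@stations, slot, "slicePositions"))))
  thickness <- study@stations[[1]]@spacing[1]
  positions <- seq(min(pos), max(pos) + thickness / 2, by = thickness)
  list(positions = positions, thickness = thickness)
}

# Place per-station slice stacks (list of (Z,H,W)) onto the composed
# grid; duplicate positions resolve to the more superior station, grid
# positions without an acquired slice are linearly interpolated along
# the patient axis.
assembleOnGrid <- function(stacks, positionsList, grid, tol = NULL) {
  if (is.null(tol)) tol <- grid$thickness / 100
  d <- dim(stacks[[1]])[2:3]
  nz <- length(grid$positions)
  out <- array(NA_real_, c(nz, d[1], d[2]))
  filled <- rep(FALSE, nz)
  for (i in seq_along(stacks)) {          # superior stations first: they win
    for (z in seq_along(positionsList[[i]])) {
      j <- which(abs(grid$positions - positionsList[[i]][z]) < tol)
      if (length(j) == 1L && !filled[j]) {
        out[j, , ] <- stacks[[i]][z, , ]
        filled[j] <- TRUE
      }
    }
  }
  if (!all(filled)) {
    have <- which(filled)
    for (j in which(!filled)) {
      lo <- max(have[have < j], -Inf); hi <- min(have[have > j], Inf)
      if (is.infinite(lo)) { out[j, , ] <- out[hi, , ]; next }
      if (is.infinite(hi)) { out[j, , ] <- out[lo, , ]; next }
      w <- (grid$positions[j] - grid$positions[lo]) /
           (grid$positions[hi] - grid$positions[lo])
      out[j, , ] <- (1 - w) * out[lo, , ] + w * out[hi, , ]
    }
  }
  out
}
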