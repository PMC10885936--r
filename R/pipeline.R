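#' Pipeline configuration
#'
#' @param bC cDWI synthesis b-value (s/mm^2).
#' @param percentile in-canal reference percentile for normalisation.
#' @param threshold canal probability threshold.
#' @param nAdjacent slices per side of a station boundary used for CDF
#'   matching.
#' @param seed seed for the GMM fit and any other pipeline randomness.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(bC = 900, percentile = 90, threshold = 0.5,
                           nAdjacent = 3, seed = 1) {
  stopifnot(bC >= 0, percentile > 0, percentile < 100,
            threshold > 0, threshold < 1, nAdjacent >= 1)
  structure(list(bC = bC, percentile = percentile, threshold = threshold,
                 nAdjacent = as.integer(nAdjacent), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full WBDWI standardisation pipeline
#'
#' Executes, in order: per-station monoexponential fitting, cDWI
#' synthesis at `bC`, whole-body composition, inter-station
#' harmonisation, U-Net canal segmentation, GMM cord/CSF
#' characterisation, and standardisation to the in-canal percentile.
#' Each stage is timed and logged; errors are re-raised with the stage
#' name. The run is deterministic given the configuration seed.
#'
#' @param study a [DWIStudy].
#' @param model a trained [buildUNet()] model.
#' @param config a [pipelineConfig()].
#' @param verbose log one message per stage.
#' @return list with `normalised` (a [NormalisedStudy]), `segmentation`
#'   (a [CanalSegmentation]), `gmm` (a [GMMResult]), `subSegmentation`,
#'   `shape` (canal/cord/CSF shape statistics), `composedAdc`, and
#'   `report` (scale factors, canal reference, GMM parameters, timings).
#' @export
runPipeline <- function(study, model, config = pipelineConfig(),
                        verbose = FALSE) {
  stopifnot(is(study, "DWIStudy"), inherits(model, "UNet"),
            inherits(config, "PipelineConfig"))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[[name]] <<- dt
    if (verbose) message(sprintf("[%s] %.2fs", name, dt))
    out
  }
  set.seed(config$seed)
  mapsList <- stage("fit", lapply(study@stations, fitMonoexponential))
  cdwiList <- stage("cdwi", lapply(mapsList, computeCDWI, bC = config$bC))
  composed <- stage("compose", composeStations(study, cdwiList))
  harmonised <- stage("harmonise",
                      harmoniseStations(composed, config$nAdjacent))
  seg <- stage("segment",
               predictCanal(model, study, threshold = config$threshold,
                            mapsList = mapsList))
  spacing <- c(composed$thickness, study@stations[[1]]@spacing[2:3])
  adcComposed <- stage("composeAdc",
                       assembleOnGrid(lapply(mapsList, slot, "adc"),
                                      lapply(study@stations, slot,
                                             "slicePositions"),
                                      composedGrid(study)))
  gmm <- stage("gmm",
               fitCanalGMM(adcComposed[seg@mask > 0], seed = config$seed))
  sub <- stage("split", splitCordCSF(seg@mask, adcComposed, gmm))
  shape <- stage("shape", list(
    canal = shapeStats(seg@mask, spacing),
    cord = shapeStats(sub@cordMask, spacing),
    csf = shapeStats(sub@csfMask, spacing)))
  norm <- stage("normalise",
                normaliseToCanal(composed, harmonised, seg@mask,
                                 percentile = config$percentile,
                                 inPlane = study@stations[[1]]@spacing[2:3]))
  report <- list(
    patient_id = study@patientId, scan_label = study@scanLabel,
    seed = config$seed, b_c = config$bC,
    station_scale_factors = norm@stationScaleFactors,
    canal_reference = norm@canalReference,
    gmm = list(weights = gmm@weights, means = gmm@means,
               variances = gmm@variances),
    shape = shape,
    # posterior-weight-based volume split of the canal, alongside the
    # hard-assignment volumes in `shape`
    weight_volumes = list(cord = gmm@weights[1] * shape$canal$volume,
                          csf = gmm@weights[2] * shape$canal$volume),
    display_window = list(level = 1.5, width = 3.0),
    timings = as.list(timings))
  list(normalised = norm, segmentation = seg, gmm = gmm,
       subSegmentation = sub, shape = shape, composedAdc = adcComposed,
       report = report)
}

#' Write pipeline reports
#'
#' Emits the JSON report and a one-row CSV of per-study canal
#' statistics (volume, average cross-section area, GMM weights, means
#' and variances for cord and CSF).
#'
#' @param result a [runPipeline()] result.
#' @param jsonPath,csvPath output files (`NULL` to skip either).
#' @return invisibly, the CSV row as a data.frame.
#' @export
writePipelineReport <- function(result, jsonPath = NULL, csvPath = NULL) {
  rep <- result$report
  if (!is.null(jsonPath))
    jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  row <- data.frame(
    patient_id = rep$patient_id, scan_label = rep$scan_label,
    volume_ml = rep$shape$canal$volume,
    avg_cross_section_mm2 = rep$shape$canal$averageCrossSectionArea,
    weight_cord = rep$gmm$weights[1], weight_csf = rep$gmm$weights[2],
    mean_cord = rep$gmm$means[1], mean_csf = rep$gmm$means[2],
    var_cord = rep$gmm$variances[1], var_csf = rep$gmm$variances[2],
    canal_reference = rep$canal_reference)
  if (!is.null(csvPath)) write.csv(row, csvPath, row.names = FALSE)
  invisible(row)
}

#' Build a slice training set from phantoms
#'
#' Generates `n` phantoms (seeds `seedStart ... seedStart + n - 1`),
#' fits ADC/S0, scales the network input with the study-wide S0 maximum,
#' and stacks all slices with their ground-truth canal masks. Slices
#' with empty canal masks are retained. The phantom index of every slice
#' is returned so splits can be made by phantom, not by slice, avoiding
#' leakage.
#'
#' @param n number of phantoms.
#' @param spec template [phantomSpec()]; its seed is overridden per
#'   phantom.
#' @param seedStart first phantom seed.
#' @param inputSize,resolution network input grid.
#' @return list with `x` (H, W, 2, N), `y` (H, W, N), `phantom` (integer
#'   N), and `phantoms` (the generated phantom objects).
#' @export
phantomTrainingData <- function(n, spec = phantomSpec(), seedStart = 100,
                                inputSize = spec$matrixSize,
                                resolution = spec$inPlaneMm) {
  xs <- list(); ys <- list(); pid <- integer(0)
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec; sp$seed <- seedStart + i - 1
    ph <- generatePhantom(sp)
    phantoms[[i]] <- ph
    mapsList <- lapply(ph$study@stations, fitMonoexponential)
    lmax <- studyLogS0Max(mapsList)
    for (m in mapsList) {
      ni <- scaleNetworkInput(m, logS0Max = lmax, matrixSize = inputSize,
                              resolution = resolution)
      nz <- dim(ni@scaledAdc)[1]
      x <- array(0, c(inputSize, inputSize, 2, nz))
      x[, , 1, ] <- aperm(ni@scaledAdc, c(2, 3, 1))
      x[, , 2, ] <- aperm(ni@scaledS0, c(2, 3, 1))
      xs[[length(xs) + 1]] <- x
    }
    # truth slices follow station order on the whole-body grid
    yAll <- aperm(ph$truth$canal, c(2, 3, 1))
    ys[[length(ys) + 1]] <- yAll
    pid <- c(pid, rep(i, dim(yAll)[3]))
  }
  N <- sum(vapply(xs, function(a) dim(a)[4], integer(1)))
  H <- dim(xs[[1]])[1]
  x <- array(0, c(H, H, 2, N)); k <- 0
  for (a in xs) {
    nz <- dim(a)[4]
    x[, , , k + seq_len(nz)] <- a
    k <- k + nz
  }
  y <- array(0, c(H, H, N)); k <- 0
  for (a in ys) {
    nz <- dim(a)[3]
    y[, , k + seq_len(nz)] <- a
    k <- k + nz
  }
  list(x = x, y = y, phantom = pid, phantoms = phantoms)
}

#' Scaled-down segmentation benchmark
#'
#' Trains the reduced U-Net (filters 8/16/32/64, bottleneck 128, 64x64
#' slices) on a set of synthetic phantoms split 70/15/15 by phantom,
#' with the Focal Tversky loss at its tuned optimum (alpha 0.7, beta
#' 0.3, gamma 1.1), and evaluates patient-wise Dice, precision and
#' recall of the thresholded predictions against the ground-truth canal
#' masks on the validation and test phantoms.
#'
#' @param nPhantoms phantoms to generate.
#' @param spec template [phantomSpec()] (defaults to a 2-station,
#'   7-slice, 64x64 phantom so ~15 phantoms give ~200 slices).
#' @param epochs training epochs.
#' @param seed master seed (phantom generation, split, training).
#' @param verbose print training progress.
#' @return list with `model`, `history`, `valMetrics`, `testMetrics`
#'   (each the mean over phantoms of dice/precision/recall), and the
#'   per-phantom metric tables.
#' @export
segmentationBenchmark <- function(nPhantoms = 15,
                                  spec = phantomSpec(nStations = 2,
                                                     slicesPerStation = 7),
                                  epochs = 30, seed = 1, verbose = FALSE) {
  data <- phantomTrainingData(nPhantoms, spec,
                              seedStart = (seed %% 1000000L) * 1000L)
  set.seed(seed)
  ids <- sample(seq_len(nPhantoms))
  nTrain <- max(1, round(0.7 * nPhantoms))
  nVal <- max(1, round(0.15 * nPhantoms))
  trainIds <- ids[seq_len(nTrain)]
  valIds <- ids[nTrain + seq_len(nVal)]
  testIds <- setdiff(ids, c(trainIds, valIds))
  sel <- function(idset) data$phantom %in% idset
  model <- buildUNet(unetConfig(encoderFilters = c(8, 16, 32, 64),
                                bottleneckFilters = 128, inputSize = 64),
                     seed = seed)
  model <- trainUNet(model,
                     data$x[, , , sel(trainIds), drop = FALSE],
                     data$y[, , sel(trainIds), drop = FALSE],
                     valX = data$x[, , , sel(valIds), drop = FALSE],
                     valY = data$y[, , sel(valIds), drop = FALSE],
                     cfg = trainConfig(epochs = epochs, seed = seed),
                     loss = lossConfig("focal_tversky"),
                     verbose = verbose)
  evalIds <- function(idset) {
    rows <- t(vapply(idset, function(i) {
      ph <- data$phantoms[[i]]
      seg <- predictCanal(model, ph$study)
      overlapMetrics(seg@mask, ph$truth$canal)
    }, numeric(3)))
    colnames(rows) <- c("dice", "precision", "recall")
    rows
  }
  valRows <- evalIds(valIds)
  testRows <- evalIds(testIds)
  list(model = model, history = model$history,
       valMetrics = colMeans(valRows), testMetrics = colMeans(testRows),
       valPerPhantom = valRows, testPerPhantom = testRows,
       split = list(train = trainIds, val = valIds, test = testIds))
}
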