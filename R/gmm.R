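#' Fit a two-component Gaussian mixture to in-canal ADC values
#'
#' The ADC distribution inside the spinal canal is bimodal: a lower mode
#' from the spinal cord and a higher one from the surrounding CSF. This
#' fits a 2-component univariate Gaussian mixture by EM with k-means
#' initialisation (`nInit` restarts, best log-likelihood kept),
#' convergence tolerance 1e-6 on the log-likelihood, at most 500
#' iterations, and a variance floor of 1e-4 to guard against collapse.
#' The EM runs on values scaled to 1e-3 mm^2/s units to stay
#' well-conditioned, and components are ordered by mean so component 1
#' is always the cord.
#'
#' @param adcValues numeric vector of ADC values in mm^2/s (at least 50).
#' @param seed RNG seed controlling the k-means restarts.
#' @param nInit number of EM restarts.
#' @param tol,maxIter EM convergence controls.
#' @return a [GMMResult] (means/variances in 1e-3 mm^2/s units).
#' @export
fitCanalGMM <- function(adcValues, seed = 1, nInit = 5, tol = 1e-6,
                        maxIter = 500) {
  x <- as.numeric(adcValues)
  if (length(x) < 50) stop("at least 50 ADC values are required")
  if (any(!is.finite(x))) stop("ADC values must be finite")
  x <- x * 1e3
  set.seed(seed)
  varFloor <- 1e-4
  best <- NULL
  for (r in seq_len(nInit)) {
    km <- tryCatch(kmeans(x, centers = 2, nstart = 1),
                   error = function(e) NULL)
    if (is.null(km)) {                  # fewer than 2 distinct values
      mu <- mean(x) + c(-1, 1) * max(sd(x), sqrt(varFloor))
      w <- c(0.5, 0.5)
      v <- rep(max(var(x), varFloor), 2)
    } else {
      mu <- as.numeric(km$centers)
      w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(x)
      w <- pmax(w, 1e-3); w <- w / sum(w)
      v <- vapply(1:2, function(k) {
        xi <- x[km$cluster == k]
        if (length(xi) > 1) max(var(xi), varFloor) else varFloor
      }, numeric(1))
    }
    fit <- emGaussian2(x, w, mu, v, tol, maxIter, varFloor)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  ord <- order(best$mu)
  mu <- best$mu[ord]
  if (mu[1] >= mu[2]) {
    # degenerate (e.g. all values identical): effectively one component;
    # split the means by a negligible epsilon to keep the ordering strict
    mu[2] <- mu[1] + sqrt(varFloor) * 1e-3
    warning("degenerate mixture: components collapsed onto one mean")
  }
  new("GMMResult", weights = best$w[ord], means = mu,
      variances = best$v[ord], logLik = best$logLik)
}

# Plain EM for a 2-component univariate Gaussian mixture. The
# log-likelihood is asserted non-decreasing at every iteration.
emGaussian2 <- function(x, w, mu, v, tol, maxIter, varFloor) {
  n <- length(x)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * dnorm(x, mu[1], sqrt(v[1]))
    d2 <- w[2] * dnorm(x, mu[2], sqrt(v[2]))
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    newLL <- sum(log(tot))
    if (newLL < ll - 1e-8 * max(1, abs(ll)))
      stop("EM log-likelihood decreased; numerical failure")
    converged <- is.finite(ll) && (newLL - ll) < tol
    ll <- newLL
    if (converged) break
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    v <- c(sum(g1 * (x - mu[1])^2) / n1,
           sum((1 - g1) * (x - mu[2])^2) / n2)
    v <- pmax(v, varFloor)
  }
  list(w = w, mu = mu, v = v, logLik = ll)
}

#' Split the canal into spinal cord and CSF
#'
#' Assigns every canal voxel to the mixture component with the higher
#' posterior probability of its ADC value; ties go to the cord
#' (component 1). The two sub-masks partition the canal exactly.
#'
#' @param canalMask binary 3-D array.
#' @param adcMap 3-D ADC array (mm^2/s) on the same grid.
#' @param gmm a [GMMResult] fitted on this canal's ADC values.
#' @return a [SubSegmentation].
#' @export
splitCordCSF <- function(canalMask, adcMap, gmm) {
  stopifnot(identical(dim(canalMask), dim(adcMap)), is(gmm, "GMMResult"))
  x <- adcMap * 1e3
  p1 <- gmm@weights[1] * dnorm(x, gmm@means[1], sqrt(gmm@variances[1]))
  p2 <- gmm@weights[2] * dnorm(x, gmm@means[2], sqrt(gmm@variances[2]))
  cord <- (canalMask > 0) & (p1 >= p2)
  csf <- (canalMask > 0) & !cord
  new("SubSegmentation", cordMask = cord * 1, csfMask = csf * 1)
}

#' Volume and average cross-sectional area of a mask
#'
#' @param mask binary 3-D array (slice, row, col).
#' @param spacing voxel spacing (slice thickness, row, col) in mm.
#' @return list with `volume` (mL) and `averageCrossSectionArea` (mm^2,
#'   averaged over slices containing at least one mask voxel). An empty
#'   mask yields zeros with a warning.
#' @export
shapeStats <- function(mask, spacing) {
  stopifnot(length(dim(mask)) == 3L, all(spacing > 0))
  nvox <- sum(mask > 0)
  if (nvox == 0) {
    warning("empty mask: volume 0, cross-section area undefined (reported 0)")
    return(list(volume = 0, averageCrossSectionArea = 0))
  }
  perSlice <- apply(mask > 0, 1, sum)
  list(volume = nvox * prod(spacing) / 1000,
       averageCrossSectionArea =
         mean(perSlice[perSlice > 0]) * spacing[2] * spacing[3])
}

#' Overlap metrics between predicted and true masks
#'
#' Patient-wise Dice, precision and recall computed over the whole 3-D
#' volume. Two empty masks are in perfect agreement and score 1.
#'
#' @param pred,truth binary arrays on the same grid.
#' @return named numeric vector `c(dice, precision, recall)`.
#' @export
overlapMetrics <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  p <- pred > 0; t <- truth > 0
  TP <- sum(p & t); FP <- sum(p & !t); FN <- sum(!p & t)
  if (TP + FP + FN == 0) {
    message("both masks empty: metrics defined as 1")
    return(c(dice = 1, precision = 1, recall = 1))
  }
  c(dice = 2 * TP / (2 * TP + FP + FN),
    precision = if (TP + FP > 0) TP / (TP + FP) else 0,
    recall = if (TP + FN > 0) TP / (TP + FN) else 0)
}
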