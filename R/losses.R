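#' Loss configuration for segmentation training
#'
#' Four region-based losses are supported for the canal segmenter:
#' log-cosh Dice (`log_cosh_dice`), Combo (`combo`, Dice plus
#' omega-weighted binary cross-entropy), Tversky (`tversky`) and Focal
#' Tversky (`focal_tversky`). Defaults are the tuned optima: omega = 0.8,
#' alpha = 0.7, beta = 0.3 (penalising false negatives more than false
#' positives) and gamma = 1.1 (boosting the gradient of small,
#' hard-to-segment regions).
#'
#' @param name loss name.
#' @param omega Combo weight on the cross-entropy term, in (0, 1).
#' @param alpha,beta Tversky false-positive/false-negative weights.
#' @param gamma Focal Tversky exponent (>= 1).
#' @return a `LossConfig` list.
#' @export
lossConfig <- function(name = c("focal_tversky", "tversky", "combo",
                                "log_cosh_dice"),
                       omega = 0.8, alpha = 0.7, beta = 0.3, gamma = 1.1) {
  name <- match.arg(name)
  stopifnot(omega > 0, omega < 1, alpha >= 0, alpha <= 1,
            beta >= 0, beta <= 1, gamma >= 1)
  structure(list(name = name, omega = omega, alpha = alpha, beta = beta,
                 gamma = gamma), class = "LossConfig")
}

# Soft overlap counts between a binary truth mask and a probability map.
softCounts <- function(truth, pred) {
  list(TP = sum(truth * pred), FP = sum((1 - truth) * pred),
       FN = sum(truth * (1 - pred)))
}

#' Evaluate a segmentation loss on one slice
#'
#' Computes the selected loss from soft counts TP = sum(y * p),
#' FP = sum((1 - y) * p), FN = sum(y * (1 - p)). With `smooth = 0` the
#' Dice and Tversky losses are the textbook ratios (an empty truth
#' against an empty prediction is defined as loss 0); `smooth = 1` adds
#' the standard +1 stabiliser to numerator and denominator, the form used
#' during training so that empty slices carry a well-defined gradient.
#'
#' @param truth binary mask (matrix or array), values in \{0, 1\}.
#' @param pred probability map of the same shape, values in [0, 1].
#' @param cfg a [lossConfig()].
#' @param smooth smoothing constant added to ratio numerator/denominator.
#' @return scalar loss value.
#' @export
lossValue <- function(truth, pred, cfg = lossConfig(), smooth = 0) {
  stopifnot(length(truth) == length(pred), all(truth %in% c(0, 1)),
            all(pred >= 0 & pred <= 1))
  ct <- softCounts(truth, pred)
  dl <- diceLoss(ct, smooth)
  switch(cfg$name,
    log_cosh_dice = log(cosh(dl)),
    combo = {
      p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
      bce <- mean(truth * log(p) + (1 - truth) * log(1 - p))
      dl - cfg$omega * bce
    },
    tversky = tverskyLoss(ct, cfg$alpha, cfg$beta, smooth),
    focal_tversky = tverskyLoss(ct, cfg$alpha, cfg$beta, smooth)^cfg$gamma)
}

diceLoss <- function(ct, smooth = 0) {
  den <- 2 * ct$TP + ct$FP + ct$FN + smooth
  if (den == 0) return(0)
  1 - (2 * ct$TP + smooth) / den
}

tverskyLoss <- function(ct, alpha, beta, smooth = 0) {
  den <- ct$TP + alpha * ct$FP + beta * ct$FN + smooth
  if (den == 0) return(0)
  1 - (ct$TP + smooth) / den
}

# Loss and gradient w.r.t. the predicted probabilities for one slice,
# using the smoothed (training) form. Returns list(loss, grad).
lossWithGrad <- function(truth, pred, cfg, smooth = 1) {
  ct <- softCounts(truth, pred)
  N <- ct$TP + smooth
  D <- ct$TP + cfg$alpha * ct$FP + cfg$beta * ct$FN + smooth
  tl <- 1 - N / D
  dDen <- truth + cfg$alpha * (1 - truth) - cfg$beta * truth
  # d(1 - N/D)/dp = -(y*D - N*dDen)/D^2
  dtl <- -(truth * D - N * dDen) / D^2
  if (cfg$name %in% c("tversky", "focal_tversky")) {
    if (cfg$name == "tversky") return(list(loss = tl, grad = dtl))
    g <- cfg$gamma
    return(list(loss = tl^g,
                grad = if (tl > 0) g * tl^(g - 1) * dtl else 0 * dtl))
  }
  # Dice-based losses: recompute with alpha = beta = 0.5 soft counts
  Nd <- 2 * ct$TP + smooth
  Dd <- 2 * ct$TP + ct$FP + ct$FN + smooth
  dl <- 1 - Nd / Dd
  ddl <- -(2 * truth * Dd - Nd * 1) / Dd^2   # d FP + d FN = 1 for every voxel
  if (cfg$name == "log_cosh_dice")
    return(list(loss = log(cosh(dl)), grad = tanh(dl) * ddl))
  # combo
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  bce <- mean(truth * log(p) + (1 - truth) * log(1 - p))
  inRange <- (pred > 1e-7 & pred < 1 - 1e-7)
  dbce <- (truth / p - (1 - truth) / (1 - p)) / length(pred) * inRange
  list(loss = dl - cfg$omega * bce, grad = ddl - cfg$omega * dbce)
}
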