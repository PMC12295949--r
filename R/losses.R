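#' Loss configuration
#'
#' Weights and numerical constants of the hybrid objective
#' `L = alpha * L_Dice + beta * L_BCE`. The weights default to equal
#' (alpha = beta = 1).
#'
#' @param alpha weight of the soft Dice term (>= 0).
#' @param beta weight of the binary cross-entropy term (>= 0).
#' @param smooth additive smoothing constant of the soft Dice ratio
#'   (default 1e-5; keeps empty-target slices finite).
#' @param clamp_eps probabilities are clamped to
#'   `[clamp_eps, 1 - clamp_eps]` before the BCE logs (default 1e-7).
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(alpha = 1, beta = 1, smooth = 1e-5, clamp_eps = 1e-7) {
  if (alpha < 0 || beta < 0) stop("invalid config: alpha, beta must be >= 0")
  if (alpha + beta <= 0) stop("invalid config: alpha + beta must be > 0")
  if (smooth <= 0) stop("invalid config: smooth must be > 0")
  if (clamp_eps <= 0 || clamp_eps >= 0.5)
    stop("invalid config: clamp_eps must be in (0, 0.5)")
  structure(list(alpha = alpha, beta = beta, smooth = smooth,
                 clamp_eps = clamp_eps), class = "loss_config")
}

.check_pair <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred and target shapes differ")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + smooth) / (sum(p) + sum(t) + smooth)`, with the sums
#' taken over all voxels of the batch (not per-sample). Zero in the
#' perfect-overlap limit as `smooth -> 0`.
#'
#' @param pred probabilities in [0, 1].
#' @param target binary array of the same shape.
#' @param smooth additive smoothing constant.
#' @return Non-negative scalar.
#' @export
dice_loss <- function(pred, target, smooth = 1e-5) {
  .check_pair(pred, target)
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target)
  1 - (2 * inter + smooth) / (denom + smooth)
}

# dL/dpred of dice_loss
.dice_loss_grad <- function(pred, target, smooth = 1e-5) {
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target) + smooth
  -(2 * target * denom - (2 * inter + smooth)) / denom^2
}

#' Binary cross-entropy loss
#'
#' Mean over voxels of `-[t*log(p) + (1-t)*log(1-p)]`, with `p` clamped to
#' `[clamp_eps, 1 - clamp_eps]` before the logarithms.
#'
#' @param pred probabilities.
#' @param target binary array of the same shape.
#' @param clamp_eps probability clamp.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, target, clamp_eps = 1e-7) {
  .check_pair(pred, target)
  p <- pmin(pmax(pred, clamp_eps), 1 - clamp_eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

.bce_loss_grad <- function(pred, target, clamp_eps = 1e-7) {
  p <- pmin(pmax(pred, clamp_eps), 1 - clamp_eps)
  inside <- (pred > clamp_eps) & (pred < 1 - clamp_eps)
  g <- (p - target) / (p * (1 - p)) / length(pred)
  g * inside
}

#' Hybrid Dice + BCE loss
#'
#' The weighted training objective `alpha * dice_loss + beta * bce_loss`.
#'
#' @param pred probabilities.
#' @param target binary array of the same shape.
#' @param cfg a [loss_config()].
#' @return Scalar loss.
#' @export
hybrid_loss <- function(pred, target, cfg = loss_config()) {
  if (!inherits(cfg, "loss_config")) stop("`cfg` must be a loss_config")
  cfg$alpha * dice_loss(pred, target, cfg$smooth) +
    cfg$beta * bce_loss(pred, target, cfg$clamp_eps)
}

#' Gradient of the hybrid loss with respect to the predictions
#'
#' Analytic `dL/dpred`, used by the training loop and checkable against
#' central finite differences.
#'
#' @inheritParams hybrid_loss
#' @return Array of the same shape as `pred`.
#' @export
hybrid_loss_grad <- function(pred, target, cfg = loss_config()) {
  g <- cfg$alpha * .dice_loss_grad(pred, target, cfg$smooth) +
    cfg$beta * .bce_loss_grad(pred, target, cfg$clamp_eps)
  dim(g) <- dim(pred)
  g
}
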