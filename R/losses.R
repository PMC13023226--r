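#' Configure the composite segmentation objective
#'
#' Each branch is trained with a weighted sum of binary cross-entropy, soft
#' Dice and Tversky losses. The two branch losses are combined as
#' \eqn{L_3 = (1-\alpha)L_1 + \alpha L_2} with \eqn{\alpha} the EMA
#' coefficient, and the total objective is \eqn{L_3 + \beta L_4} where
#' \eqn{L_4} is the cross-scale consistency loss and \eqn{\beta} is drawn
#' uniformly from \code{[0,1]} once per optimization step.
#'
#' @param w_bce,w_dice,w_tversky nonnegative weights of the three terms
#'   (default 1 each: a plain sum).
#' @param tversky_alpha,tversky_beta false-positive / false-negative penalties
#'   of the Tversky index; at 0.5/0.5 the Tversky loss equals soft Dice.
#'   Defaults 0.3/0.7 penalize missed leakage more than false alarms.
#' @param smooth small positive smoothing constant of the overlap ratios.
#' @param alpha_ema EMA coefficient \eqn{\alpha} in \code{[0,1]} (default 0.3,
#'   the value with the best reported segmentation performance).
#' @param beta_rng_seed seed of the per-step \eqn{\beta} draw.
#' @return an object of class \code{loss_config}.
#' @export
loss_config <- function(w_bce = 1, w_dice = 1, w_tversky = 1,
                        tversky_alpha = 0.3, tversky_beta = 0.7,
                        smooth = 1e-6, alpha_ema = 0.3, beta_rng_seed = 1L) {
  if (min(w_bce, w_dice, w_tversky) < 0) stop("loss weights must be nonnegative")
  if (tversky_alpha + tversky_beta <= 0) stop("tversky_alpha + tversky_beta must be > 0")
  if (smooth <= 0) stop("smooth must be positive")
  if (alpha_ema < 0 || alpha_ema > 1) stop("alpha_ema must lie in [0,1]")
  structure(list(w_bce = w_bce, w_dice = w_dice, w_tversky = w_tversky,
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 smooth = smooth, alpha_ema = alpha_ema,
                 beta_rng_seed = as.integer(beta_rng_seed)),
            class = "loss_config")
}

bce_loss <- function(p, g, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(g * log(p) + (1 - g) * log(1 - p))
}

bce_grad <- function(p, g, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  (p - g) / (p * (1 - p)) / length(p)
}

soft_dice_loss <- function(p, g, smooth = 1e-6) {
  1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
}

soft_dice_grad <- function(p, g, smooth = 1e-6) {
  num <- 2 * sum(p * g) + smooth
  den <- sum(p) + sum(g) + smooth
  -(2 * g * den - num) / den^2
}

tversky_loss <- function(p, g, a, b, smooth = 1e-6) {
  num <- sum(p * g) + smooth
  den <- sum(p * g) + a * sum(p * (1 - g)) + b * sum((1 - p) * g) + smooth
  1 - num / den
}

tversky_grad <- function(p, g, a, b, smooth = 1e-6) {
  num <- sum(p * g) + smooth
  den <- sum(p * g) + a * sum(p * (1 - g)) + b * sum((1 - p) * g) + smooth
  dden <- g + a * (1 - g) - b * g
  -(g * den - num * dden) / den^2
}

#' Per-branch composite loss
#'
#' \code{w_bce*BCE + w_dice*SoftDice + w_tversky*Tversky} over a probability
#' map and a binary target of the same shape. Predictions outside (0,1) are
#' clamped with a warning.
#'
#' @param pred probability map, values in (0,1).
#' @param target binary mask in \{0,1\}.
#' @param cfg a [loss_config()].
#' @param grad if \code{TRUE}, also return the gradient w.r.t. \code{pred}.
#' @return the scalar loss, or (with \code{grad}) a list \code{(loss, grad)}.
#' @export
branch_loss <- function(pred, target, cfg = loss_config(), grad = FALSE) {
  if (!identical(dim(pred), dim(target)) && length(pred) != length(target))
    stop("pred and target shapes differ")
  if (any(pred < 0) || any(pred > 1)) {
    warning("predictions outside [0,1] were clamped")
    pred <- clamp01(pred)
  }
  s <- cfg$smooth
  l <- cfg$w_bce * bce_loss(pred, target) +
    cfg$w_dice * soft_dice_loss(pred, target, s) +
    cfg$w_tversky * tversky_loss(pred, target, cfg$tversky_alpha, cfg$tversky_beta, s)
  if (!grad) return(l)
  g <- cfg$w_bce * bce_grad(pred, target) +
    cfg$w_dice * soft_dice_grad(pred, target, s) +
    cfg$w_tversky * tversky_grad(pred, target, cfg$tversky_alpha, cfg$tversky_beta, s)
  list(loss = l, grad = g)
}

#' Joint loss of the two branches
#'
#' \eqn{L_3 = (1-\alpha)L_1 + \alpha L_2}: the convex combination of the
#' large-scale (down-sampled) branch loss \eqn{L_1} and the small-scale
#' (cropped) branch loss \eqn{L_2}, weighted by the EMA coefficient.
#'
#' @param L1,L2 scalar branch losses.
#' @param alpha EMA coefficient in \code{[0,1]}.
#' @return scalar.
#' @export
joint_loss <- function(L1, L2, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0,1]")
  (1 - alpha) * L1 + alpha * L2
}

#' Cross-scale consistency loss
#'
#' Mean squared difference between the two branches' probability maps after
#' alignment to a common resolution.
#'
#' @param global_probs probability map of the global branch.
#' @param local_probs_montage re-assembled probability map of the local branch
#'   at the same resolution.
#' @return scalar mean squared difference.
#' @export
consistency_loss <- function(global_probs, local_probs_montage) {
  if (!identical(dim(global_probs), dim(local_probs_montage)))
    stop("consistency loss needs aligned shapes; resample one map first")
  mean((global_probs - local_probs_montage)^2)
}

#' Total training objective
#'
#' \eqn{Loss = L_3 + \beta L_4} with \eqn{\beta \sim U(0,1)} drawn once per
#' optimization step from a seeded stream.
#'
#' @param L3 joint branch loss.
#' @param L4 consistency loss.
#' @param beta random weight in \code{[0,1]}.
#' @return scalar.
#' @export
total_loss <- function(L3, L4, beta) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0,1]")
  L3 + beta * L4
}
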