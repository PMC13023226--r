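#' @export
print.cmwnet <- function(x, ...) {
  cat("Collaborative multiscale wavelet network (", x$train$mode, " mode)\n", sep = "")
  cat("  backbone: UNet-Wavelet, depth ", x$net$depth, ", base channels ",
      x$net$base_channels, ", ", format(wunet_n_params(x$large), big.mark = ","),
      " parameters per branch\n", sep = "")
  cat("  branch inputs: global ", x$train$global_size, "px (area down-sampled), local ",
      x$train$patch_size, "px tiles\n", sep = "")
  cat("  EMA alpha ", x$train$alpha_ema, ", trained ", max(x$log$epoch),
      " epochs, best epoch ", x$best_epoch, sep = "")
  if (!is.na(x$val_dsc)) cat(" (validation DSC ", round(x$val_dsc, 4), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.cmwnet <- function(object, ...) {
  s <- list(mode = object$train$mode,
            n_params = wunet_n_params(object$large),
            best_epoch = object$best_epoch,
            val_dsc = object$val_dsc,
            log = object$log)
  class(s) <- "summary.cmwnet"
  s
}

#' @export
print.summary.cmwnet <- function(x, ...) {
  cat("cmwnet fit (", x$mode, "), ", format(x$n_params, big.mark = ","),
      " parameters per branch\n", sep = "")
  cat("best epoch: ", x$best_epoch,
      if (!is.na(x$val_dsc)) paste0("  validation DSC: ", round(x$val_dsc, 4)),
      "\n", sep = "")
  cat("\nTraining log (last rows):\n")
  print(utils::tail(x$log, 5), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract branch parameters
#'
#' @param object a fitted \code{cmwnet}.
#' @param branch \code{"large"} (global/student) or \code{"small"}
#'   (local/teacher).
#' @param ... unused.
#' @return the named list of parameter arrays of that branch.
#' @export
coef.cmwnet <- function(object, branch = c("large", "small"), ...) {
  object[[match.arg(branch)]]
}

#' Predict a leakage mask for a new image
#'
#' Runs both branches at full resolution, binarizes, and refines the local
#' mask under global guidance ([cgnr()]); set \code{fusion_first} to fuse the
#' probability maps before thresholding instead.
#'
#' @param object a fitted \code{cmwnet}.
#' @param newdata an image raster (preprocessed, dims multiples of the patch
#'   size) or a list of such rasters.
#' @param type \code{"mask"} (refined binary mask), \code{"prob"} (fused
#'   probability map) or \code{"pair"} (both branch maps).
#' @param threshold binarization threshold.
#' @param cgnr_mode \code{"simultaneous"} or \code{"fixpoint"}.
#' @param fusion_first fuse probability maps before thresholding.
#' @param fusion_weight global weight of the fusion.
#' @param ... unused.
#' @return a mask / map, or a list of them for list input.
#' @export
predict.cmwnet <- function(object, newdata, type = c("mask", "prob", "pair"),
                           threshold = 0.5, cgnr_mode = "simultaneous",
                           fusion_first = FALSE, fusion_weight = 0.5, ...) {
  type <- match.arg(type)
  one <- function(img) {
    if (object$train$mode != "cmwnet")
      return(infer_mask(img, object$large, object$small, object$net, object$train))
    pc <- predict_case(img, object$large, object$small, object$net,
                       object$train$global_size, object$train$patch_size,
                       threshold, cgnr_mode, fusion_first, fusion_weight)
    switch(type, mask = pc$mask,
           prob = weighted_fusion(pc$pair, fusion_weight),
           pair = pc$pair)
  }
  if (is.list(newdata) && !is.null(newdata$image)) return(one(newdata$image))
  if (is.list(newdata) && !is.matrix(newdata)) return(lapply(newdata, one))
  one(newdata)
}

#' Plot training curves
#'
#' Loss components and validation Dice over epochs.
#'
#' @param x a fitted \code{cmwnet}.
#' @param ... passed to \code{plot}.
#' @export
plot.cmwnet <- function(x, ...) {
  lg <- x$log
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(lg$epoch, lg$total, type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  if (any(is.finite(lg$L1))) lines(lg$epoch, lg$L1, lty = 2)
  if (any(is.finite(lg$L2))) lines(lg$epoch, lg$L2, lty = 3)
  legend("topright", c("total", "L1 (global)", "L2 (local)"),
         lty = 1:3, bty = "n", cex = 0.8)
  if (any(!is.na(lg$val_dsc))) {
    plot(lg$epoch, lg$val_dsc, type = "b", xlab = "epoch", ylab = "DSC",
         main = "validation Dice", ylim = c(0, 1))
    abline(h = x$val_dsc, lty = 2)
  }
  invisible(x)
}
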