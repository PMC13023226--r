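#' Single-level 2D Haar wavelet analysis
#'
#' Decomposes a raster into approximation and detail subbands with the
#' orthonormal Haar filter pair. For each 2x2 block \code{[[a,b],[c,d]]} the
#' subbands are \code{LL=(a+b+c+d)/2}, \code{LH=(a+b-c-d)/2} (horizontal
#' detail), \code{HL=(a-b+c-d)/2} (vertical detail) and \code{HH=(a-b-c+d)/2}.
#' The transform is orthogonal, so squared norms are conserved:
#' \eqn{\|x\|^2 = \|LL\|^2+\|LH\|^2+\|HL\|^2+\|HH\|^2}.
#'
#' @param x a 2D matrix or 3D (H, W, C) array with even spatial dimensions.
#' @return an object of class \code{wavelet_subbands}: a list with elements
#'   \code{LL}, \code{LH}, \code{HL}, \code{HH}, each of spatial size
#'   (H/2, W/2) and the same channel count as the input.
#' @seealso [dwt2_inverse()]
#' @export
#' @examples
#' sb <- dwt2_forward(matrix(1:16, 4, 4) / 16)
#' str(sb$LL)
dwt2_forward <- function(x) {
  stopifnot_image(x)
  x3 <- as_raster3(x)
  h <- dim(x3)[1]; w <- dim(x3)[2]
  if (h %% 2L != 0L || w %% 2L != 0L)
    stop("dwt2_forward needs even spatial dimensions, got ", h, "x", w)
  ro <- seq(1L, h, 2L); re <- ro + 1L
  co <- seq(1L, w, 2L); ce <- co + 1L
  a <- x3[ro, co, , drop = FALSE]; b <- x3[ro, ce, , drop = FALSE]
  cc <- x3[re, co, , drop = FALSE]; d <- x3[re, ce, , drop = FALSE]
  sb <- list(LL = (a + b + cc + d) / 2,
             LH = (a + b - cc - d) / 2,
             HL = (a - b + cc - d) / 2,
             HH = (a - b - cc + d) / 2)
  if (is.matrix(x)) sb <- lapply(sb, function(s) matrix(s, dim(s)[1], dim(s)[2]))
  structure(sb, class = "wavelet_subbands")
}

#' Single-level 2D Haar wavelet synthesis
#'
#' Exact inverse of [dwt2_forward()]: reconstructs the raster from its four
#' subbands. With all detail subbands zero it performs smooth dyadic
#' up-sampling of the approximation band.
#'
#' @param sb a \code{wavelet_subbands} object or a list with equal-shaped
#'   elements \code{LL}, \code{LH}, \code{HL}, \code{HH}.
#' @return a raster with doubled spatial dimensions.
#' @export
dwt2_inverse <- function(sb) {
  need <- c("LL", "LH", "HL", "HH")
  if (!all(need %in% names(sb))) stop("subband list must have LL, LH, HL, HH")
  was2d <- is.matrix(sb$LL)
  bands <- lapply(sb[need], as_raster3)
  dims <- lapply(bands, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all four subbands must share one shape")
  LL <- bands$LL; LH <- bands$LH; HL <- bands$HL; HH <- bands$HH
  h2 <- dim(LL)[1]; w2 <- dim(LL)[2]; nc <- dim(LL)[3]
  out <- array(0, dim = c(2L * h2, 2L * w2, nc))
  ro <- seq(1L, 2L * h2, 2L); re <- ro + 1L
  co <- seq(1L, 2L * w2, 2L); ce <- co + 1L
  out[ro, co, ] <- (LL + LH + HL + HH) / 2
  out[ro, ce, ] <- (LL + LH - HL - HH) / 2
  out[re, co, ] <- (LL - LH + HL - HH) / 2
  out[re, ce, ] <- (LL - LH - HL + HH) / 2
  if (was2d) out[, , 1] else out
}

# Stack subbands along channels (LL, LH, HL, HH blocks); used by the encoder.
subbands_to_channels <- function(sb) {
  b <- lapply(unclass(sb)[c("LL", "LH", "HL", "HH")], as_raster3)
  d <- dim(b$LL)
  out <- array(0, dim = c(d[1], d[2], 4L * d[3]))
  for (k in 1:4) out[, , ((k - 1) * d[3] + 1):(k * d[3])] <- b[[k]]
  out
}

channels_to_subbands <- function(x) {
  d <- dim(x); cc <- d[3] / 4L
  structure(list(LL = x[, , 1:cc, drop = FALSE],
                 LH = x[, , (cc + 1):(2 * cc), drop = FALSE],
                 HL = x[, , (2 * cc + 1):(3 * cc), drop = FALSE],
                 HH = x[, , (3 * cc + 1):(4 * cc), drop = FALSE]),
            class = "wavelet_subbands")
}
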