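## Internal helpers: seeded evaluation, raster plumbing, separable resampling.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched. All package randomness flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Coerce an image to a 3D (H, W, C) array, remembering whether it came in 2D.
as_raster3 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L))
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a 2D matrix or 3D (H, W, C) array")
}

# Undo as_raster3 when the original input was 2D.
drop_raster3 <- function(x, like) {
  if (is.matrix(like) && dim(x)[3] == 1L) matrix(x, dim(x)[1], dim(x)[2]) else x
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_image <- function(x) {
  if (!(is.matrix(x) || (is.array(x) && length(dim(x)) == 3L)))
    stop("image must be a 2D matrix or 3D (H, W, C) array")
  if (any(dim(x) == 0L)) stop("image has zero extent")
  invisible(TRUE)
}

## ---- separable resampling -------------------------------------------------
## A 1D resampling step from n_in to n_out samples is a (n_out x n_in) matrix;
## a 2D resample is M_rows %*% X %*% t(M_cols) per channel. Implementing the
## three resamplers this way gives exact adjoints (matrix transposes) for
## backpropagation through bilinear up-sampling.

interp_rows_nn <- function(n_in, n_out) {
  idx <- floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1
  pmin(pmax(idx, 1L), n_in)
}

interp_matrix_linear <- function(n_in, n_out) {
  # pixel-centre convention: output centre i+0.5 maps to input coord scale*(i+0.5)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  frac <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  m <- matrix(0, n_out, n_in)
  ii <- seq_len(n_out)
  m[cbind(ii, lo + 1)] <- m[cbind(ii, lo + 1)] + (1 - frac)
  m[cbind(ii, hi + 1)] <- m[cbind(ii, hi + 1)] + frac
  m
}

interp_matrix_area <- function(n_in, n_out) {
  # exact overlap weights of output cell [i*s, (i+1)*s) with unit input cells
  s <- n_in / n_out
  m <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * s; b <- i * s
    j0 <- floor(a); j1 <- ceiling(b) - 1
    for (j in j0:j1) {
      ov <- min(b, j + 1) - max(a, j)
      if (ov > 0) m[i, j + 1] <- ov / s
    }
  }
  m
}

# Apply row/col matrices to every channel of a (H, W[, C]) raster.
resample_with <- function(x, m_rows, m_cols) {
  x3 <- as_raster3(x)
  out <- array(0, dim = c(nrow(m_rows), nrow(m_cols), dim(x3)[3]))
  for (c in seq_len(dim(x3)[3]))
    out[, , c] <- m_rows %*% x3[, , c] %*% t(m_cols)
  drop_raster3(out, x)
}

resize_nearest <- function(x, h_out, w_out) {
  x3 <- as_raster3(x)
  out <- x3[interp_rows_nn(dim(x3)[1], h_out), interp_rows_nn(dim(x3)[2], w_out), , drop = FALSE]
  drop_raster3(out, x)
}

resize_bilinear <- function(x, h_out, w_out) {
  d <- dim(as_raster3(x))
  resample_with(x, interp_matrix_linear(d[1], h_out), interp_matrix_linear(d[2], w_out))
}

resize_area <- function(x, h_out, w_out) {
  d <- dim(as_raster3(x))
  resample_with(x, interp_matrix_area(d[1], h_out), interp_matrix_area(d[2], w_out))
}

## ---- PNG I/O --------------------------------------------------------------

read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3]  # drop alpha
  x
}

write_image_png <- function(x, path) {
  png::writePNG(clamp01(x), target = path)
  invisible(path)
}

# Masks travel as {0,1} in memory and {0,255} in 8-bit PNGs.
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x >= 0.5) * 1
}

write_mask_png <- function(mask, path) {
  png::writePNG((mask >= 0.5) * 1, target = path)
  invisible(path)
}
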