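#' Contrast-limited adaptive histogram equalization
#'
#' Standard CLAHE: the image is divided into a grid of contextual tiles,
#' per-tile histograms are clipped at \code{clip_limit} times the uniform
#' level, and the equalization mappings are bilinearly interpolated between
#' tile centres. Grayscale images are equalized directly; for RGB the
#' luminance channel is equalized and chrominance preserved.
#'
#' @param image raster in \code{[0,1]}, (H, W) or (H, W, 3).
#' @param clip_limit positive contrast limit (default 2).
#' @param tile_grid integer vector (nx, ny) of contextual tiles (default 8x8).
#' @return raster in \code{[0,1]} of the input shape.
#' @export
clahe <- function(image, clip_limit = 2, tile_grid = c(8L, 8L)) {
  stopifnot_image(image)
  if (clip_limit <= 0) stop("clip_limit must be positive")
  if (is.matrix(image)) {
    if (diff(range(image)) == 0) return(image)  # nothing to redistribute
    # pad by edge replication to tile-multiple dimensions, equalize, crop back
    h <- nrow(image); w <- ncol(image)
    hp <- as.integer(ceiling(h / tile_grid[1]) * tile_grid[1])
    wp <- as.integer(ceiling(w / tile_grid[2]) * tile_grid[2])
    x <- image[c(seq_len(h), rep(h, hp - h)), c(seq_len(w), rep(w, wp - w))]
    out <- EBImage::clahe(EBImage::Image(x), nx = tile_grid[1],
                          ny = tile_grid[2], limit = clip_limit)
    out <- matrix(EBImage::imageData(out), hp, wp)
    return(clamp01(out[seq_len(h), seq_len(w)]))
  }
  if (dim(image)[3] != 3L) stop("expected grayscale (H, W) or RGB (H, W, 3)")
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  lum_eq <- clahe(lum, clip_limit, tile_grid)
  ratio <- ifelse(lum > 1e-8, lum_eq / pmax(lum, 1e-8), 1)
  out <- image
  for (c in 1:3) out[, , c] <- clamp01(image[, , c] * ratio)
  out
}

#' Gamma correction
#'
#' Elementwise power transform \code{out = in^gamma}. Values below 1 brighten
#' the (dark) periphery; the preprocessing default is 0.8.
#'
#' @param image raster in \code{[0,1]}.
#' @param gamma positive exponent.
#' @return raster of the input shape.
#' @export
gamma_correct <- function(image, gamma) {
  stopifnot_image(image)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  image^gamma
}

#' Resize so both dimensions are exact multiples of a base
#'
#' Rounds each dimension UP to the next multiple of \code{base} and resamples
#' with nearest-neighbour interpolation, so binary masks stay binary and no
#' detail is destroyed by shrinking. Idempotent.
#'
#' @param image raster (or mask).
#' @param base target multiple (default 512).
#' @return resized raster of size \code{ceil(H/base)*base} x
#'   \code{ceil(W/base)*base}.
#' @export
resize_to_multiple <- function(image, base = 512L) {
  stopifnot_image(image)
  if (base < 1L) stop("base must be >= 1")
  d <- dim(as_raster3(image))
  h2 <- as.integer(ceiling(d[1] / base) * base)
  w2 <- as.integer(ceiling(d[2] / base) * base)
  if (h2 == d[1] && w2 == d[2]) return(image)
  resize_nearest(image, h2, w2)
}

#' Cut an image into a non-overlapping grid of square patches
#'
#' The inverse bookkeeping (tile index to source offset, row-major, 0-based,
#' origin top-left, half-open intervals) is returned as a \code{patch_grid}
#' and consumed by [montage()].
#'
#' @param image raster whose dimensions are exact multiples of
#'   \code{patch_size} (use [resize_to_multiple()] first).
#' @param patch_size tile side length (default 512).
#' @return list with \code{patches} (row-major list of rasters) and
#'   \code{grid} (a \code{patch_grid}).
#' @export
crop_grid <- function(image, patch_size = 512L) {
  stopifnot_image(image)
  d <- dim(as_raster3(image))
  if (d[1] %% patch_size != 0L || d[2] %% patch_size != 0L)
    stop("image dims ", d[1], "x", d[2], " are not multiples of ", patch_size,
         "; apply resize_to_multiple() first")
  rows <- d[1] %/% patch_size; cols <- d[2] %/% patch_size
  grid <- structure(list(source_height = d[1], source_width = d[2],
                         patch_size = as.integer(patch_size),
                         rows = as.integer(rows), cols = as.integer(cols)),
                    class = "patch_grid")
  patches <- vector("list", rows * cols)
  x3 <- as_raster3(image)
  for (j in seq_len(rows * cols) - 1L) {
    rc <- patch_origin(grid, j)
    p <- x3[(rc[1] + 1L):(rc[1] + patch_size), (rc[2] + 1L):(rc[2] + patch_size), , drop = FALSE]
    patches[[j + 1L]] <- drop_raster3(p, image)
  }
  list(patches = patches, grid = grid)
}

# 0-based (row, col) pixel origin of tile j (0-based, row-major).
patch_origin <- function(grid, j) {
  if (j < 0L || j >= grid$rows * grid$cols) stop("tile index out of range")
  r <- j %/% grid$cols; c <- j %% grid$cols
  c(r * grid$patch_size, c * grid$patch_size)
}

#' Reassemble patches into the source image
#'
#' Exact inverse of [crop_grid()] on a matching grid.
#'
#' @param patches row-major list of patches.
#' @param grid the \code{patch_grid} from [crop_grid()].
#' @return the reassembled raster.
#' @export
montage <- function(patches, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  if (length(patches) != grid$rows * grid$cols)
    stop("expected ", grid$rows * grid$cols, " patches, got ", length(patches))
  p1 <- as_raster3(patches[[1]])
  if (dim(p1)[1] != grid$patch_size || dim(p1)[2] != grid$patch_size)
    stop("patch shape does not match grid patch_size")
  out <- array(0, dim = c(grid$source_height, grid$source_width, dim(p1)[3]))
  ps <- grid$patch_size
  for (j in seq_along(patches) - 1L) {
    rc <- patch_origin(grid, j)
    out[(rc[1] + 1L):(rc[1] + ps), (rc[2] + 1L):(rc[2] + ps), ] <- as_raster3(patches[[j + 1L]])
  }
  drop_raster3(out, patches[[1]])
}

#' Down-sample a full image to the shared branch input size
#'
#' Area (box-average) resampling to \code{target} x \code{target}: the
#' global-branch reduction that gives both branches a uniform input size.
#' Mean intensity is preserved exactly.
#'
#' @param image raster.
#' @param target output side length (default 512, minimum 32).
#' @return raster of size target x target.
#' @export
downsample_global <- function(image, target = 512L) {
  stopifnot_image(image)
  if (target < 32L) stop("target must be >= 32")
  d <- dim(as_raster3(image))
  if (target > min(d[1], d[2]))
    warning("target exceeds input size; up-sampling the 'down-sampled' branch")
  resize_area(image, target, target)
}

#' Paired training augmentation
#'
#' With probability 0.5 both image and mask are horizontally flipped
#' together; photometric jitter (brightness, contrast, and for RGB also
#' saturation and hue) is applied to the image only. Mask geometry follows
#' image geometry exactly, so the foreground pixel count is invariant.
#'
#' @param image raster in \code{[0,1]}.
#' @param mask paired binary mask.
#' @param seed integer seed of the augmentation draw.
#' @param brightness,contrast,saturation half-widths of the multiplicative /
#'   additive jitter ranges (defaults 0.2).
#' @param hue half-width of the hue rotation (default 0.05; RGB only).
#' @return list with augmented \code{image} and \code{mask}.
#' @export
augment <- function(image, mask, seed, brightness = 0.2, contrast = 0.2,
                    saturation = 0.2, hue = 0.05) {
  stopifnot_image(image)
  dm <- dim(as_raster3(image))
  if (!all(dim(as_raster3(mask))[1:2] == dm[1:2])) stop("image and mask shapes differ")
  with_seed(seed, {
    flip <- runif(1) < 0.5
    db <- runif(1, -brightness, brightness)
    dc <- runif(1, 1 - contrast, 1 + contrast)
    ds <- runif(1, 1 - saturation, 1 + saturation)
    dh <- runif(1, -hue, hue)
    img <- image; msk <- mask
    if (flip) {
      img <- flip_h(img); msk <- flip_h(msk)
    }
    m <- mean(img)
    img <- (img - m) * dc + m + db          # contrast about the mean, then brightness
    if (!is.matrix(img) && dim(img)[3] == 3L) {
      lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      for (c in 1:3) img[, , c] <- lum + (img[, , c] - lum) * ds
      img <- rotate_hue(img, dh)
    }
    list(image = clamp01(img), mask = msk)
  })
}

flip_h <- function(x) {
  if (is.matrix(x)) x[, rev(seq_len(ncol(x)))]
  else x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
}

# Small hue rotation via the YIQ-like chroma plane.
rotate_hue <- function(img, dh) {
  if (dh == 0) return(img)
  th <- dh * 2 * pi
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  i <- 0.596 * r - 0.274 * g - 0.322 * b
  q <- 0.211 * r - 0.523 * g + 0.312 * b
  i2 <- i * cos(th) - q * sin(th)
  q2 <- i * sin(th) + q * cos(th)
  out <- img
  out[, , 1] <- y + 0.956 * i2 + 0.621 * q2
  out[, , 2] <- y - 0.272 * i2 - 0.647 * q2
  out[, , 3] <- y - 1.106 * i2 + 1.703 * q2
  out
}

#' Full preprocessing for one case
#'
#' CLAHE, then gamma correction, then resize so dimensions are multiples of
#' \code{base}; the mask is only resized (nearest neighbour), never
#' photometrically altered.
#'
#' @param image raster in \code{[0,1]}.
#' @param mask optional paired binary mask.
#' @param base multiple for [resize_to_multiple()].
#' @param clahe_clip,clahe_tiles CLAHE parameters.
#' @param gamma gamma exponent (default 0.8).
#' @return list with \code{image} and (if given) \code{mask}.
#' @export
preprocess_case <- function(image, mask = NULL, base = 512L, clahe_clip = 2,
                            clahe_tiles = c(8L, 8L), gamma = 0.8) {
  img <- clahe(image, clahe_clip, clahe_tiles)
  img <- gamma_correct(img, gamma)
  img <- resize_to_multiple(img, base)
  out <- list(image = img)
  if (!is.null(mask)) out$mask <- (resize_to_multiple(mask, base) >= 0.5) * 1
  out
}
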