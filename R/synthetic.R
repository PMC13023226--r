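#' Configure the synthetic fundus generator
#'
#' Defines the study conditions for fundus-style test images: an elliptical
#' bright field of view with radial vignetting, bright curvilinear vessels
#' (confusable with lesions but never labelled), irregular fuzzy
#' hyperfluorescent leakage blobs with an analytic ground-truth mask, and
#' additive Gaussian noise. The default canvas is 2048x1536 — deliberately
#' not a multiple of 512, as real angiograms are not.
#'
#' @param height,width canvas size in pixels (>= 64).
#' @param n_vessels number of curvilinear vessel structures.
#' @param vessel_intensity vessel brightness in \code{[0,1]}.
#' @param n_leakage number of leakage lesions.
#' @param leakage_radius_range lesion radius range (pixels), min <= max.
#' @param leakage_contrast mean intensity lift of a lesion over background,
#'   in \code{[0,1]}.
#' @param blur_sigma Gaussian blur (pixels) applied to lesion blobs.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param vignette_strength radial vignetting strength in \code{[0,1]}.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(height = 2048L, width = 1536L, n_vessels = 12L,
                         vessel_intensity = 0.85, n_leakage = 6L,
                         leakage_radius_range = c(6, 60),
                         leakage_contrast = 0.35, blur_sigma = 4,
                         noise_sd = 0.02, vignette_strength = 0.5, seed = 1L) {
  if (height < 64L || width < 64L) stop("canvas must be at least 64x64")
  r <- leakage_radius_range
  if (length(r) != 2L || r[1] > r[2]) stop("leakage_radius_range must be (min, max) with min <= max")
  if (r[2] > min(height, width) / 2) stop("maximum lesion radius exceeds half the canvas")
  for (v in c(vessel_intensity, leakage_contrast, vignette_strength))
    if (v < 0 || v > 1) stop("intensity fields must lie in [0,1]")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_vessels = as.integer(n_vessels),
                 vessel_intensity = vessel_intensity,
                 n_leakage = as.integer(n_leakage),
                 leakage_radius_range = as.numeric(r),
                 leakage_contrast = leakage_contrast, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, vignette_strength = vignette_strength,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Easy high-contrast preset
#'
#' Large, bright, well-separated lesions on a small canvas: the regime used
#' for fast training recovery experiments on CPU.
#' @param size canvas side (square), default 256.
#' @param seed integer seed.
#' @return a [synth_config()].
#' @export
synth_config_easy <- function(size = 256L, seed = 1L) {
  synth_config(height = size, width = size, n_vessels = 4L,
               vessel_intensity = 0.8, n_leakage = 3L,
               leakage_radius_range = c(0.07 * size, 0.16 * size),
               leakage_contrast = 0.5, blur_sigma = 2, noise_sd = 0.01,
               vignette_strength = 0.3, seed = seed)
}

# Stamp a disc of radius r at integer centre (cy, cx) into logical matrix m.
stamp_disc <- function(m, cy, cx, r) {
  h <- nrow(m); w <- ncol(m)
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(m)
  yy <- y0:y1; xx <- x0:x1
  dd <- outer((yy - cy)^2, (xx - cx)^2, "+")
  m[yy, xx] <- m[yy, xx] | (dd <= r^2)
  m
}

draw_vessels <- function(cfg, fov) {
  h <- cfg$height; w <- cfg$width
  stencil <- matrix(FALSE, h, w)
  for (v in seq_len(cfg$n_vessels)) {
    # quadratic Bezier with endpoints near the field border, bowed control point
    t0 <- runif(1, 0, 2 * pi); t1 <- t0 + runif(1, pi / 2, 3 * pi / 2)
    p0 <- c(h / 2 + 0.45 * h * sin(t0), w / 2 + 0.45 * w * cos(t0))
    p2 <- c(h / 2 + 0.45 * h * sin(t1), w / 2 + 0.45 * w * cos(t1))
    p1 <- (p0 + p2) / 2 + c(runif(1, -0.25, 0.25) * h, runif(1, -0.25, 0.25) * w)
    width_px <- runif(1, 1.2, 3)
    ts <- seq(0, 1, length.out = 2L * max(h, w) %/% 2)
    pts <- cbind((1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * p2[1],
                 (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * p2[2])
    pts <- round(pts)
    keep <- pts[, 1] >= 1 & pts[, 1] <= h & pts[, 2] >= 1 & pts[, 2] <= w
    pts <- unique(pts[keep, , drop = FALSE])
    rr <- ceiling(width_px)
    offs <- expand.grid(dy = -rr:rr, dx = -rr:rr)
    offs <- offs[offs$dy^2 + offs$dx^2 <= width_px^2, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      py <- pts[, 1] + offs$dy[k]; px <- pts[, 2] + offs$dx[k]
      ok <- py >= 1 & py <= h & px >= 1 & px <= w
      stencil[cbind(py[ok], px[ok])] <- TRUE
    }
  }
  stencil & fov
}

# One lesion: union of jittered discs, Gaussian blur, mask at half-maximum.
# Returns NULL if it cannot be placed off the vessel stencil.
draw_lesion <- function(cfg, fov, vessels, radius, n_discs, sigma = cfg$blur_sigma) {
  h <- cfg$height; w <- cfg$width
  pad <- ceiling(3 * sigma + radius * 2)
  for (attempt in 1:100) {
    cy <- runif(1, 0.15 * h, 0.85 * h); cx <- runif(1, 0.15 * w, 0.85 * w)
    if (!fov[round(cy), round(cx)]) next
    sup <- matrix(FALSE, h, w)
    sup <- stamp_disc(sup, cy, cx, radius)
    if (n_discs > 1) {
      for (dsc in seq_len(n_discs - 1L)) {
        jy <- cy + runif(1, -0.7, 0.7) * radius
        jx <- cx + runif(1, -0.7, 0.7) * radius
        sup <- stamp_disc(sup, jy, jx, runif(1, 0.4, 0.9) * radius)
      }
    }
    # blur and threshold on a bounding box for speed
    y0 <- max(1L, round(cy) - pad); y1 <- min(h, round(cy) + pad)
    x0 <- max(1L, round(cx) - pad); x1 <- min(w, round(cx) + pad)
    box <- sup[y0:y1, x0:x1] * 1
    bb <- EBImage::gblur(box, sigma = sigma)
    bb <- bb / max(bb)
    mbox <- bb >= 0.5
    mask <- matrix(FALSE, h, w); mask[y0:y1, x0:x1] <- mbox
    if (any(mask & vessels)) next   # lesions never touch the vessel stencil
    if (any(mask & !fov)) next
    bump <- matrix(0, h, w); bump[y0:y1, x0:x1] <- bb
    return(list(bump = bump, mask = mask))
  }
  NULL
}

#' Generate one synthetic fundus image and its leakage mask
#'
#' @param config a [synth_config()].
#' @param force_subtle if \code{TRUE}, the first lesion is shrunk until its
#'   mask area is below \code{height*width/4096}, guaranteeing one lesion in
#'   the subtle-leakage regime that plain down-sampling destroys.
#' @return list with \code{image} ((H, W) matrix in \code{[0,1]}) and
#'   \code{mask} ((H, W) matrix over \{0,1\}). The internal vessel stencil and
#'   field-of-view are attached as attributes \code{"vessels"} and
#'   \code{"fov"} for structural checks.
#' @export
generate_fundus <- function(config, force_subtle = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    h <- config$height; w <- config$width
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    re2 <- ((yy - h / 2) / (0.48 * h))^2 + ((xx - w / 2) / (0.48 * w))^2
    fov <- re2 <= 1
    base <- matrix(0.02, h, w)
    base[fov] <- 0.22 * (1 - config$vignette_strength * re2[fov])
    vessels <- draw_vessels(config, fov)
    mask <- matrix(FALSE, h, w)
    lesion_field <- matrix(0, h, w)
    if (config$n_leakage > 0) {
      for (k in seq_len(config$n_leakage)) {
        if (force_subtle && k == 1L) {
          # tiny sharp focus: shrink until below the subtle-leakage area bound
          lim <- h * w / 4096
          r <- max(1, floor(sqrt(lim / pi) * 0.6))
          best <- NULL
          repeat {
            les <- draw_lesion(config, fov, vessels, r, n_discs = 1L,
                               sigma = min(config$blur_sigma, 0.8))
            if (!is.null(les)) best <- les
            if (!is.null(les) && sum(les$mask) < lim) break
            r <- r - 1
            if (r < 1) { les <- best; break }
          }
        } else {
          r <- runif(1, config$leakage_radius_range[1], config$leakage_radius_range[2])
          les <- draw_lesion(config, fov, vessels, r, n_discs = sample(3:8, 1))
        }
        if (is.null(les)) next
        lesion_field <- pmax(lesion_field, les$bump)
        mask <- mask | les$mask
      }
    }
    img <- base + config$leakage_contrast * lesion_field
    img <- pmax(img, vessels * config$vessel_intensity)
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(h * w, sd = config$noise_sd), h, w)
    img <- clamp01(img)
    structure(list(image = img, mask = mask * 1),
              vessels = vessels, fov = fov)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes \code{n} image/mask PNG pairs (\code{case_0000.png},
#' \code{case_0000_mask.png}, ...) plus a CSV manifest. The per-case seed is
#' \code{config$seed + k} (0-based counter), so regeneration with the same
#' arguments is byte-identical. The first case always carries one
#' subtle (small, low-contrast-regime) lesion.
#'
#' @param n number of cases.
#' @param config a [synth_config()]; its \code{seed} anchors the per-case seeds.
#' @param out_dir output directory (created if missing).
#' @return the manifest data frame (id, path, mask_path, height, width),
#'   also written to \code{out_dir/manifest.csv}.
#' @export
generate_dataset <- function(n, config, out_dir) {
  stopifnot(n >= 1, inherits(config, "synth_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n)
  for (k in seq_len(n) - 1L) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    case <- generate_fundus(cfg_k, force_subtle = (k == 0L))
    id <- sprintf("case_%04d", k)
    ipath <- file.path(out_dir, paste0(id, ".png"))
    mpath <- file.path(out_dir, paste0(id, "_mask.png"))
    tryCatch({
      write_image_png(case$image, ipath)
      write_mask_png(case$mask, mpath)
    }, error = function(e) stop("failed to write ", ipath, ": ", conditionMessage(e)))
    rows[[k + 1L]] <- data.frame(id = id, path = ipath, mask_path = mpath,
                                 height = config$height, width = config$width,
                                 stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
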