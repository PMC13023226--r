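# Independent brute-force oracles. These deliberately use plain per-pixel
# loops, not the package's vectorized code paths.

# Cross-guided refinement, single simultaneous pass, neighbors read from the
# original base.
cgnr_oracle <- function(base, guide) {
  h <- nrow(base); w <- ncol(base)
  out <- base
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (base[r, c] == 0 && guide[r, c] == 1) {
      found <- FALSE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && base[rr, cc] == 1)
          found <- TRUE
      }
      if (found) out[r, c] <- 1
    }
  }
  out
}

confusion_oracle <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && ref[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && ref[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && ref[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

boundary_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] != 1) next
    edge <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > h || cc < 1 || cc > w || mask[rr, cc] == 0) edge <- TRUE
    }
    if (edge) pts <- rbind(pts, c(r, c))
  }
  if (is.null(pts)) matrix(integer(0), 0, 2) else pts
}

# All-pairs nearest-boundary distances; returns hd95 and asd.
surface_dist_oracle <- function(pred, ref) {
  a <- boundary_oracle(pred); b <- boundary_oracle(ref)
  if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
  dir_min <- function(p, q) {
    out <- numeric(nrow(p))
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt((p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2)
        if (d < best) best <- d
      }
      out[i] <- best
    }
    out
  }
  dab <- dir_min(a, b); dba <- dir_min(b, a)
  list(hd95 = max(quantile(dab, 0.95, names = FALSE),
                  quantile(dba, 0.95, names = FALSE)),
       hd = max(c(dab, dba)),
       asd = mean(c(dab, dba)))
}

# Random binary mask with a few blobs, for metric fixtures.
random_mask <- function(h, w, p = 0.2) {
  matrix(as.numeric(rbinom(h * w, 1, p)), h, w)
}

# Tiny in-memory training set used by trainer tests: fast, easy cases.
tiny_cases <- function(n, size = 128L, seed = 11L) {
  scfg <- synth_config_easy(size = size, seed = seed)
  lapply(seq_len(n) - 1L, function(k) {
    ck <- scfg; ck$seed <- scfg$seed + k
    generate_fundus(ck)
  })
}

smooth_raster <- function(x, sigma = 3) {
  matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma)),
         nrow(x), ncol(x))
}

tiny_net <- function() wunet_config(base_channels = 4L, depth = 2L,
                                    input_size = 64L, norm_groups = 4L)

tiny_train <- function(epochs = 1L, ...) {
  train_config(global_size = 64L, patch_size = 64L, patches_per_image = 2L,
               epochs = epochs, ...)
}
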