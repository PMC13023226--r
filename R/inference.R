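#' Full-resolution predictions from both branches
#'
#' The global path down-samples the image, runs the large-scale model, and
#' bilinearly up-samples its probability map back to source resolution; the
#' local path runs the small-scale model on every grid tile and reassembles
#' the tile maps.
#'
#' @param image preprocessed raster whose dims are multiples of \code{patch_size}.
#' @param large_params,small_params parameter lists of the two branches.
#' @param net the shared [wunet_config()].
#' @param global_size input size of the global branch.
#' @param patch_size tile size of the local branch.
#' @return an object of class \code{prediction_pair}: list with
#'   \code{global_probs}, \code{local_probs} (both at source resolution) and
#'   \code{source_shape}.
#' @export
predict_pair <- function(image, large_params, small_params, net,
                         global_size = 512L, patch_size = 512L) {
  stopifnot_image(image)
  d <- dim(as_raster3(image))
  gin <- downsample_global(image, global_size)
  gp <- wunet_forward(large_params, net, gin)$probs
  gup <- resize_bilinear(gp, d[1], d[2])
  cg <- crop_grid(image, patch_size)
  tile_probs <- lapply(cg$patches, function(p) wunet_forward(small_params, net, p)$probs)
  lp <- montage(tile_probs, cg$grid)
  structure(list(global_probs = clamp01(gup), local_probs = lp,
                 source_shape = d[1:2]),
            class = "prediction_pair")
}

#' Weighted fusion of the two probability maps
#'
#' \code{w * global + (1 - w) * local}, pixelwise.
#'
#' @param pair a \code{prediction_pair}.
#' @param w global-branch weight in \code{[0,1]}.
#' @return fused probability map.
#' @export
weighted_fusion <- function(pair, w) {
  if (w < 0 || w > 1) stop("fusion weight must lie in [0,1]")
  w * pair$global_probs + (1 - w) * pair$local_probs
}

#' Threshold a probability map to a binary mask
#'
#' @param probs probability map in \code{[0,1]}.
#' @param threshold decision threshold in (0,1), default 0.5.
#' @return binary \{0,1\} mask (encoded \{0,255\} when written to PNG).
#' @export
binarize <- function(probs, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  (probs >= threshold) * 1
}

# Count of foreground 8-neighbours at each pixel (out-of-bounds treated as 0).
neighbor8_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  acc <- matrix(0, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    acc <- acc + p[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
  }
  acc
}

#' Cross-guided neighborhood refinement
#'
#' Boundary refinement of a base mask under the structural guidance of a
#' second mask: every background pixel of \code{base} where \code{guide} is
#' foreground is a candidate, and a candidate is promoted to foreground iff
#' at least one of its eight neighbors is foreground in \code{base}. In
#' \code{"simultaneous"} mode all neighbors are read from the original base
#' (a single order-independent pass); \code{"fixpoint"} mode repeats the pass
#' on the updated mask until nothing changes, so guided regions grow until
#' they are filled. Guide-only components with no base support are never
#' added, suppressing isolated false positives.
#'
#' @param base binary mask to be refined (the local-branch mask).
#' @param guide binary guidance mask (the global-branch mask).
#' @param mode \code{"simultaneous"} (default) or \code{"fixpoint"}.
#' @return refined binary mask; always satisfies
#'   \code{base <= result <= base | guide} pixelwise.
#' @export
cgnr <- function(base, guide, mode = c("simultaneous", "fixpoint")) {
  mode <- match.arg(mode)
  if (!identical(dim(base), dim(guide))) stop("base and guide shapes differ")
  base <- (base >= 0.5) * 1
  guide <- (guide >= 0.5) * 1
  step <- function(b) {
    promote <- (b == 0) & (guide == 1) & (neighbor8_count(b) > 0)
    b + promote
  }
  if (mode == "simultaneous") return(step(base))
  cur <- base
  for (it in seq_len(length(base))) {
    nxt <- step(cur)
    if (all(nxt == cur)) break
    cur <- nxt
  }
  cur
}

#' End-to-end prediction for one image
#'
#' Default pipeline: binarize both branch maps, then refine the local mask
#' under global guidance with [cgnr()]. The alternative pipeline fuses the
#' probability maps first ([weighted_fusion()]), binarizes the fusion and
#' refines it under global guidance.
#'
#' @param image preprocessed raster.
#' @param large_params,small_params branch parameters.
#' @param net shared [wunet_config()].
#' @param global_size,patch_size branch input sizes.
#' @param threshold binarization threshold.
#' @param cgnr_mode refinement mode passed to [cgnr()].
#' @param fusion_first use the fusion-first pipeline.
#' @param fusion_weight global weight of [weighted_fusion()].
#' @return list with the final \code{mask} and the \code{pair} of branch maps.
#' @export
predict_case <- function(image, large_params, small_params, net,
                         global_size = 512L, patch_size = 512L,
                         threshold = 0.5, cgnr_mode = "simultaneous",
                         fusion_first = FALSE, fusion_weight = 0.5) {
  pair <- predict_pair(image, large_params, small_params, net, global_size, patch_size)
  gmask <- binarize(pair$global_probs, threshold)
  if (fusion_first) {
    fmask <- binarize(weighted_fusion(pair, fusion_weight), threshold)
    mask <- cgnr(fmask, gmask, cgnr_mode)
  } else {
    lmask <- binarize(pair$local_probs, threshold)
    mask <- cgnr(lmask, gmask, cgnr_mode)
  }
  list(mask = mask, pair = pair)
}
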