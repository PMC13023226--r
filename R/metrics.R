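#' Pixelwise confusion counts
#'
#' @param pred,ref binary masks of equal shape (foreground = positive).
#' @return list of class \code{confusion_counts} with TP, FP, FN, TN.
#' @export
confusion_counts <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("pred and ref shapes differ")
  p <- pred >= 0.5; g <- ref >= 0.5
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_counts")
}

#' Dice coefficient, precision and recall from confusion counts
#'
#' \code{DSC = 2TP/(2TP+FP+FN)}, \code{PR = TP/(TP+FP)},
#' \code{RC = TP/(TP+FN)}. When both masks are empty all three are defined
#' as 1 (perfect agreement on absence).
#'
#' @param c a \code{confusion_counts}.
#' @return named numeric vector (DSC, PR, RC).
#' @export
dice_precision_recall <- function(c) {
  with(c, {
    dsc <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
    pr <- if (TP + FP == 0) (if (FN == 0) 1 else 0) else TP / (TP + FP)
    rc <- if (TP + FN == 0) (if (FP == 0) 1 else 0) else TP / (TP + FN)
    c(DSC = dsc, PR = pr, RC = rc)
  })
}

#' Boundary points of a binary mask
#'
#' Foreground pixels with at least one background 8-neighbor; the image
#' border counts as background.
#'
#' @param mask binary mask.
#' @return integer matrix of (row, col) coordinates, one point per row.
#' @export
boundary_points <- function(mask) {
  m <- mask >= 0.5
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  allnb <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    allnb <- allnb & p[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
  }
  which(m & !allnb, arr.ind = TRUE)
}

# Directed nearest-boundary distances from each point of `a` to the set `b`
# (both k x 2 coordinate matrices), Euclidean pixel metric.
directed_boundary_dists <- function(a, b) {
  if (nrow(a) == 0L) return(numeric(0))
  # chunked cross-distance minimum to bound memory
  out <- numeric(nrow(a))
  step <- max(1L, floor(2e6 / max(1L, nrow(b))))
  for (s in seq(1L, nrow(a), by = step)) {
    e <- min(nrow(a), s + step - 1L)
    d2 <- outer(a[s:e, 1], b[, 1], "-")^2 + outer(a[s:e, 2], b[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

hd95_asd_core <- function(pred, ref) {
  bp <- boundary_points(pred); br <- boundary_points(ref)
  if (nrow(bp) == 0L || nrow(br) == 0L) {
    sentinel <- sqrt(sum(dim(as.matrix(pred))^2))
    return(list(hd95 = sentinel, asd = sentinel, empty = TRUE))
  }
  dab <- directed_boundary_dists(bp, br)
  dba <- directed_boundary_dists(br, bp)
  list(hd95 = max(quantile(dab, 0.95, names = FALSE),
                  quantile(dba, 0.95, names = FALSE)),
       asd = mean(c(dab, dba)), empty = FALSE)
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Symmetric HD95: the larger of the two directed 95th-percentile
#' nearest-boundary distances between the boundary point sets of the two
#' masks (Euclidean, in pixels). If either mask is empty the image diagonal
#' is returned as a sentinel.
#'
#' @param pred,ref binary masks of equal shape.
#' @return distance in pixels.
#' @export
hd95 <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("pred and ref shapes differ")
  hd95_asd_core(pred, ref)$hd95
}

#' Average surface distance between mask boundaries
#'
#' Symmetric ASD: the mean of the pooled directed nearest-boundary distances
#' in both directions (Euclidean, in pixels). Empty masks yield the image
#' diagonal as a sentinel.
#'
#' @param pred,ref binary masks of equal shape.
#' @return distance in pixels.
#' @export
asd <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("pred and ref shapes differ")
  hd95_asd_core(pred, ref)$asd
}

#' Evaluate a directory of predictions against references
#'
#' Matches cases by id (\code{<id>.png} predictions against
#' \code{<id>_mask.png} references), computes per-case DSC/PR/RC/HD95/ASD,
#' and appends mean and sd rows. Unmatched ids are listed with a warning and
#' skipped.
#'
#' @param pred_dir directory of predicted mask PNGs.
#' @param ref_dir directory of reference mask PNGs.
#' @param out_csv optional path for the CSV report.
#' @return data frame with columns case_id, DSC, PR, RC, HD95, ASD,
#'   empty_flag.
#' @export
evaluate_dataset <- function(pred_dir, ref_dir, out_csv = NULL) {
  preds <- list.files(pred_dir, pattern = "\\.png$")
  preds <- preds[!grepl("_mask\\.png$", preds)]
  ids <- sub("\\.png$", "", preds)
  refs <- file.path(ref_dir, paste0(ids, "_mask.png"))
  missing <- !file.exists(refs)
  if (any(missing)) {
    warning("no reference for: ", paste(ids[missing], collapse = ", "))
    ids <- ids[!missing]; preds <- preds[!missing]; refs <- refs[!missing]
  }
  if (length(ids) == 0L) stop("no matched prediction/reference pairs")
  rows <- lapply(seq_along(ids), function(i) {
    p <- read_mask_png(file.path(pred_dir, preds[i]))
    r <- read_mask_png(refs[i])
    cc <- confusion_counts(p, r)
    dpr <- dice_precision_recall(cc)
    hh <- hd95_asd_core(p, r)
    data.frame(case_id = ids[i], DSC = dpr[["DSC"]], PR = dpr[["PR"]],
               RC = dpr[["RC"]], HD95 = hh$hd95, ASD = hh$asd,
               empty_flag = hh$empty, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  summ <- data.frame(case_id = c("mean", "sd"),
                     DSC = c(mean(tab$DSC), sd(tab$DSC)),
                     PR = c(mean(tab$PR), sd(tab$PR)),
                     RC = c(mean(tab$RC), sd(tab$RC)),
                     HD95 = c(mean(tab$HD95), sd(tab$HD95)),
                     ASD = c(mean(tab$ASD), sd(tab$ASD)),
                     empty_flag = NA, stringsAsFactors = FALSE)
  out <- rbind(tab, summ)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
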