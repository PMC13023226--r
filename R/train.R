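#' Training configuration
#'
#' Defaults reproduce the published optimization recipe: AdamW with learning
#' rate 0.005, betas (0.9, 0.999), weight decay 3e-5, AMSGrad off; cosine
#' annealing over \code{t_max = 50} epochs down to \code{lr_min = 1e-5};
#' training batches of four images, evaluation batches of one.
#'
#' @param alpha_ema EMA coefficient \eqn{\alpha} (default 0.3).
#' @param lr initial learning rate.
#' @param adam_betas AdamW (beta1, beta2).
#' @param weight_decay decoupled weight decay.
#' @param amsgrad logical; AMSGrad variant (off).
#' @param t_max cosine annealing period in epochs.
#' @param lr_min floor of the cosine schedule.
#' @param batch_train images per optimizer step (gradient accumulation).
#' @param batch_eval images per evaluation step.
#' @param epochs training epochs.
#' @param patches_per_image tiles sampled per image per step.
#' @param ema_every blend the large branch toward the small branch every this
#'   many optimizer steps (default 1); \code{Inf} disables EMA.
#' @param global_size input size of the down-sampled global branch.
#' @param patch_size tile size of the cropped local branch.
#' @param mode \code{"cmwnet"} (both branches, EMA-coupled),
#'   \code{"downsample"} (global branch only) or \code{"crop"} (local branch
#'   only) — the two ablation baselines correspond to EMA-disabled
#'   single-branch training.
#' @param seed integer seed driving initialization, shuffling, tile sampling,
#'   augmentation and the \eqn{\beta} draws.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(alpha_ema = 0.3, lr = 0.005, adam_betas = c(0.9, 0.999),
                         weight_decay = 3e-5, amsgrad = FALSE, t_max = 50L,
                         lr_min = 1e-5, batch_train = 4L, batch_eval = 1L,
                         epochs = 30L, patches_per_image = 4L, ema_every = 1,
                         global_size = 512L, patch_size = 512L,
                         mode = c("cmwnet", "downsample", "crop"), seed = 1L) {
  if (alpha_ema < 0 || alpha_ema > 1) stop("alpha_ema must lie in [0,1]")
  structure(list(alpha_ema = alpha_ema, lr = lr, adam_betas = adam_betas,
                 weight_decay = weight_decay, amsgrad = isTRUE(amsgrad),
                 t_max = as.integer(t_max), lr_min = lr_min,
                 batch_train = as.integer(batch_train),
                 batch_eval = as.integer(batch_eval),
                 epochs = as.integer(epochs),
                 patches_per_image = as.integer(patches_per_image),
                 ema_every = ema_every,
                 global_size = as.integer(global_size),
                 patch_size = as.integer(patch_size),
                 mode = match.arg(mode), seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config()].
#' @return learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, cfg) {
  t <- min(epoch, cfg$t_max)
  cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) * (1 + cos(pi * t / cfg$t_max))
}

check_congruent <- function(a, b) {
  bad <- union(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
  if (length(bad) == 0L)
    bad <- names(a)[!mapply(function(x, y) identical(dim(x), dim(y)) &&
                              length(x) == length(y), a, b[names(a)])]
  if (length(bad) > 0L)
    stop("parameter vectors are not congruent; mismatched: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Exponential-moving-average weight exchange
#'
#' Blends the large-scale (student) branch toward the small-scale (teacher)
#' branch: \eqn{\theta_G \leftarrow (1-\alpha)\theta_G + \alpha\theta_L},
#' elementwise over congruent parameter vectors. A higher \eqn{\alpha} gives
#' more weight to the teacher's current parameters.
#'
#' @param theta_large,theta_small congruent named parameter lists.
#' @param alpha blend coefficient in \code{[0,1]}.
#' @return the updated large-branch parameter list.
#' @export
ema_update <- function(theta_large, theta_small, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0,1]")
  check_congruent(theta_large, theta_small)
  out <- theta_large
  for (nm in names(out)) out[[nm]] <- (1 - alpha) * theta_large[[nm]] + alpha * theta_small[[nm]]
  out
}

#' Deterministic k-fold split
#'
#' Partitions case ids into k near-equal disjoint folds (sizes differ by at
#' most one), reproducibly for a given seed.
#'
#' @param case_ids vector of ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k id vectors.
#' @export
kfold_split <- function(case_ids, k = 5L, seed = 1L) {
  n <- length(case_ids)
  if (k > n) stop("k exceeds the number of cases")
  perm <- with_seed(seed, sample(case_ids))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(perm, rep(seq_len(k), times = sizes))
}

#' Proportional train/validation/test split
#'
#' Emulates the published internal split (111/29/43, i.e. roughly
#' 60/16/24 percent) on an arbitrary case list, deterministically.
#'
#' @param case_ids vector of ids.
#' @param seed integer seed.
#' @param frac named fractions (train, val, test) summing to 1.
#' @return list with \code{train}, \code{val}, \code{test} id vectors.
#' @export
split_cases <- function(case_ids, seed = 1L,
                        frac = c(train = 0.60, val = 0.16, test = 0.24)) {
  n <- length(case_ids)
  perm <- with_seed(seed, sample(case_ids))
  n_tr <- max(1L, round(n * frac[["train"]]))
  n_va <- max(1L, round(n * frac[["val"]]))
  if (n_tr + n_va >= n) stop("too few cases for a three-way split")
  list(train = perm[seq_len(n_tr)],
       val = perm[(n_tr + 1L):(n_tr + n_va)],
       test = perm[(n_tr + n_va + 1L):n])
}

## ---- AdamW ---------------------------------------------------------------

adamw_new <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, vmax = zeros, t = 0L)
}

adamw_step <- function(opt, params, grads, lr, cfg) {
  b1 <- cfg$adam_betas[1]; b2 <- cfg$adam_betas[2]; eps <- 1e-8
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    vh <- opt$v[[nm]] / c2
    if (cfg$amsgrad) {
      opt$vmax[[nm]] <- pmax(opt$vmax[[nm]], vh)
      vh <- opt$vmax[[nm]]
    }
    params[[nm]] <- params[[nm]] -
      lr * ((opt$m[[nm]] / c1) / (sqrt(vh) + eps) + cfg$weight_decay * params[[nm]])
  }
  list(opt = opt, params = params)
}

## ---- batch construction --------------------------------------------------

#' Build the two-branch training batch for one case
#'
#' The global pair is the area-down-sampled image and mask; the local inputs
#' are \code{patches_per_image} distinct tiles sampled without replacement
#' from the non-overlapping grid, with paired augmentation in training mode.
#'
#' @param case list with \code{image} and \code{mask} (preprocessed, dims
#'   multiples of \code{cfg$patch_size}).
#' @param cfg a [train_config()].
#' @param seed integer seed of the tile draw and augmentation.
#' @param train apply augmentation (default TRUE).
#' @return list with global_input, global_target, patch_inputs,
#'   patch_targets, tile_idx (0-based), flips, grid.
#' @export
make_batch <- function(case, cfg, seed = 1L, train = TRUE) {
  gi <- downsample_global(case$image, cfg$global_size)
  gt <- (downsample_global(case$mask, cfg$global_size) >= 0.5) * 1
  cgi <- crop_grid(case$image, cfg$patch_size)
  cgm <- crop_grid(case$mask, cfg$patch_size)
  ntiles <- cgi$grid$rows * cgi$grid$cols
  k <- min(cfg$patches_per_image, ntiles)
  idx <- with_seed(seed, sort(sample.int(ntiles, k))) - 1L
  pin <- vector("list", k); ptg <- vector("list", k); flips <- logical(k)
  for (i in seq_len(k)) {
    img <- cgi$patches[[idx[i] + 1L]]
    msk <- cgm$patches[[idx[i] + 1L]]
    if (train) {
      aseed <- seed + 1000L + i
      aug <- augment(img, msk, seed = aseed)
      flips[i] <- with_seed(aseed, runif(1) < 0.5)  # replays augment's flip draw
      img <- aug$image; msk <- aug$mask
    }
    pin[[i]] <- img; ptg[[i]] <- (msk >= 0.5) * 1
  }
  list(global_input = gi, global_target = gt, patch_inputs = pin,
       patch_targets = ptg, tile_idx = idx, flips = flips, grid = cgi$grid)
}

## ---- one training step (loss + gradients for one case) --------------------

case_grads <- function(batch, large, small, net, tcfg, lcfg, beta) {
  alpha <- tcfg$alpha_ema
  mode <- tcfg$mode
  H <- batch$grid$source_height; W <- batch$grid$source_width
  ps <- batch$grid$patch_size
  rec <- list(L1 = NA_real_, L2 = NA_real_, L3 = NA_real_, L4 = NA_real_,
              beta = beta, total = NA_real_)
  g_large <- NULL; g_small <- NULL

  if (mode != "crop") {
    fw_g <- wunet_forward(large, net, batch$global_input, keep_cache = TRUE)
    bl_g <- branch_loss(fw_g$probs, batch$global_target, lcfg, grad = TRUE)
    rec$L1 <- bl_g$loss
  }
  if (mode != "downsample") {
    k <- length(batch$patch_inputs)
    fw_p <- vector("list", k); dL2 <- vector("list", k); l2s <- numeric(k)
    for (i in seq_len(k)) {
      fw_p[[i]] <- wunet_forward(small, net, batch$patch_inputs[[i]], keep_cache = TRUE)
      bl <- branch_loss(fw_p[[i]]$probs, batch$patch_targets[[i]], lcfg, grad = TRUE)
      l2s[i] <- bl$loss; dL2[[i]] <- bl$grad
    }
    rec$L2 <- mean(l2s)
  }

  if (mode == "cmwnet") {
    # consistency on sampled-tile footprints at source resolution
    mr <- interp_matrix_linear(tcfg$global_size, H)
    mc <- interp_matrix_linear(tcfg$global_size, W)
    gup <- mr %*% fw_g$probs %*% t(mc)
    diffsum <- matrix(0, H, W); foot <- matrix(FALSE, H, W)
    local_maps <- vector("list", length(batch$tile_idx))
    for (i in seq_along(batch$tile_idx)) {
      rc <- patch_origin(batch$grid, batch$tile_idx[i])
      pm <- fw_p[[i]]$probs
      if (batch$flips[i]) pm <- pm[, rev(seq_len(ncol(pm)))]  # undo flip for alignment
      local_maps[[i]] <- pm
      rr <- (rc[1] + 1L):(rc[1] + ps); cc <- (rc[2] + 1L):(rc[2] + ps)
      diffsum[rr, cc] <- gup[rr, cc] - pm
      foot[rr, cc] <- TRUE
    }
    nf <- sum(foot)
    rec$L4 <- sum(diffsum[foot]^2) / nf
    rec$L3 <- joint_loss(rec$L1, rec$L2, alpha)
    rec$total <- total_loss(rec$L3, rec$L4, beta)
    # gradients
    dgup <- 2 * diffsum / nf
    dglobal <- (1 - alpha) * bl_g$grad + beta * (t(mr) %*% dgup %*% mc)
    g_large <- wunet_backward(large, net, fw_g$cache, dglobal)
    kk <- length(batch$patch_inputs)
    for (i in seq_len(kk)) {
      rc <- patch_origin(batch$grid, batch$tile_idx[i])
      rr <- (rc[1] + 1L):(rc[1] + ps); cc <- (rc[2] + 1L):(rc[2] + ps)
      dcons <- -dgup[rr, cc]
      if (batch$flips[i]) dcons <- dcons[, rev(seq_len(ncol(dcons)))]
      dlocal <- alpha * dL2[[i]] / kk + beta * dcons
      gi <- wunet_backward(small, net, fw_p[[i]]$cache, dlocal)
      g_small <- if (is.null(g_small)) gi else add_grads(g_small, gi)
    }
  } else if (mode == "downsample") {
    rec$L3 <- rec$total <- rec$L1
    g_large <- wunet_backward(large, net, fw_g$cache, bl_g$grad)
  } else {
    rec$L3 <- rec$total <- rec$L2
    kk <- length(batch$patch_inputs)
    for (i in seq_len(kk)) {
      gi <- wunet_backward(small, net, fw_p[[i]]$cache, dL2[[i]] / kk)
      g_small <- if (is.null(g_small)) gi else add_grads(g_small, gi)
    }
  }
  if (!is.finite(rec$total))
    stop("non-finite loss (L1=", rec$L1, ", L2=", rec$L2, ", L4=", rec$L4, ")")
  list(rec = rec, g_large = g_large, g_small = g_small)
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(a, s) lapply(a, function(x) x * s)

#' Fit the collaborative multiscale wavelet network
#'
#' Trains the large-scale (down-sampled, student) and small-scale (cropped,
#' teacher) UNet-Wavelet branches jointly: both branches receive gradients
#' from the total objective \eqn{(1-\alpha)L_1 + \alpha L_2 + \beta L_4},
#' and after each optimizer step the large branch is additionally blended
#' toward the small branch by [ema_update()]. Validation Dice selects the
#' best epoch. Ablation modes train a single branch without EMA.
#'
#' @param cases training cases: a list of \code{list(image, mask)} rasters
#'   (already preprocessed to multiples of \code{train$patch_size}), or a
#'   manifest data frame with \code{path}/\code{mask_path} columns.
#' @param val_cases validation cases in the same format (may be \code{NULL};
#'   the last training epoch is then kept).
#' @param net a [wunet_config()].
#' @param train a [train_config()].
#' @param loss a [loss_config()]; its \code{alpha_ema} is taken from
#'   \code{train}.
#' @param preprocess run [preprocess_case()] on loaded manifests (default
#'   TRUE for manifests, ignored for in-memory cases).
#' @param verbose print per-epoch progress.
#' @return an object of class \code{cmwnet}: parameter lists of both
#'   branches, configs, the per-epoch training log, and the best validation
#'   Dice.
#' @export
cmwnet <- function(cases, val_cases = NULL, net = wunet_config(),
                   train = train_config(), loss = NULL,
                   preprocess = TRUE, verbose = FALSE) {
  cl <- match.call()
  tcfg <- train
  if (is.null(loss)) loss <- loss_config(alpha_ema = tcfg$alpha_ema)
  lcfg <- loss
  cases <- load_cases(cases, tcfg, preprocess)
  if (length(cases) == 0L) stop("empty training set")
  val <- if (!is.null(val_cases)) load_cases(val_cases, tcfg, preprocess) else NULL

  large <- wunet_init(net, seed = tcfg$seed)
  small <- large                      # shared seeded initialization
  opt_l <- adamw_new(large); opt_s <- adamw_new(small)
  log <- list(); best <- list(dsc = -Inf, large = large, small = small, epoch = 0L)
  step_ct <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    lr_e <- cosine_lr(epoch - 1L, tcfg)
    ord <- with_seed(tcfg$seed + 7919L * epoch, sample.int(length(cases)))
    comps <- c(L1 = 0, L2 = 0, L3 = 0, L4 = 0, total = 0); nrec <- 0L
    b0 <- seq(1L, length(ord), by = tcfg$batch_train)
    for (bi in seq_along(b0)) {
      sel <- ord[b0[bi]:min(length(ord), b0[bi] + tcfg$batch_train - 1L)]
      acc_l <- NULL; acc_s <- NULL
      beta <- with_seed(lcfg$beta_rng_seed + step_ct, runif(1))
      for (ci in sel) {
        bseed <- tcfg$seed + 100003L * epoch + 17L * ci
        batch <- make_batch(cases[[ci]], tcfg, seed = bseed, train = TRUE)
        cg <- case_grads(batch, large, small, net, tcfg, lcfg, beta)
        for (nm in names(comps))
          if (is.finite(cg$rec[[nm]])) comps[nm] <- comps[nm] + cg$rec[[nm]]
        nrec <- nrec + 1L
        if (!is.null(cg$g_large)) acc_l <- if (is.null(acc_l)) cg$g_large else add_grads(acc_l, cg$g_large)
        if (!is.null(cg$g_small)) acc_s <- if (is.null(acc_s)) cg$g_small else add_grads(acc_s, cg$g_small)
      }
      if (!is.null(acc_l)) {
        st <- adamw_step(opt_l, large, scale_grads(acc_l, 1 / length(sel)), lr_e, tcfg)
        opt_l <- st$opt; large <- st$params
      }
      if (!is.null(acc_s)) {
        st <- adamw_step(opt_s, small, scale_grads(acc_s, 1 / length(sel)), lr_e, tcfg)
        opt_s <- st$opt; small <- st$params
      }
      step_ct <- step_ct + 1L
      if (tcfg$mode == "cmwnet" && is.finite(tcfg$ema_every) &&
          step_ct %% tcfg$ema_every == 0)
        large <- ema_update(large, small, tcfg$alpha_ema)
    }
    val_dsc <- if (!is.null(val)) mean(vapply(val, function(cs)
      eval_case_dsc(cs, large, small, net, tcfg), numeric(1))) else NA_real_
    log[[epoch]] <- data.frame(epoch = epoch, lr = lr_e,
                               t(comps / max(1L, nrec)), val_dsc = val_dsc)
    if (verbose)
      message(sprintf("epoch %d  lr %.5f  loss %.4f  val DSC %s", epoch, lr_e,
                      comps[["total"]] / max(1L, nrec),
                      ifelse(is.na(val_dsc), "-", sprintf("%.4f", val_dsc))))
    if (is.na(val_dsc) || val_dsc >= best$dsc) {
      best <- list(dsc = ifelse(is.na(val_dsc), -Inf, val_dsc),
                   large = large, small = small, epoch = epoch)
    }
  }
  structure(list(large = best$large, small = best$small, net = net,
                 train = tcfg, loss = lcfg,
                 log = do.call(rbind, log), best_epoch = best$epoch,
                 val_dsc = if (is.null(val)) NA_real_ else best$dsc,
                 call = cl),
            class = "cmwnet")
}

# Validation Dice of one case under the configured mode's inference path.
eval_case_dsc <- function(case, large, small, net, tcfg) {
  pred <- infer_mask(case$image, large, small, net, tcfg)
  dice_precision_recall(confusion_counts(pred, case$mask))[["DSC"]]
}

infer_mask <- function(image, large, small, net, tcfg, ...) {
  d <- dim(as_raster3(image))
  if (tcfg$mode == "downsample") {
    gp <- wunet_forward(large, net, downsample_global(image, tcfg$global_size))$probs
    binarize(resize_bilinear(gp, d[1], d[2]))
  } else if (tcfg$mode == "crop") {
    cg <- crop_grid(image, tcfg$patch_size)
    tp <- lapply(cg$patches, function(p) wunet_forward(small, net, p)$probs)
    binarize(montage(tp, cg$grid))
  } else {
    predict_case(image, large, small, net, tcfg$global_size, tcfg$patch_size, ...)$mask
  }
}

load_cases <- function(cases, tcfg, preprocess = TRUE) {
  if (is.data.frame(cases)) {
    out <- lapply(seq_len(nrow(cases)), function(i) {
      img <- read_image_png(cases$path[i])
      msk <- read_mask_png(cases$mask_path[i])
      if (preprocess) {
        pp <- preprocess_case(img, msk, base = tcfg$patch_size)
        list(image = pp$image, mask = pp$mask)
      } else list(image = img, mask = msk)
    })
    return(out)
  }
  lapply(cases, function(cs) list(image = cs$image, mask = cs$mask))
}

#' Save / load a fitted model
#'
#' The checkpoint is a single serialized archive; the network configuration
#' is additionally written as a JSON sidecar when jsonlite is installed.
#'
#' @param object a fitted \code{cmwnet} object.
#' @param path checkpoint path (e.g. \code{"runs/exp1/best.rds"}).
#' @return \code{path}, invisibly (for \code{save_cmwnet});
#'   the restored object (for \code{load_cmwnet}).
#' @export
save_cmwnet <- function(object, path) {
  stopifnot(inherits(object, "cmwnet"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(object, path)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(unclass(object$net), paste0(path, ".json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_cmwnet
#' @export
load_cmwnet <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "cmwnet"))
  obj
}
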