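#' Configure a UNet-Wavelet backbone
#'
#' The backbone is a symmetric encoder--decoder U-Net in which forward and
#' inverse Haar wavelet transforms replace pooling and unpooling. Each encoder
#' stage applies two 3x3 convolutions (each followed by group normalization
#' and ReLU) and then a single-level 2D DWT whose four subbands, stacked along
#' channels, feed the next stage. After \code{depth} DWT stages a bottleneck
#' double-convolution block (without DWT) processes the coarsest features.
#' Each decoder stage projects channels with a 1x1 convolution, up-samples by
#' an inverse DWT with zero-filled detail subbands, adds the stored encoder
#' feature map of the matching stage, and applies another double-convolution
#' block. A final 1x1 convolution and sigmoid produce a probability map.
#'
#' @param in_channels number of input channels (1 for grayscale).
#' @param out_channels number of output channels; 1 for binary leakage.
#' @param base_channels channels of the first stage; doubled at each stage.
#' @param depth number of DWT down-sampling stages (default 4, so with the
#'   bottleneck the double-convolution unit is applied five times).
#' @param wavelet mother wavelet; only \code{"haar"} is supported.
#' @param norm_groups target group count for group normalization; reduced per
#'   layer to the largest divisor of the channel count not exceeding it.
#' @param input_size spatial side length the network expects; must be
#'   divisible by \code{2^depth}.
#' @param skip_subbands if \code{TRUE}, the decoder re-injects the encoder's
#'   detail subbands into the inverse DWT instead of zero-filling them
#'   (alternative wiring; off by default).
#' @return an object of class \code{wunet_config}.
#' @export
wunet_config <- function(in_channels = 1L, out_channels = 1L, base_channels = 16L,
                         depth = 4L, wavelet = "haar", norm_groups = 8L,
                         input_size = 512L, skip_subbands = FALSE) {
  if (!identical(wavelet, "haar")) stop("only the Haar wavelet is supported")
  if (input_size %% (2^depth) != 0L)
    stop("input_size must be divisible by 2^depth = ", 2^depth)
  if (depth < 1L || base_channels < 1L) stop("depth and base_channels must be >= 1")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), wavelet = wavelet,
                 norm_groups = as.integer(norm_groups),
                 input_size = as.integer(input_size),
                 skip_subbands = isTRUE(skip_subbands)),
            class = "wunet_config")
}

# Largest divisor of n_channels that does not exceed the requested group count.
eff_groups <- function(n_channels, groups) {
  g <- min(groups, n_channels)
  while (n_channels %% g != 0L) g <- g - 1L
  g
}

stage_channels <- function(cfg) c(cfg$base_channels * 2^(0:(cfg$depth - 1)),
                                  cfg$base_channels * 2^cfg$depth)

he_conv <- function(cin, cout, k2 = 9L) {
  matrix(rnorm(cout * cin * k2, sd = sqrt(2 / (cin * k2))), cout, cin * k2)
}

init_double_conv <- function(cin, cmid) {
  list(w1 = he_conv(cin, cmid), b1 = numeric(cmid),
       g1 = rep(1, cmid), be1 = numeric(cmid),
       w2 = he_conv(cmid, cmid), b2 = numeric(cmid),
       g2 = rep(1, cmid), be2 = numeric(cmid))
}

#' Initialize UNet-Wavelet parameters
#'
#' He-initialized weights, unit group-norm scales, zero biases. The returned
#' named list of arrays is the flat parameter vector that EMA blending and the
#' optimizer operate on.
#'
#' @param cfg a [wunet_config()].
#' @param seed integer seed for the weight draw.
#' @return named list of parameter arrays.
#' @export
wunet_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    ch <- stage_channels(cfg)
    p <- list()
    cin <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      dc <- init_double_conv(cin, ch[i])
      names(dc) <- paste0("enc", i, ".", names(dc))
      p <- c(p, dc)
      cin <- 4L * ch[i]  # four subbands stacked along channels
    }
    bot <- init_double_conv(cin, ch[cfg$depth + 1L])
    names(bot) <- paste0("bot.", names(bot))
    p <- c(p, bot)
    for (j in rev(seq_len(cfg$depth))) {
      cup <- if (j == cfg$depth) ch[cfg$depth + 1L] else ch[j + 1L]
      proj <- list(w = matrix(rnorm(ch[j] * cup, sd = sqrt(2 / cup)), ch[j], cup),
                   b = numeric(ch[j]))
      names(proj) <- paste0("dec", j, ".proj.", names(proj))
      dc <- init_double_conv(ch[j], ch[j])
      names(dc) <- paste0("dec", j, ".", names(dc))
      p <- c(p, proj, dc)
    }
    p[["head.w"]] <- matrix(rnorm(cfg$out_channels * ch[1],
                                  sd = sqrt(2 / ch[1])), cfg$out_channels, ch[1])
    p[["head.b"]] <- numeric(cfg$out_channels)
    p
  })
}

#' Count trainable parameters
#' @param params a parameter list from [wunet_init()].
#' @return integer count of scalar parameters.
#' @export
wunet_n_params <- function(params) sum(vapply(params, length, integer(1)))

double_conv_fwd <- function(x, p, prefix, groups) {
  w1 <- p[[paste0(prefix, ".w1")]]
  y1 <- conv3x3(x, w1, p[[paste0(prefix, ".b1")]])
  g <- eff_groups(dim(y1)[3], groups)
  gn1 <- group_norm(y1, p[[paste0(prefix, ".g1")]], p[[paste0(prefix, ".be1")]], g)
  r1 <- relu(gn1$y)
  y2 <- conv3x3(r1, p[[paste0(prefix, ".w2")]], p[[paste0(prefix, ".b2")]])
  gn2 <- group_norm(y2, p[[paste0(prefix, ".g2")]], p[[paste0(prefix, ".be2")]], g)
  r2 <- relu(gn2$y)
  list(out = r2, x = x, gn1 = gn1, gn2 = gn2, r1 = r1)
}

double_conv_bwd <- function(dout, cache, p, prefix, grads) {
  dgn2y <- dout * (cache$gn2$y > 0)
  gb2 <- group_norm_bwd(dgn2y, cache$gn2, p[[paste0(prefix, ".g2")]])
  cb2 <- conv3x3_bwd(cache$r1, gb2$dx, p[[paste0(prefix, ".w2")]])
  dgn1y <- cb2$dx * (cache$gn1$y > 0)
  gb1 <- group_norm_bwd(dgn1y, cache$gn1, p[[paste0(prefix, ".g1")]])
  cb1 <- conv3x3_bwd(cache$x, gb1$dx, p[[paste0(prefix, ".w1")]])
  grads[[paste0(prefix, ".w2")]] <- cb2$dw
  grads[[paste0(prefix, ".b2")]] <- cb2$db
  grads[[paste0(prefix, ".g2")]] <- gb2$dgamma
  grads[[paste0(prefix, ".be2")]] <- gb2$dbeta
  grads[[paste0(prefix, ".w1")]] <- cb1$dw
  grads[[paste0(prefix, ".b1")]] <- cb1$db
  grads[[paste0(prefix, ".g1")]] <- gb1$dgamma
  grads[[paste0(prefix, ".be1")]] <- gb1$dbeta
  list(dx = cb1$dx, grads = grads)
}

# Inverse DWT receiving only an approximation band (detail subbands zero).
idwt_ll <- function(LL) {
  d <- dim(LL)
  out <- array(0, dim = c(2L * d[1], 2L * d[2], d[3]))
  ro <- seq(1L, 2L * d[1], 2L); co <- seq(1L, 2L * d[2], 2L)
  half <- LL / 2
  out[ro, co, ] <- half; out[ro, co + 1L, ] <- half
  out[ro + 1L, co, ] <- half; out[ro + 1L, co + 1L, ] <- half
  out
}

idwt_ll_bwd <- function(dout) {
  d <- dim(dout)
  ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  (dout[ro, co, , drop = FALSE] + dout[ro, co + 1L, , drop = FALSE] +
     dout[ro + 1L, co, , drop = FALSE] + dout[ro + 1L, co + 1L, , drop = FALSE]) / 2
}

#' Forward pass of the UNet-Wavelet
#'
#' @param params parameter list from [wunet_init()].
#' @param cfg the matching [wunet_config()].
#' @param x input raster: (H, W) matrix or (H, W, C) array with H = W =
#'   \code{cfg$input_size} (any size divisible by \code{2^depth} is accepted;
#'   the network is fully convolutional).
#' @param keep_cache keep intermediate activations for [wunet_backward()].
#' @return list with \code{probs}, the (H, W) probability map in \code{[0,1]},
#'   and (if requested) \code{cache}.
#' @export
wunet_forward <- function(params, cfg, x, keep_cache = FALSE) {
  x3 <- as_raster3(x)
  d <- dim(x3)
  if (d[1] %% 2^cfg$depth != 0L || d[2] %% 2^cfg$depth != 0L)
    stop("input spatial dims must be divisible by 2^depth = ", 2^cfg$depth)
  if (d[3] != cfg$in_channels) stop("input has ", d[3], " channels, config expects ", cfg$in_channels)
  caches <- list(); skips <- list(); skip_sb <- list()
  cur <- x3
  for (i in seq_len(cfg$depth)) {
    dc <- double_conv_fwd(cur, params, paste0("enc", i), cfg$norm_groups)
    skips[[i]] <- dc$out
    sb <- dwt2_forward(dc$out)
    skip_sb[[i]] <- sb
    cur <- subbands_to_channels(sb)
    caches[[paste0("enc", i)]] <- dc
  }
  bot <- double_conv_fwd(cur, params, "bot", cfg$norm_groups)
  caches[["bot"]] <- bot
  up <- bot$out
  for (j in rev(seq_len(cfg$depth))) {
    prj <- conv1x1(up, params[[paste0("dec", j, ".proj.w")]],
                   params[[paste0("dec", j, ".proj.b")]])
    caches[[paste0("dec", j, ".projin")]] <- up
    if (cfg$skip_subbands) {
      u <- as_raster3(dwt2_inverse(list(LL = prj,
                                        LH = as_raster3(skip_sb[[j]]$LH),
                                        HL = as_raster3(skip_sb[[j]]$HL),
                                        HH = as_raster3(skip_sb[[j]]$HH))))
    } else {
      u <- idwt_ll(prj)
    }
    u <- u + skips[[j]]
    dc <- double_conv_fwd(u, params, paste0("dec", j), cfg$norm_groups)
    caches[[paste0("dec", j)]] <- dc
    up <- dc$out
  }
  caches[["headin"]] <- up
  z <- conv1x1(up, params[["head.w"]], params[["head.b"]])
  probs <- sigmoid(z)
  out <- list(probs = if (cfg$out_channels == 1L) probs[, , 1] else probs)
  if (keep_cache) {
    caches[["probs"]] <- probs
    out$cache <- caches
  }
  out
}

#' Backward pass of the UNet-Wavelet
#'
#' Computes gradients of a scalar loss with respect to every parameter, given
#' the gradient of the loss with respect to the output probability map.
#'
#' @param params parameter list.
#' @param cfg the [wunet_config()].
#' @param cache the cache returned by \code{wunet_forward(..., keep_cache = TRUE)}.
#' @param dprobs gradient w.r.t. the probability map (same shape).
#' @return named list of gradients congruent with \code{params}.
#' @export
wunet_backward <- function(params, cfg, cache, dprobs) {
  probs <- cache[["probs"]]
  dp3 <- as_raster3(dprobs)
  dz <- dp3 * probs * (1 - probs)            # through the sigmoid
  grads <- list()
  hb <- conv1x1_bwd(cache[["headin"]], dz, params[["head.w"]])
  grads[["head.w"]] <- hb$dw; grads[["head.b"]] <- hb$db
  dup <- hb$dx
  for (j in seq_len(cfg$depth)) {
    db <- double_conv_bwd(dup, cache[[paste0("dec", j)]], params, paste0("dec", j), grads)
    grads <- db$grads
    du <- db$dx                               # gradient at (idwt + skip) output
    dskip <- du                               # additive skip into encoder feature
    if (cfg$skip_subbands) {
      sb <- dwt2_forward(du)     # adjoint of the orthonormal synthesis
      dprj <- as_raster3(sb$LL)
      dsb_detail <- sb           # detail gradients flow to the encoder subbands
    } else {
      dprj <- idwt_ll_bwd(du)
      dsb_detail <- NULL
    }
    pb <- conv1x1_bwd(cache[[paste0("dec", j, ".projin")]], dprj,
                      params[[paste0("dec", j, ".proj.w")]])
    grads[[paste0("dec", j, ".proj.w")]] <- pb$dw
    grads[[paste0("dec", j, ".proj.b")]] <- pb$db
    dup <- pb$dx
    # stash the skip gradient for the encoder sweep
    cache[[paste0("dskip", j)]] <- dskip
    if (!is.null(dsb_detail)) cache[[paste0("ddetail", j)]] <- dsb_detail
  }
  # bottleneck
  bb <- double_conv_bwd(dup, cache[["bot"]], params, "bot", grads)
  grads <- bb$grads
  dcur <- bb$dx
  for (i in rev(seq_len(cfg$depth))) {
    # dcur is gradient w.r.t. the channel-stacked subbands of stage i
    sb <- channels_to_subbands(dcur)
    if (cfg$skip_subbands && !is.null(cache[[paste0("ddetail", i)]])) {
      dd <- cache[[paste0("ddetail", i)]]
      sb$LH <- sb$LH + as_raster3(dd$LH)
      sb$HL <- sb$HL + as_raster3(dd$HL)
      sb$HH <- sb$HH + as_raster3(dd$HH)
    }
    dF <- as_raster3(dwt2_inverse(sb))        # adjoint of the orthonormal DWT
    dF <- dF + cache[[paste0("dskip", i)]]
    eb <- double_conv_bwd(dF, cache[[paste0("enc", i)]], params, paste0("enc", i), grads)
    grads <- eb$grads
    dcur <- eb$dx
  }
  grads
}
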