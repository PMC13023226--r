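## Network layers with hand-written backward passes. Activations are (H, W, C)
## arrays; conv weights are (Cout x Cin*9) matrices (column index
## c*9 + kr*3 + kc, 0-based) so the compiled im2col/GEMM kernels apply them
## directly.

conv3x3 <- function(x, w, b) conv3x3_fwd(x, w, as.numeric(b))

conv3x3_bwd <- function(x, dy, w) {
  g <- conv3x3_bwd_wb(x, dy)
  list(dx = conv3x3_bwd_input(dy, w), dw = g$dw, db = as.numeric(g$db))
}

conv1x1 <- function(x, w, b) {
  # w: (Cout x Cin)
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  ym <- xm %*% t(w)
  ym <- sweep(ym, 2, b, "+")
  array(ym, dim = c(d[1], d[2], nrow(w)))
}

conv1x1_bwd <- function(x, dy, w) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  dym <- matrix(dy, d[1] * d[2], nrow(w))
  list(dx = array(dym %*% w, dim = d),
       dw = t(dym) %*% xm,
       db = colSums(dym))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Group normalization over (H, W, channels-in-group), per sample.
group_norm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  if (d[3] %% groups != 0L) stop("channel count not divisible by norm groups")
  cg <- d[3] / groups
  xhat <- array(0, dim = d)
  ivar <- numeric(groups)
  for (g in seq_len(groups)) {
    ch <- ((g - 1) * cg + 1):(g * cg)
    v <- x[, , ch, drop = FALSE]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    ivar[g] <- 1 / sqrt(va + eps)
    xhat[, , ch] <- (v - mu) * ivar[g]
  }
  y <- xhat
  for (c in seq_len(d[3])) y[, , c] <- gamma[c] * xhat[, , c] + beta[c]
  list(y = y, xhat = xhat, ivar = ivar, groups = groups)
}

group_norm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  d <- dim(xhat)
  groups <- cache$groups
  cg <- d[3] / groups
  dgamma <- numeric(d[3]); dbeta <- numeric(d[3])
  dxhat <- array(0, dim = d)
  for (c in seq_len(d[3])) {
    dgamma[c] <- sum(dy[, , c] * xhat[, , c])
    dbeta[c] <- sum(dy[, , c])
    dxhat[, , c] <- dy[, , c] * gamma[c]
  }
  dx <- array(0, dim = d)
  for (g in seq_len(groups)) {
    ch <- ((g - 1) * cg + 1):(g * cg)
    dxh <- dxhat[, , ch, drop = FALSE]
    xh <- xhat[, , ch, drop = FALSE]
    m1 <- mean(dxh)
    m2 <- mean(dxh * xh)
    dx[, , ch] <- cache$ivar[g] * (dxh - m1 - xh * m2)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}
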