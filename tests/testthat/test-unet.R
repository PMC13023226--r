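test_that("forward pass honors the output contract", {
  cfg <- tiny_net()
  p <- wunet_init(cfg, seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  out1 <- wunet_forward(p, cfg, x)$probs
  expect_equal(dim(out1), c(64, 64))
  expect_true(all(out1 >= 0 & out1 <= 1))
  # deterministic: identical weights and input give bit-identical output
  out2 <- wunet_forward(p, cfg, x)$probs
  expect_identical(out1, out2)
  expect_error(wunet_forward(p, cfg, matrix(0, 30, 30)), "divisible")
})

test_that("encoder stages halve resolution and double channels as configured", {
  cfg <- wunet_config(base_channels = 4, depth = 3, input_size = 32, norm_groups = 4)
  p <- wunet_init(cfg, seed = 1)
  x <- matrix(runif(32 * 32), 32, 32)
  fw <- wunet_forward(p, cfg, x, keep_cache = TRUE)
  for (i in 1:3) {
    f <- fw$cache[[paste0("enc", i)]]$out
    expect_equal(dim(f)[1:2], c(32, 32) / 2^(i - 1))
    expect_equal(dim(f)[3], 4 * 2^(i - 1))
  }
  # decoder shape chain mirrors the encoder in reverse, ending at input size
  for (j in 1:3) {
    u <- fw$cache[[paste0("dec", j)]]$out
    expect_equal(dim(u)[1:2], c(32, 32) / 2^(j - 1))
  }
})

test_that("parameter count is the closed-form function of the configuration", {
  cfg <- wunet_config(base_channels = 16, depth = 4, input_size = 512)
  p <- wunet_init(cfg, seed = 1)
  ch <- 16 * 2^(0:4)
  dconv <- function(cin, cout) (cin * cout * 9 + cout) + (cout * cout * 9 + cout) + 4 * cout
  expected <- 0
  cin <- 1
  for (i in 1:4) { expected <- expected + dconv(cin, ch[i]); cin <- 4 * ch[i] }
  expected <- expected + dconv(cin, ch[5])
  for (j in 4:1) {
    cup <- if (j == 4) ch[5] else ch[j + 1]
    expected <- expected + (cup * ch[j] + ch[j]) + dconv(ch[j], ch[j])
  }
  expected <- expected + (16 + 1)
  expect_identical(wunet_n_params(p), as.integer(expected))
})

test_that("analytic gradients match finite differences through the whole net", {
  cfg <- tiny_net()
  p <- wunet_init(cfg, seed = 3)
  set.seed(7)
  x <- matrix(runif(64 * 64), 64, 64)
  g <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  lcfg <- loss_config()
  fw <- wunet_forward(p, cfg, x, keep_cache = TRUE)
  bl <- branch_loss(fw$probs, g, lcfg, grad = TRUE)
  grads <- wunet_backward(p, cfg, fw$cache, bl$grad)
  lossfn <- function(pp) branch_loss(wunet_forward(pp, cfg, x)$probs, g, lcfg)
  for (nm in c("enc1.w1", "enc2.g2", "bot.w2", "dec2.proj.w", "dec1.w1", "head.w")) {
    for (i in seq_len(min(2L, length(p[[nm]])))) {
      e1 <- p; e1[[nm]][i] <- e1[[nm]][i] + 1e-6
      e2 <- p; e2[[nm]][i] <- e2[[nm]][i] - 1e-6
      num <- (lossfn(e1) - lossfn(e2)) / 2e-6
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("the network is translation-covariant for dyadic shifts", {
  # depth 2: covariant for shifts by multiples of 4, away from borders
  cfg <- wunet_config(base_channels = 4, depth = 2, input_size = 128,
                      norm_groups = 4)
  p <- wunet_init(cfg, seed = 5)
  set.seed(9)
  big <- smooth_raster(matrix(runif(140 * 140), 140, 140))
  xa <- big[1:128, 1:128]
  xb <- big[5:132, 5:132]   # shift by (4, 4) = 2^depth
  ya <- wunet_forward(p, cfg, xa)$probs
  yb <- wunet_forward(p, cfg, xb)$probs
  inner <- 25:100           # interior beyond the receptive-field border band
  expect_gt(cor(as.vector(ya[inner + 4, inner + 4]), as.vector(yb[inner, inner])), 0.99)
})

test_that("alternative subband-carrying skips also reconstruct shapes and gradients", {
  cfg <- wunet_config(base_channels = 4, depth = 2, input_size = 16,
                      norm_groups = 4, skip_subbands = TRUE)
  p <- wunet_init(cfg, seed = 3)
  set.seed(11)
  x <- matrix(runif(256), 16, 16)
  g <- matrix(rbinom(256, 1, 0.4), 16, 16)
  fw <- wunet_forward(p, cfg, x, keep_cache = TRUE)
  expect_equal(dim(fw$probs), c(16, 16))
  bl <- branch_loss(fw$probs, g, grad = TRUE)
  grads <- wunet_backward(p, cfg, fw$cache, bl$grad)
  lossfn <- function(pp) branch_loss(wunet_forward(pp, cfg, x)$probs, g)
  for (nm in c("enc1.w1", "dec1.proj.w")) {
    e1 <- p; e1[[nm]][1] <- e1[[nm]][1] + 1e-6
    e2 <- p; e2[[nm]][1] <- e2[[nm]][1] - 1e-6
    expect_equal(grads[[nm]][1], (lossfn(e1) - lossfn(e2)) / 2e-6, tolerance = 1e-4)
  }
})
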