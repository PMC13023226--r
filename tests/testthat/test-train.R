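test_that("EMA blending follows the closed-form geometric decay", {
  cfg <- tiny_net()
  large0 <- wunet_init(cfg, seed = 1)
  small <- wunet_init(cfg, seed = 2)
  for (alpha in c(0.1, 0.3, 0.5, 0.9)) {
    large <- large0
    for (k in 1:10) {
      large <- ema_update(large, small, alpha)
      for (nm in c("enc1.w1", "head.w")) {
        expected <- (1 - alpha)^k * large0[[nm]] + (1 - (1 - alpha)^k) * small[[nm]]
        expect_equal(large[[nm]], expected, tolerance = 1e-10)
      }
    }
  }
})

test_that("EMA endpoints and congruence checks behave", {
  a <- list(w = matrix(1, 2, 2), b = c(0.5, 0.5))
  b <- list(w = matrix(0, 2, 2), b = c(1, 1))
  expect_identical(ema_update(a, b, 0), a)
  expect_equal(ema_update(a, b, 1), b)
  expect_equal(ema_update(list(x = 1), list(x = 0), 0.3)$x, 0.7)
  expect_error(ema_update(a, list(w = matrix(0, 2, 2)), 0.5), "congruent.*b")
  # distance to a frozen teacher is non-increasing
  d_old <- Inf
  cur <- a
  for (k in 1:5) {
    cur <- ema_update(cur, b, 0.3)
    d <- sqrt(sum((cur$w - b$w)^2) + sum((cur$b - b$b)^2))
    expect_lte(d, d_old)
    d_old <- d
  }
})

test_that("k-fold splits are deterministic, disjoint and near-equal", {
  ids <- sprintf("c%03d", 1:111)
  f1 <- kfold_split(ids, k = 5, seed = 42)
  f2 <- kfold_split(ids, k = 5, seed = 42)
  expect_identical(f1, f2)
  expect_equal(unname(sort(vapply(f1, length, integer(1)), decreasing = TRUE)),
               c(23L, 22L, 22L, 22L, 22L))
  expect_setequal(unlist(f1), ids)
  expect_equal(anyDuplicated(unlist(f1)), 0)
  expect_error(kfold_split(1:3, k = 5), "exceeds")
})

test_that("proportional splitting emulates the 60/16/24 partition", {
  sp <- split_cases(1:10, seed = 3)
  expect_equal(lengths(sp), c(train = 6L, val = 2L, test = 2L))
  expect_setequal(unlist(sp), 1:10)
})

test_that("the cosine schedule hits the published endpoints", {
  cfg <- train_config()
  expect_equal(cosine_lr(0, cfg), 0.005)
  expect_equal(cosine_lr(50, cfg), 0.00001)
  expect_gt(cosine_lr(10, cfg), cosine_lr(40, cfg))
})

test_that("batches sample distinct disjoint tiles and an empty mask yields an empty target", {
  cases <- tiny_cases(1, size = 128, seed = 301)
  tcfg <- tiny_train()
  for (s in 1:20) {
    b <- make_batch(cases[[1]], tcfg, seed = s)
    expect_equal(length(b$patch_inputs), 2)
    expect_equal(anyDuplicated(b$tile_idx), 0)
    # footprints are disjoint by grid construction
    origins <- t(vapply(b$tile_idx, function(j)
      cmwnet:::patch_origin(b$grid, j), numeric(2)))
    expect_equal(anyDuplicated(origins), 0)
  }
  empty <- list(image = cases[[1]]$image, mask = cases[[1]]$mask * 0)
  be <- make_batch(empty, tcfg, seed = 1)
  expect_true(all(be$global_target == 0))
  # more requested than available: all tiles returned
  tall <- train_config(global_size = 64, patch_size = 64, patches_per_image = 99)
  expect_equal(length(make_batch(cases[[1]], tall, seed = 1)$patch_inputs), 4)
})

test_that("with beta = 0, branch gradients flow only through their own loss", {
  cases <- tiny_cases(1, size = 128, seed = 307)
  net <- tiny_net()
  lcfg <- loss_config()
  large <- wunet_init(net, seed = 1); small <- wunet_init(net, seed = 1)
  tcfg0 <- tiny_train(alpha_ema = 0)
  b <- make_batch(cases[[1]], tcfg0, seed = 5)
  cg <- cmwnet:::case_grads(b, large, small, net, tcfg0, lcfg, beta = 0)
  # alpha = 0: the small branch receives no gradient at all
  expect_true(all(vapply(cg$g_small, function(g) max(abs(g)), numeric(1)) < 1e-14))
  expect_gt(max(abs(cg$g_large[["enc1.w1"]])), 0)
  tcfg1 <- tiny_train(alpha_ema = 1)
  cg1 <- cmwnet:::case_grads(b, large, small, net, tcfg1, lcfg, beta = 0)
  expect_true(all(vapply(cg1$g_large, function(g) max(abs(g)), numeric(1)) < 1e-14))
  expect_gt(max(abs(cg1$g_small[["enc1.w1"]])), 0)
  # loss record is complete and finite
  expect_true(all(is.finite(unlist(cg$rec))))
})

test_that("two seeded runs produce identical loss records and predictions", {
  cases <- tiny_cases(3, size = 128, seed = 311)
  net <- tiny_net()
  run <- function() cmwnet(cases[1:2], val_cases = cases[3], net = net,
                           train = tiny_train(epochs = 2, seed = 99),
                           preprocess = FALSE)
  f1 <- run(); f2 <- run()
  expect_identical(f1$log, f2$log)
  p1 <- predict(f1, cases[[3]]$image)
  p2 <- predict(f2, cases[[3]]$image)
  expect_identical(p1, p2)
})

test_that("checkpoints reload to the identical validation Dice", {
  cases <- tiny_cases(3, size = 128, seed = 313)
  fit <- cmwnet(cases[1:2], val_cases = cases[3], net = tiny_net(),
                train = tiny_train(epochs = 1, seed = 7), preprocess = FALSE)
  td <- withr::local_tempdir()
  save_cmwnet(fit, file.path(td, "best.rds"))
  back <- load_cmwnet(file.path(td, "best.rds"))
  expect_identical(coef(back), coef(fit))
  dsc0 <- cmwnet:::eval_case_dsc(cases[[3]], fit$large, fit$small, fit$net, fit$train)
  dsc1 <- cmwnet:::eval_case_dsc(cases[[3]], back$large, back$small, back$net, back$train)
  expect_identical(dsc0, dsc1)
})

test_that("single-branch ablation modes train only their own branch", {
  cases <- tiny_cases(2, size = 128, seed = 317)
  net <- tiny_net()
  fit_ds <- cmwnet(cases, net = net,
                   train = tiny_train(epochs = 1, seed = 5, mode = "downsample"),
                   preprocess = FALSE)
  init <- wunet_init(net, seed = 5)
  expect_identical(fit_ds$small, init)            # teacher untouched
  expect_false(identical(fit_ds$large, init))     # student trained
  fit_cr <- cmwnet(cases, net = net,
                   train = tiny_train(epochs = 1, seed = 5, mode = "crop"),
                   preprocess = FALSE)
  expect_identical(fit_cr$large, init)
  expect_false(identical(fit_cr$small, init))
})

test_that("model printing and coefficient access work", {
  cases <- tiny_cases(2, size = 128, seed = 331)
  fit <- cmwnet(cases, net = tiny_net(), train = tiny_train(epochs = 1, seed = 3),
                preprocess = FALSE)
  expect_output(print(fit), "Collaborative multiscale")
  expect_output(print(summary(fit)), "Training log")
  expect_named(coef(fit, "large"))
  expect_identical(names(coef(fit, "large")), names(coef(fit, "small")))
})
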