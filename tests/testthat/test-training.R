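test_that("cross-entropy closed forms", {
  # uninformative prediction: ln 2
  expect_equal(cross_entropy(rep(0.5, 8), rep(c(0, 1), 4)), log(2),
               tolerance = 1e-12)
  # hand-evaluated two-example batch
  expect_equal(cross_entropy(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.9, 0.2), c(1, 0)), 0.1643, tolerance = 5e-4)
  # perfect prediction ~ 0 (clipped at 1e-12)
  expect_lt(cross_entropy(c(1, 0), c(1, 0)), 1e-10)
  expect_gte(cross_entropy(runif(5), rbinom(5, 1, 0.5)), 0)
  expect_error(cross_entropy(0.5, 2), class = "stressecg_error")
})

test_that("learning-rate schedule: step decay, two plateaus in 10 epochs", {
  cfgI <- train_config("I")
  cfgIII <- train_config("III")
  expect_equal(lr_at_epoch(cfgI, 0), 1e-3)
  expect_equal(lr_at_epoch(cfgI, 5), 1e-4)
  expect_equal(lr_at_epoch(cfgIII, 0), 1e-4)
  expect_equal(lr_at_epoch(cfgIII, 9), 1e-5)
  lrs <- lr_at_epoch(cfgI, 0:9)
  expect_equal(length(unique(lrs)), 2L)   # exactly two plateaus
  expect_equal(unique(lrs), c(1e-3, 1e-4))
})

test_that("train_config regimes carry the stated defaults", {
  cfg2 <- train_config("II")
  expect_equal(cfg2$batch_size, 64L)
  expect_equal(cfg2$max_epochs, 10L)
  expect_equal(cfg2$base_lr, 1e-3)
  expect_equal(cfg2$frozen_stages, integer(0))
  expect_equal(c(cfg2$beta1, cfg2$beta2, cfg2$eps), c(0.9, 0.999, 1e-8))
  cfg3 <- train_config("III")
  expect_equal(cfg3$base_lr, 1e-4)
  expect_equal(cfg3$frozen_stages, 1:7)
  expect_error(train_config("II", frozen_stages = c(0, 3)),
               class = "stressecg_error")
})

test_that("optimizer reduces the loss on a fixed tiny batch", {
  ds <- make_toy_dataset(n = 64, offset = 0.5, seed = 11)
  net <- build_model(model_config(10), seed = 4)
  cfg <- train_config("II", max_epochs = 3, seed = 6)
  fit <- train(net, ds, cfg)
  expect_lt(tail(fit$log$loss, 1), fit$log$loss[1])
  expect_lte(nrow(fit$log), 10)
})

test_that("training is deterministic under a fixed seed", {
  ds <- make_toy_dataset(n = 64, seed = 12)
  cfg <- train_config("II", max_epochs = 2, seed = 9)
  f1 <- train(build_model(model_config(10), seed = 3), ds, cfg)
  f2 <- train(build_model(model_config(10), seed = 3), ds, cfg)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$net$params, f2$net$params)
})

test_that("capacity sanity: separable toy reaches >= 0.99 train accuracy", {
  ds <- make_toy_dataset(n = 256, offset = 1, seed = 1)
  net <- build_model(model_config(10), seed = 2)
  fit <- train(net, ds, train_config("II", max_epochs = 6, seed = 3))
  expect_gte(max(fit$log$train_acc), 0.99)
})

test_that("prepare_transfer: head re-initialized, stages copied, seeds reproducible", {
  pre <- build_model(model_config(10), seed = 5)
  pre$meta$regime <- "I"
  tl <- prepare_transfer(pre, seed = 8)
  expect_true(tl$meta$transfer_prepared)
  expect_equal(tl$meta$frozen_stages, 1:7)
  expect_identical(tl$params[["s5.conv1.W"]], pre$params[["s5.conv1.W"]])
  expect_false(identical(tl$params[["head.W"]], pre$params[["head.W"]]))
  tl2 <- prepare_transfer(pre, seed = 8)
  expect_identical(tl$params[["head.W"]], tl2$params[["head.W"]])
  # architecture mismatch rejected
  expect_error(prepare_transfer(pre, cfg = model_config(30)),
               class = "stressecg_config_error")
  expect_error(prepare_transfer(pre, cfg = model_config(10,
                                                        channel_mode = "table3")),
               class = "stressecg_config_error")
})

test_that("regime III freezes stages 1-7 bit-exactly and updates stage 8 + head", {
  ds <- make_toy_dataset(n = 64, seed = 21)
  pre <- train(build_model(model_config(10), seed = 2), ds,
               train_config("I", max_epochs = 1, seed = 4))$net
  tl <- prepare_transfer(pre, seed = 5)
  before <- param_checksums(tl, stages = 1:7)
  head_before <- tl$params[["head.W"]]
  s8_before <- tl$params[["s8.conv1.W"]]
  fit <- train(tl, ds, train_config("III", max_epochs = 2, seed = 6))
  after <- param_checksums(fit$net, stages = 1:7)
  expect_identical(before, after)   # weights + BN gammas/betas + running stats
  expect_false(identical(fit$net$params[["head.W"]], head_before))
  expect_false(identical(fit$net$params[["s8.conv1.W"]], s8_before))
  # single-step gradient probe: frozen parameter untouched by one update
  expect_identical(fit$net$params[["s1.conv1.W"]], tl$params[["s1.conv1.W"]])
})

test_that("regime III requires a prepared pretrained network", {
  ds <- make_toy_dataset(n = 16, seed = 2)
  net <- build_model(model_config(10), seed = 1)
  expect_error(train(net, ds, train_config("III", max_epochs = 1)),
               class = "stressecg_error")
  empty <- stressecg:::ds_subset(ds, integer(0))
  expect_error(train(net, empty, train_config("II")),
               class = "stressecg_error")
})

test_that("checkpoints round-trip the full network state", {
  net <- build_model(model_config(10), seed = 13)
  net$meta$regime <- "I"
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, net$params)
  expect_identical(back$running, net$running)
  expect_equal(back$meta$regime, "I")
  expect_error(load_checkpoint(file.path(tempdir(), "absent.rds")),
               class = "stressecg_error")
})
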