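test_that("stage_output_shape matches the closed-form dimension contract", {
  cfg <- model_config(10)
  expect_equal(stage_output_shape(cfg, 1), c(width = 1280L, channels = 8L))
  expect_equal(stage_output_shape(cfg, 4), c(width = 160L, channels = 16L))
  expect_equal(stage_output_shape(cfg, 8), c(width = 10L, channels = 64L))
  chans <- vapply(1:8, function(N) stage_output_shape(cfg, N)[["channels"]], 0L)
  expect_equal(chans, c(8L, 8L, 16L, 16L, 32L, 32L, 64L, 64L))
  # 30 s: widths halve from 3840 down to 30
  cfg30 <- model_config(30)
  widths <- vapply(1:8, function(N) stage_output_shape(cfg30, N)[["width"]], 0L)
  expect_equal(widths, 7680L %/% 2L^(1:8))
  expect_error(stage_output_shape(cfg, 9), class = "stressecg_error")
  expect_error(stage_output_shape(cfg, 0), class = "stressecg_error")
})

test_that("probe batches reproduce the dimension equations at every stage", {
  for (ws in c(10, 30, 60)) {
    cfg <- model_config(ws)
    net <- build_model(cfg, seed = 1)
    m <- 2
    X <- with_seed(4, matrix(rnorm(cfg$w * m), cfg$w, m))
    for (N in c(1, 3, 8)) {
      fw <- stressecg:::net_forward(net, X, upto_stage = N, with_head = FALSE)
      sh <- stage_output_shape(cfg, N)
      expect_equal(dim(fw$feat), c(sh[["width"]], sh[["channels"]], m))
    }
  }
  # stage-8 feature width equals window_s
  expect_equal(stage_output_shape(model_config(60), 8)[["width"]], 60L)
})

test_that("table3 channel mode doubles the channel schedule", {
  cfg <- model_config(10, channel_mode = "table3")
  expect_equal(stage_output_shape(cfg, 8)[["channels"]], 128L)
  net <- build_model(cfg, seed = 1)
  fw <- stressecg:::net_forward(net, matrix(0, 2560, 1), upto_stage = 1,
                                with_head = FALSE)
  expect_equal(dim(fw$feat)[2], 16L)
})

test_that("softmax head normalizes and argmax labels follow probabilities", {
  net <- build_model(model_config(10), seed = 2)
  X <- matrix(0, 2560, 3)  # all-zero batch
  p <- predict(net, X)
  expect_equal(rowSums(p$prob), rep(1, 3), tolerance = 1e-6)
  # symmetry / closed-form softmax values
  expect_equal(stressecg:::softmax_rows(matrix(c(0, 0), 1)),
               matrix(0.5, 1, 2))
  expect_equal(stressecg:::softmax_rows(matrix(c(1, 0), 1))[1, 1],
               exp(1) / (exp(1) + 1), tolerance = 1e-6)
  # inference determinism
  Xr <- with_seed(9, matrix(rnorm(2560 * 4), 2560, 4))
  expect_identical(predict(net, Xr)$prob, predict(net, Xr)$prob)
  # width mismatch names the expected width
  err <- expect_error(predict(net, matrix(0, 1000, 2)),
                      class = "stressecg_shape_error")
  expect_match(conditionMessage(err), "2560")
})

test_that("He initialization: moment check and determinism", {
  cfg <- model_config(10)
  net <- build_model(cfg, seed = 7)
  # stage-8 first conv: fan-in 16 * 64 = 1024, 32768 weights >= 1e4
  W <- net$params[["s8.conv1.W"]]
  expect_gte(length(W), 1e4)
  target <- 2 / nrow(W)
  expect_lt(abs(var(as.vector(W)) - target) / target, 0.10)
  expect_lt(abs(mean(W)), 3 * sqrt(target / length(W)) * 2)
  # biases zero, bn gamma 1 / beta 0
  expect_equal(net$params[["s3.conv1.b"]], rep(0, 8))
  expect_equal(net$params[["s5.bn.gamma"]], rep(1, 32))
  expect_equal(net$params[["s5.bn.beta"]], rep(0, 32))
  # bit-identical rebuild under the same seed
  net2 <- build_model(cfg, seed = 7)
  expect_identical(net$params, net2$params)
  net3 <- build_model(cfg, seed = 8)
  expect_false(identical(net$params[["head.W"]], net3$params[["head.W"]]))
  # parameter count identical across rebuilds
  expect_identical(vapply(net$params, length, 0L),
                   vapply(net2$params, length, 0L))
})

test_that("strided-conv and pooling branches each carry half the channels", {
  cfg <- model_config(10)
  net <- build_model(cfg, seed = 3)
  X <- with_seed(2, array(rnorm(2560 * 2), c(2560, 1, 2)))
  fw <- stressecg:::net_forward(net, X, upto_stage = 1, with_head = FALSE,
                                keep_cache = TRUE)
  cc <- fw$caches[[1]]
  expect_equal(cc$br, 4L)               # c(1)/2 per branch
  expect_equal(dim(cc$A1), c(2560, 4, 2))  # first conv keeps width
  # pooling output is a true max over each window of the first conv output
  pool <- stressecg:::cpp_maxpool_fwd(cc$A1, 16L, 2L)
  o <- 10; ch <- 2; sl <- 1
  lo <- (o - 1) * 2 - 7  # same padding, pad_left = 7
  win <- cc$A1[max(1, lo + 1):min(2560, lo + 16), ch, sl]
  expect_equal(pool$Y[o, ch, sl], max(win))
})

test_that("invalid configurations error", {
  expect_error(model_config(10, fs = 100), class = "stressecg_config_error")
  expect_error(model_config(10.3), class = "stressecg_config_error")
})
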