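test_that("network output matches input size and stays in [0,1]", {
  m <- build_model(unet_tiny(), seed = 0)
  x <- array(rnorm(96 * 96 * 3, sd = 2), c(96, 96, 3))
  p <- predict_prob(m, x)
  expect_equal(dim(p), c(96, 96))
  expect_true(all(p >= 0 & p <= 1))
  expect_false(anyNA(p))

  # five-block configuration at the nominal 384 input (narrow widths so
  # the forward pass stays cheap)
  cfg5 <- unet_config(depth = 5, channel_schedule = c(4L, 8L, 8L, 8L, 8L),
                      bottleneck_channels = 8L, input_size = 384L)
  m5 <- build_model(cfg5, seed = 0)
  p5 <- predict_prob(m5, array(0.5, c(384, 384, 3)))
  expect_equal(dim(p5), c(384, 384))
  expect_true(all(p5 >= 0 & p5 <= 1))
})

test_that("constant inputs give finite outputs across init seeds", {
  x <- array(1, c(32, 32, 3))
  cfg <- unet_config(depth = 2, channel_schedule = c(4L, 8L),
                     bottleneck_channels = 8L, input_size = 32L)
  for (s in 0:4) {
    p <- predict_prob(build_model(cfg, seed = s), x)
    expect_true(all(is.finite(p)))
  }
})

test_that("config validation and input divisibility are enforced", {
  expect_error(unet_config(depth = 5, input_size = 100), "divisible")
  expect_error(unet_config(depth = 3, channel_schedule = c(8L, 16L)),
               "one entry per block")
  m <- build_model(unet_tiny(), seed = 0)
  expect_error(predict_prob(m, array(0, c(50, 50, 3))), "divisible")
})

test_that("tiny preset stays under 200k parameters and is fast", {
  m <- build_model(unet_tiny(), seed = 0)
  expect_lt(n_parameters(m), 2e5)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3))
  predict_prob(m, x)  # warm-up
  times <- vapply(1:5, function(i) {
    t0 <- Sys.time()
    predict_prob(m, x)
    as.numeric(Sys.time() - t0, units = "secs")
  }, 0)
  expect_lt(median(times), 0.05)
})

test_that("prediction is deterministic and initialization is seeded", {
  m1 <- build_model(unet_tiny(), seed = 7)
  m2 <- build_model(unet_tiny(), seed = 7)
  expect_identical(m1$weights, m2$weights)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3))
  expect_identical(predict_prob(m1, x), predict_prob(m1, x))
})

test_that("analytic gradients match finite differences", {
  cfg <- unet_config(depth = 2, channel_schedule = c(4L, 8L),
                     bottleneck_channels = 8L, input_size = 16L)
  m <- build_model(cfg, seed = 1)
  set.seed(2)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  M <- matrix(runif(256), 16, 16)
  res <- boxseg:::unet_loss_grad(m, list(x), list(y), list(M))
  eps <- 1e-6
  for (nm in c("enc1_W1", "dec1_upW", "dec2_W1", "head_W", "enc2_b2")) {
    k <- which.max(abs(res$grads[[nm]]))  # probe the most active weight
    up <- m; up$weights[[nm]][k] <- up$weights[[nm]][k] + eps
    dn <- m; dn$weights[[nm]][k] <- dn$weights[[nm]][k] - eps
    fd <- (boxseg:::unet_loss_grad(up, list(x), list(y), list(M))$loss -
             boxseg:::unet_loss_grad(dn, list(x), list(y), list(M))$loss) /
      (2 * eps)
    expect_equal(res$grads[[nm]][k], fd, tolerance = 1e-5)
  }
})

test_that("batch loss equals the masked-loss formula on predictions", {
  cfg <- unet_config(depth = 2, channel_schedule = c(4L, 8L),
                     bottleneck_channels = 8L, input_size = 16L)
  m <- build_model(cfg, seed = 3)
  set.seed(4)
  xs <- lapply(1:3, function(i) array(rnorm(16 * 16 * 3), c(16, 16, 3)))
  ys <- lapply(1:3, function(i) matrix(rbinom(256, 1, 0.4), 16, 16))
  ms <- lapply(1:3, function(i) matrix(runif(256), 16, 16))
  res <- boxseg:::unet_loss_grad(m, xs, ys, ms)
  num <- 0; den <- 0
  for (i in 1:3) {
    p <- predict_prob(m, xs[[i]])
    num <- num + masked_loss(p, ys[[i]], ms[[i]]) * sum(ms[[i]])
    den <- den + sum(ms[[i]])
  }
  expect_equal(res$loss, num / den, tolerance = 1e-10)
})

test_that("checkpoints round-trip exactly", {
  m <- build_model(unet_tiny(), seed = 5)
  m$norm_stats <- list(mean = c(0.4, 0.5, 0.6), sd = c(0.2, 0.2, 0.2))
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3))
  expect_identical(predict_prob(m, x), predict_prob(m2, x))
  expect_equal(m2$norm_stats$mean, m$norm_stats$mean)
})

test_that("encoder weight replacement respects shapes and sources", {
  m <- build_model(unet_tiny(), seed = 1)
  r1 <- load_encoder_weights(m, "random", seed = 9)
  r2 <- load_encoder_weights(m, "random", seed = 9)
  expect_identical(r1$weights, r2$weights)
  expect_false(identical(r1$weights$enc1_W1, m$weights$enc1_W1))
  expect_identical(r1$weights$head_W, m$weights$head_W)  # decoder untouched

  donor <- build_model(unet_tiny(), seed = 2)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(donor, tmp)
  tr <- load_encoder_weights(m, "checkpoint", path = tmp)
  expect_identical(tr$weights$enc2_W2, donor$weights$enc2_W2)
  expect_identical(tr$weights$dec1_W1, m$weights$dec1_W1)

  expect_error(load_encoder_weights(m, "vgg16-imagenet", path = tmp),
               "depth 5")
  other <- build_model(unet_config(depth = 3,
                                   channel_schedule = c(4L, 8L, 16L),
                                   bottleneck_channels = 16L,
                                   input_size = 96L), seed = 0)
  tmp2 <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(other, tmp2)
  expect_error(load_encoder_weights(m, "checkpoint", path = tmp2),
               "shape mismatch")
  expect_error(load_encoder_weights(m, "checkpoint", path = "nope.rds"),
               "existing")
})
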