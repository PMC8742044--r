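# F-Net unit: backbone variants, feature extraction, classification head,
# freezing, checkpoints.

test_that("tiny variant geometry: 64 channels, x8 downsampling", {
  net <- build_fnet(backbone_config("tiny", 64, seed = 1))
  x <- array(runif(64 * 64 * 3 * 3) * 255, c(64, 64, 3, 3))
  f <- extract_features(net, x)
  expect_identical(dim(f), c(8L, 8L, 64L, 3L))
})

test_that("input size must divide the downsampling factor", {
  expect_error(backbone_config("tiny", 60), "divisible")
  expect_error(backbone_config("full", 100), "divisible")
})

test_that("full variant terminates in 2048 channels (5 x 2048 = 10,240)", {
  cfg <- backbone_config("full", 32, seed = 2)
  expect_identical(cfg$channels, 2048L)
  net <- build_fnet(cfg)
  x <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  f <- extract_features(net, x)
  expect_identical(dim(f), c(1L, 1L, 2048L, 1L))
  expect_identical(5L * cfg$channels, 10240L)
})

test_that("initialisation is deterministic under the config seed", {
  n1 <- build_fnet(backbone_config("tiny", 32, seed = 7))
  n2 <- build_fnet(backbone_config("tiny", 32, seed = 7))
  n3 <- build_fnet(backbone_config("tiny", 32, seed = 8))
  expect_identical(param_checksum(n1), param_checksum(n2))
  expect_false(identical(param_checksum(n1), param_checksum(n3)))
})

test_that("feature extraction is deterministic and numerically sane", {
  net <- build_fnet(backbone_config("tiny", 32, seed = 3))
  x <- array(runif(32 * 32 * 3 * 2) * 255, c(32, 32, 3, 2))
  f1 <- extract_features(net, x)
  f2 <- extract_features(net, x)
  expect_identical(f1, f2)
  f0 <- extract_features(net, array(0, c(32, 32, 3)))
  expect_true(all(is.finite(f0)))
  expect_error(extract_features(net, array(0, c(16, 16, 3))), "spatial size")
})

test_that("classification yields a proper softmax over two categories", {
  net <- build_fnet(backbone_config("tiny", 32, seed = 4))
  x <- array(runif(32 * 32 * 3 * 5) * 255, c(32, 32, 3, 5))
  p <- classify(net, x)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  # zero logits force (0.5, 0.5)
  net$head_fc$W$v[] <- 0
  net$head_fc$b$v[] <- 0
  p0 <- classify(net, x)
  expect_true(all(p0 == 0.5))
  # softmax is monotone: argmax of probabilities = argmax of logits
  set.seed(5)
  logits <- matrix(rnorm(20), 2, 10)
  pr <- hmtnet:::softmax_cols(logits)
  expect_identical(apply(pr, 2, which.max), apply(logits, 2, which.max))
})

test_that("freezing conserves every parameter under training steps", {
  sep <- fix_separable("q1", n_per_class = 4L, image_size = 32L)
  net <- build_fnet(backbone_config("tiny", 32, seed = 6), "Q1")
  net <- freeze(net)
  net <- freeze(net)   # idempotent
  cs0 <- param_checksum(net)
  params <- hmtnet:::fnet_params(net)
  vals0 <- lapply(params, function(p) p$v)
  # push gradient-like updates through the optimizer; frozen params skip
  for (p in params) p$g <- p$v * 0 + 1
  hmtnet:::adam_step(params, lr = 0.1, t = 1)
  expect_identical(lapply(params, function(p) p$v), vals0)
  expect_identical(param_checksum(net), cs0)

  # contrast: an unfrozen training run changes the checksum
  net2 <- train_stage1(sep$records, "q1",
                       backbone_config("tiny", 32, seed = 6),
                       train_config(epochs = 2, batch_size = 4, seed = 1),
                       images = sep$images)
  expect_false(identical(param_checksum(net2), cs0))
})

test_that("checkpoints round-trip and refuse mismatched architectures", {
  net <- build_fnet(backbone_config("tiny", 32, seed = 9), "Q3")
  p <- tempfile(fileext = ".rds")
  save_fnet(net, p)
  back <- load_fnet(p)
  expect_identical(param_checksum(back), param_checksum(net))
  expect_identical(back$provenance, "Q3")
  expect_error(
    build_fnet(backbone_config("tiny", 64, weight_init = "external_checkpoint",
                               checkpoint = p)),
    "mismatch")
  # loading into a matching architecture reproduces the parameters
  same <- build_fnet(backbone_config("tiny", 32,
                                     weight_init = "external_checkpoint",
                                     checkpoint = p, seed = 99))
  expect_identical(param_checksum(same), param_checksum(net))
})
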