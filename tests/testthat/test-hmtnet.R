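# HMT-Net assembly, channel-attention fusion, compression arithmetic and
# reduced-branch variants.

test_that("assembly yields five parallel branches with frozen sub-networks", {
  m <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                     fix_tiny_cfg(9), seed = 1))
  expect_identical(m$n_branches, 5L)
  expect_identical(length(m$branches), 4L)
  expect_true(all(vapply(m$branches, function(b) b$frozen, logical(1))))
  expect_false(m$sup$frozen)
  expect_identical(m$c_total, 320L)
  expect_identical(m$c1, 128L)
  expect_identical(m$c2, 64L)
})

test_that("tiny fusion compresses 320 -> 128 -> 64 preserving spatial size", {
  m <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                     fix_tiny_cfg(9), seed = 1))
  x <- array(runif(32 * 32 * 3 * 2) * 255, c(32, 32, 3, 2))
  maps <- hmtnet:::hmtnet_branch_features(m, x)
  z <- hmtnet:::concat_channels(maps)
  expect_identical(dim(z)[3], 320L)
  h1 <- hmtnet:::layer_forward(m$fusion$conv1, z, FALSE)
  expect_identical(dim(h1), c(4L, 4L, 128L, 2L))
  fused <- fuse(m, maps)
  expect_identical(dim(fused), c(4L, 4L, 64L, 2L))
})

test_that("attention weights are strictly inside (0, 1) and per-sample", {
  m <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                     fix_tiny_cfg(9), seed = 2))
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 3) * 255, c(32, 32, 3, 3))
  z <- hmtnet:::concat_channels(hmtnet:::hmtnet_branch_features(m, x))
  s <- hmtnet:::gap_pool(z)
  a1 <- pmax(m$fusion$W1$v %*% s + m$fusion$b1$v, 0)
  g <- hmtnet:::sigmoid(m$fusion$W2$v %*% a1 + m$fusion$b2$v)
  expect_true(all(g > 0 & g < 1))
  # different samples get different gates (they depend on the features)
  expect_gt(max(abs(g[, 1] - g[, 2])), 0)
})

test_that("clamping the attention gate to 1 equals the no-attention path", {
  m <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                     fix_tiny_cfg(9), seed = 3))
  x <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  maps <- hmtnet:::hmtnet_branch_features(m, x)
  clamped <- fuse(m, maps, gate_override = 1)
  # no-attention pathway: the two compression convolutions on raw concat
  z <- hmtnet:::concat_channels(maps)
  h1 <- hmtnet:::layer_forward(m$fusion$conv1, z, FALSE)
  h1[h1 < 0] <- 0
  h2 <- hmtnet:::layer_forward(m$fusion$conv2, h1, FALSE)
  h2[h2 < 0] <- 0
  expect_identical(clamped, h2)
})

test_that("predictions are proper probabilities, deterministic and batch-stable", {
  m <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                     fix_tiny_cfg(9), seed = 4))
  set.seed(2)
  x <- array(runif(32 * 32 * 3 * 4) * 255, c(32, 32, 3, 4))
  p1 <- predict_q5(m, x)
  p2 <- predict_q5(m, x)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  out <- hmtnet:::hmtnet_forward(m, x)
  expect_true(all(abs(rowSums(out$p) - 1) < 1e-6))
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 4, 2)
  p_perm <- predict_q5(m, x[, , , perm, drop = FALSE])
  expect_equal(p_perm, p1[perm], tolerance = 1e-12)
})

test_that("assembly is deterministic and rejects mixed variants", {
  c1 <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                      fix_tiny_cfg(9), seed = 5))
  c2 <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                      fix_tiny_cfg(9), seed = 5))
  expect_identical(param_checksum(c1), param_checksum(c2))
  mismatched <- build_fnet(backbone_config("tiny", 64, seed = 1))
  expect_error(
    assemble_hmtnet(hmtnet_config(list(q1 = mismatched), fix_tiny_cfg(9))),
    "assembly error")
})

test_that("branch-subset variants scale the compression widths", {
  br <- fix_frozen_branches()
  m2 <- variant_with_branches(br, "q2", sup_config = fix_tiny_cfg(9))
  expect_identical(m2$n_branches, 2L)
  expect_identical(m2$c_total, 128L)
  expect_identical(m2$c1, 48L)   # 128 * 0.4 = 51.2, rounded to multiple of 8
  expect_identical(m2$c2, 24L)   # 128 * 0.2 = 25.6
  m0 <- variant_with_branches(br, character(0), sup_config = fix_tiny_cfg(9))
  expect_identical(m0$n_branches, 1L)
  expect_identical(m0$c_total, 64L)
  m4 <- variant_with_branches(br, c("q1", "q2", "q3", "q4"),
                              sup_config = fix_tiny_cfg(9))
  expect_identical(m4$c1, 128L)
  expect_identical(m4$c2, 64L)
  expect_error(variant_with_branches(br["q1"], c("q1", "q2")),
               "missing checkpoint")
})

test_that("the empty-subset baseline is a single F-Net plus fusion/head", {
  m0 <- variant_with_branches(fix_frozen_branches(), character(0),
                              sup_config = fix_tiny_cfg(9))
  n_model <- sum(vapply(hmtnet:::hmtnet_params(m0, "all"),
                        function(p) length(p$v), numeric(1)))
  n_sup <- sum(vapply(hmtnet:::fnet_params(m0$sup),
                      function(p) length(p$v), numeric(1)))
  n_fusion <- sum(vapply(hmtnet:::hmtnet_params(m0, "fusion"),
                         function(p) length(p$v), numeric(1)))
  expect_identical(n_model, n_sup + n_fusion)
})

test_that("model archives reload to an inference-identical model", {
  m <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                     fix_tiny_cfg(9), seed = 6))
  set.seed(3)
  x <- array(runif(32 * 32 * 3 * 2) * 255, c(32, 32, 3, 2))
  p <- tempfile(fileext = ".rds")
  save_hmtnet(m, p)
  back <- load_hmtnet(p)
  expect_identical(predict_q5(back, x), predict_q5(m, x))
})
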