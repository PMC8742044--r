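# Two-stage training protocol and cross-validation driver.

test_that("a separable mini-task is fit to 100% training accuracy", {
  sep <- fix_separable("q2", n_per_class = 8L, image_size = 64L)
  net <- train_stage1(sep$records, "q2",
                      backbone_config("tiny", 64, seed = 3),
                      train_config(epochs = 30, batch_size = 8, lr = 1e-3,
                                   seed = 3),
                      images = sep$images)
  p <- classify(net, sep$images)
  expect_identical(mean((p[, 2] > 0.5) == (sep$labels == 1)), 1)
  h <- attr(net, "history")
  expect_true(all(is.finite(h$loss)))
  # near-chance initial output: epoch-1 mean loss close to ln 2
  expect_lte(h$loss[1], log(2) + 0.5)
  expect_identical(net$provenance, "Q2")
})

test_that("stage-I end state is deterministic under fixed seed and data", {
  sep <- fix_separable("q1", n_per_class = 4L, image_size = 32L)
  run <- function() {
    net <- train_stage1(sep$records, "q1",
                        backbone_config("tiny", 32, seed = 2),
                        train_config(epochs = 3, batch_size = 4, seed = 9),
                        images = sep$images)
    param_checksum(net)
  }
  expect_identical(run(), run())
})

test_that("degenerate stage-I inputs are rejected", {
  sep <- fix_separable("q1", n_per_class = 4L, image_size = 32L)
  rec_one <- sep$records
  rec_one$q1 <- 1L
  expect_error(train_stage1(rec_one, "q1", backbone_config("tiny", 32),
                            images = sep$images), "degenerate")
  rec_na <- sep$records
  rec_na$q1[1] <- NA_integer_
  expect_error(train_stage1(rec_na, "q1", backbone_config("tiny", 32),
                            images = sep$images), "missing labels")
})

test_that("stage-II only updates sup, fusion and head parameters", {
  sep <- fix_separable("q2", n_per_class = 6L, image_size = 32L)
  rec <- data.frame(path = sep$records$path, q5 = sep$labels)
  m <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                     fix_tiny_cfg(9), seed = 21))
  cs_branches <- param_checksum(m, "branches")
  cs_sup <- param_checksum(m, "sup")
  cs_fusion <- param_checksum(m, "fusion")
  m <- train_stage2(m, rec, train_config(epochs = 2, batch_size = 6, seed = 2),
                    images = sep$images)
  expect_identical(param_checksum(m, "branches"), cs_branches)
  expect_false(identical(param_checksum(m, "sup"), cs_sup))
  expect_false(identical(param_checksum(m, "fusion"), cs_fusion))
  expect_true(all(is.finite(attr(m, "history")$loss)))
})

test_that("stage-II rejects empty data and unfrozen branches", {
  m <- assemble_hmtnet(hmtnet_config(fix_frozen_branches(),
                                     fix_tiny_cfg(9), seed = 22))
  expect_error(train_stage2(m, data.frame(path = character(0),
                                          q5 = integer(0))),
               "empty Dataset-II")
  m$branches[[1]]$frozen <- FALSE
  sep <- fix_separable("q1", n_per_class = 2L, image_size = 32L)
  rec <- data.frame(path = sep$records$path, q5 = sep$labels)
  expect_error(train_stage2(m, rec, images = sep$images), "unfrozen")
})

test_that("cross-validation partitions cleanly and aggregates by the mean", {
  co <- fix_small_corpus()
  plan <- make_folds(co$manifest, k = 4, unit = "subject", seed = 5)
  pc <- pipeline_config(
    backbone = backbone_config("tiny", 64),
    stage1_config = train_config(epochs = 1, batch_size = 16, seed = 1),
    stage2_config = train_config(epochs = 1, batch_size = 16, seed = 2),
    branch_subset = c("q1", "q2"),
    seed = 77)
  cv <- run_crossvalidation(co$manifest, plan, pc, co$images)
  expect_identical(length(cv$fold_reports), 4L)
  # test sets are disjoint and cover all records
  tests <- lapply(cv$audit, function(a) a$test)
  expect_identical(sort(unlist(tests)), sort(co$manifest$path))
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(tests[[i]], tests[[j]]), 0)
  # no training path of a fold is in its test set
  for (a in cv$audit) {
    expect_length(intersect(c(a$stage1, a$stage2), a$test), 0)
    expect_length(intersect(a$stage1, a$stage2), 0)
  }
  # the aggregate equals the hand-computed mean of fold accuracies
  accs <- vapply(cv$fold_reports, function(r) r$acc, numeric(1))
  expect_equal(unname(cv$mean["acc"]), mean(accs), tolerance = 1e-12)
  aucs <- vapply(cv$fold_reports, function(r) r$auc, numeric(1))
  expect_equal(unname(cv$mean["auc"]), mean(aucs), tolerance = 1e-12)
})

test_that("pretext pretraining returns a usable initial network", {
  net <- pretext_pretrain(backbone_config("tiny", 32, seed = 3),
                          n_images = 6L,
                          config = train_config(epochs = 1, batch_size = 4,
                                                seed = 3))
  x <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
  expect_identical(dim(extract_features(net, x)), c(4L, 4L, 64L, 1L))
})
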