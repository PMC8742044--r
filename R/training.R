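# Two-stage training protocol and the cross-validation driver.

#' Training configuration
#'
#' @param epochs number of passes over the training data (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param lr initial learning rate (> 0).
#' @param lr_decay optional multiplicative decay factor applied every
#'   `lr_step` epochs.
#' @param lr_step epochs between decays.
#' @param optimizer `"adam"` (adaptive moments) or `"sgd"` (gradient descent
#'   with momentum).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param seed seed for shuffling (and any stochastic layer).
#' @param patience optional early-stop patience on the epoch loss.
#' @param class_weights optional length-2 loss weights (negative, positive);
#'   `"balanced"` uses inverse class frequencies.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, lr = 1e-3,
                         lr_decay = NULL, lr_step = 10L,
                         optimizer = c("adam", "sgd"), momentum = 0.9,
                         weight_decay = 0, seed = 1L, patience = NULL,
                         class_weights = NULL) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1 || batch_size < 1 || lr <= 0)
    stop("invalid training configuration: need epochs >= 1, batch_size >= 1, lr > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 optimizer = optimizer, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 patience = patience, class_weights = class_weights),
            class = "train_config")
}

resolve_class_weights <- function(cw, labels) {
  if (is.null(cw)) return(NULL)
  if (identical(cw, "balanced")) {
    n <- c(sum(labels == 0), sum(labels == 1))
    w <- length(labels) / (2 * pmax(n, 1))
    return(w)
  }
  cw
}

# Shared minibatch loop. step_fn(xb, yb, training_step_index) must return the
# batch loss and accumulate/apply gradients itself.
run_epochs <- function(config, n, step_fn, on_epoch = NULL) {
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  lr <- config$lr
  t <- 0L
  best <- Inf; wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot <- 0
    for (b in batches) {
      t <- t + 1L
      tot <- tot + step_fn(b, lr, t) * length(b)
    }
    epoch_loss <- tot / n
    if (!is.finite(epoch_loss)) stop("non-finite training loss at epoch ", epoch)
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss))
    if (!is.null(on_epoch)) on_epoch(epoch, epoch_loss)
    if (!is.null(config$lr_decay) && epoch %% config$lr_step == 0L)
      lr <- lr * config$lr_decay
    if (!is.null(config$patience)) {
      if (epoch_loss < best - 1e-6) { best <- epoch_loss; wait <- 0L }
      else { wait <- wait + 1L; if (wait >= config$patience) break }
    }
  }
  history
}

#' Train a Stage-I sub-question F-Net
#'
#' Trains one F-Net on a binary sub-question label (Q1..Q4; Q5 gives the
#' single-network baseline) with softmax cross-entropy. The end state is
#' deterministic under fixed seeds and data order.
#'
#' @param records manifest rows of the training images (Dataset-I portion).
#' @param question one of `"q1"`..`"q5"` naming the label column.
#' @param backbone a [backbone_config()].
#' @param config a [train_config()].
#' @param images optional preloaded `(H, W, 3, N)` array matching `records`;
#'   loaded from `records$path` when `NULL`.
#' @param augment_config optional [augmentation_config()]; when supplied,
#'   the augmented copies of each training image are added to the epoch
#'   pool (training portion only).
#' @return a trained `fnet` with attribute `history` (per-epoch loss) and
#'   `train_paths` (the image paths seen, for leakage audits).
#' @export
train_stage1 <- function(records, question, backbone = backbone_config(),
                         config = train_config(), images = NULL,
                         augment_config = NULL) {
  question <- tolower(question)
  labels <- records[[question]]
  if (anyNA(labels)) stop("records carry missing labels for ", question)
  if (length(unique(labels)) < 2)
    stop("degenerate task: all training labels for ", question,
         " are one category")
  if (is.null(images)) images <- load_images(records)
  if (!is.null(augment_config)) {
    aug <- expand_augmented(images, labels, augment_config, config$seed)
    images <- aug$images; labels <- aug$labels
  }
  net <- build_fnet(backbone, provenance = toupper(question))
  params <- fnet_params(net)
  cw <- resolve_class_weights(config$class_weights, labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  history <- run_epochs(config, dim(images)[4], function(b, lr, t) {
    xb <- images[, , , b, drop = FALSE]
    yb <- labels[b]
    feat <- extract_features(net, xb, training = TRUE)
    pooled <- gap_pool(feat)
    logits <- fc_forward(net$head_fc, pooled)
    ce <- softmax_xent(logits, yb, cw)
    zero_grads(params)
    net$head_fc$W$g <- ce$dlogits %*% t(pooled)
    net$head_fc$b$g <- rowSums(ce$dlogits)
    dpooled <- t(net$head_fc$W$v) %*% ce$dlogits
    d <- dim(feat); HW <- d[1] * d[2]
    dfeat <- array(rep(as.numeric(dpooled / HW), each = HW), d)
    net_backward(net$extractor, dfeat)
    optim_step(params, config, lr, t)
    ce$loss
  })
  attr(net, "history") <- history
  attr(net, "train_paths") <- records$path
  net
}

expand_augmented <- function(images, labels, aug_config, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 7L)
  outs <- list(); labs <- integer(0)
  for (i in seq_len(dim(images)[4])) {
    img <- images[, , , i]
    storage.mode(img) <- "integer"
    a <- augment(img, mask = NULL,
                 config = within_mask_heuristic(aug_config))
    outs <- c(outs, a)
    labs <- c(labs, rep(labels[i], length(a)))
  }
  arr <- array(0, c(dim(images)[1:3], length(outs)))
  for (i in seq_along(outs)) arr[, , , i] <- outs[[i]]
  list(images = arr, labels = labs)
}

within_mask_heuristic <- function(cfg) { cfg$mask_source <- "heuristic"; cfg }

optim_step <- function(params, config, lr, t) {
  if (config$optimizer == "adam")
    adam_step(params, lr, weight_decay = config$weight_decay, t = t)
  else
    sgd_step(params, lr, momentum = config$momentum,
             weight_decay = config$weight_decay)
}

#' Train Stage-II: the fused disease classifier
#'
#' Fine-tunes the HMT-Net on the disease label (`q5`) over Dataset-II. Only
#' the supplementary branch, the attention/compression fusion and the
#' classifier head receive updates; the sub-question branches must be frozen
#' (verified before training) and their features are computed once and
#' cached, since frozen parameters cannot change.
#'
#' @param model an assembled `hmtnet`.
#' @param records manifest rows with `q5` labels (Dataset-II portion).
#' @param config a [train_config()].
#' @param images optional preloaded image array matching `records`.
#' @return the trained `hmtnet` with attributes `history` and `train_paths`.
#' @export
train_stage2 <- function(model, records, config = train_config(),
                         images = NULL) {
  if (!nrow(records)) stop("empty Dataset-II: nothing to train on")
  labels <- records$q5
  if (anyNA(labels)) stop("records carry missing q5 labels")
  for (b in model$branches)
    if (!b$frozen) stop("configuration error: unfrozen sub-question branch detected")
  if (is.null(images)) images <- load_images(records)
  n <- dim(images)[4]

  frozen_feats <- NULL
  if (length(model$branches)) {
    maps <- lapply(model$branches, function(b) extract_features(b, images))
    frozen_feats <- concat_channels(maps)
  }
  params <- c(hmtnet_params(model, "sup"), hmtnet_params(model, "fusion"))
  cw <- resolve_class_weights(config$class_weights, labels)
  ch_sup <- model$sup$config$channels
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  history <- run_epochs(config, n, function(b, lr, t) {
    xb <- images[, , , b, drop = FALSE]
    yb <- labels[b]
    sup_map <- extract_features(model$sup, xb, training = TRUE)
    z <- if (is.null(frozen_feats)) sup_map
         else {
           fz <- frozen_feats[, , , b, drop = FALSE]
           d <- dim(fz)
           out <- array(0, c(d[1], d[2], d[3] + ch_sup, d[4]))
           out[, , seq_len(d[3]), ] <- fz
           out[, , d[3] + seq_len(ch_sup), ] <- sup_map
           out
         }
    fused <- fusion_forward(model, z, training = TRUE)
    pooled <- gap_pool(fused)
    logits <- fc_forward(model$fusion$head_fc, pooled)
    ce <- softmax_xent(logits, yb, cw)
    zero_grads(params)
    model$fusion$head_cache <- list(pooled = pooled, fdim = dim(fused))
    hmtnet_backward(model, ce$dlogits)
    optim_step(params, config, lr, t)
    ce$loss
  })
  attr(model, "history") <- history
  attr(model, "train_paths") <- records$path
  model
}

#' Pipeline configuration for cross-validated runs
#'
#' @param backbone [backbone_config()] shared by all branches.
#' @param stage1_config,stage2_config [train_config()]s for the two stages.
#'   Desk-scale defaults (4 epochs each at lr 2e-3) keep a fivefold run in
#'   minutes.
#' @param branch_subset character vector of sub-questions used as frozen
#'   branches; `character(0)` gives the single-branch baseline.
#' @param stage1_fraction fraction of each training split assigned to
#'   Dataset-I.
#' @param split_unit `"subject"` or `"image"` for the internal Stage-I/II
#'   partition.
#' @param seed master seed fanned out to the per-fold derived seeds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(backbone = backbone_config(),
                            stage1_config = train_config(epochs = 4L, lr = 2e-3),
                            stage2_config = train_config(epochs = 4L, lr = 2e-3),
                            branch_subset = c("q1", "q2", "q3", "q4"),
                            stage1_fraction = 0.5,
                            split_unit = "subject",
                            seed = 1L) {
  structure(list(backbone = backbone, stage1_config = stage1_config,
                 stage2_config = stage2_config,
                 branch_subset = tolower(branch_subset),
                 stage1_fraction = stage1_fraction,
                 split_unit = split_unit, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Cross-validated two-stage training and evaluation
#'
#' For each fold: the non-test records are partitioned into Dataset-I and
#' Dataset-II; Stage-I trains one frozen branch per requested sub-question
#' on Dataset-I; Stage-II assembles and trains the fused model on
#' Dataset-II; the fold's held-out images are scored. No test image of a
#' fold enters any training stage of that fold (asserted from the logged
#' path sets; violation is a hard failure).
#'
#' @param records manifest `data.frame`.
#' @param plan a [make_folds()] split plan covering all records.
#' @param config a [pipeline_config()].
#' @param images optional preloaded image array matching `records`.
#' @return object of class `cv_result`: per-fold [metrics_report()]s,
#'   mean/sd aggregates, the plan fingerprint and leakage audit log.
#' @export
run_crossvalidation <- function(records, plan, config = pipeline_config(),
                                images = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  fold_of <- plan$fold[match(records$path, plan$path)]
  if (anyNA(fold_of)) stop("split plan does not cover all records")
  if (is.null(images)) images <- load_images(records)
  k <- attr(plan, "k")
  reports <- vector("list", k)
  audit <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    fold_seed <- (config$seed * 1009L + f * 101L) %% .Machine$integer.max
    tr <- records[train_idx, , drop = FALSE]
    stage <- split_stage_datasets(tr, config$stage1_fraction,
                                  unit = config$split_unit, seed = fold_seed)
    i1 <- train_idx[stage$stage == "I"]
    i2 <- train_idx[stage$stage == "II"]

    branches <- list()
    for (q in config$branch_subset) {
      cfgq <- config$stage1_config
      cfgq$seed <- fold_seed + match(q, c("q1", "q2", "q3", "q4", "q5"))
      bb <- config$backbone
      bb$seed <- cfgq$seed
      branches[[q]] <- train_stage1(records[i1, , drop = FALSE], q,
                                    backbone = bb, config = cfgq,
                                    images = images[, , , i1, drop = FALSE])
    }
    bb_sup <- config$backbone
    bb_sup$seed <- fold_seed + 7L
    model <- assemble_hmtnet(hmtnet_config(branches = branches,
                                           sup_config = bb_sup,
                                           seed = fold_seed + 11L))
    cfg2 <- config$stage2_config
    cfg2$seed <- fold_seed + 13L
    model <- train_stage2(model, records[i2, , drop = FALSE], cfg2,
                          images = images[, , , i2, drop = FALSE])

    train_paths <- unique(c(records$path[i1], records$path[i2]))
    test_paths <- records$path[test_idx]
    if (length(intersect(train_paths, test_paths)))
      stop("leakage detected: test images of fold ", f, " appeared in training")
    audit[[f]] <- list(stage1 = records$path[i1], stage2 = records$path[i2],
                       test = test_paths)

    scores <- predict_q5(model, images[, , , test_idx, drop = FALSE])
    reports[[f]] <- metrics_report(scores, records$q5[test_idx])
  }
  agg_names <- c("se", "sp", "acc", "auc")
  vals <- sapply(reports, function(r) unlist(r[agg_names]))
  structure(list(fold_reports = reports,
                 mean = rowMeans(vals), sd = apply(vals, 1, stats::sd),
                 k = k, plan_fingerprint = plan_fingerprint(plan),
                 audit = audit, config = config),
            class = "cv_result")
}

plan_fingerprint <- function(plan) {
  paste0(attr(plan, "k"), "/", attr(plan, "unit"), "/", attr(plan, "seed"),
         "/", sum(plan$fold * seq_along(plan$fold)))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "-fold cross-validation\n", sep = "")
  m <- x$mean; s <- x$sd
  for (nm in names(m))
    cat(sprintf("  %s: %.4f (sd %.4f)\n", toupper(nm), m[nm], s[nm]))
  invisible(x)
}

#' Self-contained pretext pretraining
#'
#' Initialises a backbone by training it to discriminate vessel-bearing from
#' vessel-free synthetic patches, a stand-in initialisation when no external
#' checkpoint is available.
#'
#' @param backbone a [backbone_config()].
#' @param n_images patches per class.
#' @param config a [train_config()].
#' @return an `fnet` whose extractor can seed further training.
#' @export
pretext_pretrain <- function(backbone = backbone_config(),
                             n_images = 32L,
                             config = train_config(epochs = 5L)) {
  spec <- synthetic_spec(image_size = backbone$input_size,
                         n_diseased_subjects = 2L, n_healthy_subjects = 2L,
                         n_images_diseased = n_images, n_images_healthy = n_images,
                         vessels_per_image_range = c(1L, 3L),
                         pixel_noise_sd = 8, seed = config$seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  arr <- array(0, c(backbone$input_size, backbone$input_size, 3, 2L * n_images))
  labels <- integer(2L * n_images)
  for (i in seq_len(2L * n_images)) {
    has_vessel <- i %% 2L == 0L
    if (has_vessel) {
      smp <- render_conjunctiva(spec, c(0L, 0L, 0L, 0L), "p", 0L)
      arr[, , , i] <- smp$image
    } else {
      arr[, , , i] <- array(rep(spec$background_mean_color,
                                each = backbone$input_size^2),
                            c(backbone$input_size, backbone$input_size, 3)) +
        stats::rnorm(3 * backbone$input_size^2, sd = spec$pixel_noise_sd)
    }
    labels[i] <- as.integer(has_vessel)
  }
  rec <- data.frame(path = sprintf("pretext_%03d", seq_along(labels)),
                    qp = labels)
  train_stage1(rec, "qp", backbone = backbone, config = config, images = arr)
}
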