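#' HMT-Net configuration
#'
#' Configuration of the hierarchical multi-task network: up to four frozen
#' sub-question F-Net branches (Q1..Q4) plus a trainable supplementary
#' branch, fused by per-channel attention and two compression convolutions
#' (kernel size 3, stride 1), followed by a GAP + FC + softmax head over
#' \{healthy, diabetic\}.
#'
#' At full scale the five 2048-channel branches concatenate to 10,240
#' channels, compressed to 4096 and then 2048; at tiny scale 5 x 64 = 320
#' channels are compressed to 128 and 64. When `compression` is `NULL` the
#' two widths scale proportionally to the concatenated width (ratios 0.4 and
#' 0.2), rounded to a multiple of 8 with floor 8, which reproduces those
#' numbers exactly.
#'
#' @param branches list of trained F-Nets (or checkpoint paths) for the
#'   sub-questions, in fixed order; may be empty (baseline model).
#' @param sup_config [backbone_config()] for the supplementary branch.
#' @param compression integer pair `(c1, c2)` of compression-convolution
#'   output channels, or `NULL` to scale from the concatenated width.
#' @param reduction_ratio bottleneck reduction of the channel-attention gate
#'   (default 16).
#' @param seed seed for fusion/head initialisation.
#' @return An object of class `hmtnet_config`.
#' @export
hmtnet_config <- function(branches = list(), sup_config = backbone_config(),
                          compression = NULL, reduction_ratio = 16L,
                          seed = 1L) {
  branches <- lapply(branches, function(b) if (is.character(b)) load_fnet(b) else b)
  structure(list(branches = branches, sup_config = sup_config,
                 compression = compression,
                 reduction_ratio = as.integer(reduction_ratio),
                 kernel_size = 3L, stride = 1L,
                 seed = as.integer(seed)),
            class = "hmtnet_config")
}

scaled_compression <- function(c_total) {
  r8 <- function(x) max(8L, as.integer(round(x / 8) * 8))
  c(r8(c_total * 4096 / 10240), r8(c_total * 2048 / 10240))
}

#' Assemble an HMT-Net
#'
#' Builds the five-parallel-branch model: the GAP/FC heads of the
#' sub-question branches are discarded (only their feature extraction layers
#' are kept) and the branches frozen; the supplementary branch is initialised
#' from its own configuration; attention, compression convolutions and the
#' classifier head are freshly initialised under the config seed.
#'
#' @param config an [hmtnet_config()].
#' @return An object of class `hmtnet`.
#' @export
assemble_hmtnet <- function(config) {
  stopifnot(inherits(config, "hmtnet_config"))
  sup <- build_fnet(config$sup_config, provenance = "sup")
  for (b in config$branches) {
    if (!identical(b$config$variant, sup$config$variant) ||
        !identical(b$config$input_size, sup$config$input_size))
      stop("assembly error: branch (", b$config$variant, "/",
           b$config$input_size, ") does not match sup branch (",
           sup$config$variant, "/", sup$config$input_size, ")")
  }
  branches <- lapply(config$branches, freeze)
  ch <- sup$config$channels
  n_br <- length(branches) + 1L
  c_total <- n_br * ch
  comp <- config$compression
  if (is.null(comp)) comp <- scaled_compression(c_total)
  c1 <- as.integer(comp[1]); c2 <- as.integer(comp[2])
  if (!(c2 < c1 && c1 < c_total))
    stop("compression widths must satisfy c2 < c1 < concatenated channels; got ",
         c1, ", ", c2, " for ", c_total)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  c_red <- max(1L, c_total %/% config$reduction_ratio)
  fus <- new.env(parent = emptyenv())
  fus$W1 <- new_param(he_init(c_red, c_total, gain = 1))
  fus$b1 <- new_param(numeric(c_red))
  fus$W2 <- new_param(he_init(c_total, c_red, gain = 1))
  fus$b2 <- new_param(numeric(c_total))
  fus$conv1 <- nn_conv(c_total, c1, k = 3L, stride = 1L, bias = TRUE)
  fus$conv2 <- nn_conv(c1, c2, k = 3L, stride = 1L, bias = TRUE)
  fus$head_fc <- nn_fc(c2, 2L)

  structure(list(config = config, branches = branches, sup = sup,
                 fusion = fus, c_total = c_total, c1 = c1, c2 = c2,
                 n_branches = n_br),
            class = "hmtnet")
}

#' Reduced-branch HMT-Net variants
#'
#' Builds the model that uses only a subset of the sub-question branches.
#' `subset = character(0)` yields the single-branch baseline (one F-Net
#' predicting the disease directly through the same fusion/head geometry);
#' the full subset reproduces [assemble_hmtnet()] with all four branches.
#'
#' @param branches named list of trained F-Nets, e.g.
#'   `list(Q1 = ..., Q2 = ...)`.
#' @param subset character vector naming the branches to keep, in order.
#' @param sup_config,seed,reduction_ratio passed to [hmtnet_config()].
#' @return An `hmtnet`.
#' @export
variant_with_branches <- function(branches, subset, sup_config = backbone_config(),
                                  seed = 1L, reduction_ratio = 16L) {
  missing <- setdiff(subset, names(branches))
  if (length(missing))
    stop("missing checkpoint for requested branch(es): ",
         paste(missing, collapse = ", "))
  assemble_hmtnet(hmtnet_config(branches = branches[subset],
                                sup_config = sup_config,
                                reduction_ratio = reduction_ratio,
                                seed = seed))
}

# Concatenate per-branch feature maps (h,w,C,N each) along channels.
concat_channels <- function(maps) {
  d <- dim(maps[[1]])
  for (m in maps) if (!all(dim(m)[c(1, 2, 4)] == d[c(1, 2, 4)]))
    stop("mismatched spatial sizes across branches")
  ch <- vapply(maps, function(m) dim(m)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(ch), d[4]))
  at <- 0L
  for (i in seq_along(maps)) {
    out[, , at + seq_len(ch[i]), ] <- maps[[i]]
    at <- at + ch[i]
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Fusion forward: channel attention then two compression convolutions.
# gate_override clamps every attention weight to the given constant
# (used to compare against the attention-free pathway).
fusion_forward <- function(model, z, training = FALSE, gate_override = NULL) {
  fus <- model$fusion
  d <- dim(z); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  s <- gap_pool(z)
  a1pre <- fus$W1$v %*% s + fus$b1$v
  a1 <- pmax(a1pre, 0)
  gpre <- fus$W2$v %*% a1 + fus$b2$v
  g <- sigmoid(gpre)
  if (!is.null(gate_override)) g <- matrix(gate_override, C, N)
  zg <- matrix(z, nrow = HW) * rep(as.numeric(g), each = HW)
  dim(zg) <- d
  h1 <- layer_forward(fus$conv1, zg, training)
  m1 <- h1 > 0
  h1[h1 < 0] <- 0
  h2 <- layer_forward(fus$conv2, h1, training)
  m2 <- h2 > 0
  h2[h2 < 0] <- 0
  if (training) {
    fus$cache <- list(z = z, s = s, a1pre = a1pre, a1 = a1, g = g,
                      m1 = m1, m2 = m2, d = d,
                      overridden = !is.null(gate_override))
  }
  h2
}

fusion_backward <- function(model, dh2) {
  fus <- model$fusion
  cc <- fus$cache
  d <- cc$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dh2[!cc$m2] <- 0
  dh1 <- layer_backward(fus$conv2, dh2)
  dh1[!cc$m1] <- 0
  dzg <- layer_backward(fus$conv1, dh1)
  gfull <- rep(as.numeric(cc$g), each = HW)
  zm <- matrix(cc$z, nrow = HW)
  dzgm <- matrix(dzg, nrow = HW)
  dz <- dzgm * gfull
  if (!cc$overridden) {
    dg <- matrix(.colSums(dzgm * zm, HW, C * N), C, N)
    dgpre <- dg * cc$g * (1 - cc$g)
    fus$W2$g <- acc_grad(fus$W2$g, dgpre %*% t(cc$a1))
    fus$b2$g <- acc_grad(fus$b2$g, rowSums(dgpre))
    da1 <- t(fus$W2$v) %*% dgpre
    da1[cc$a1pre <= 0] <- 0
    fus$W1$g <- acc_grad(fus$W1$g, da1 %*% t(cc$s))
    fus$b1$g <- acc_grad(fus$b1$g, rowSums(da1))
    ds <- t(fus$W1$v) %*% da1
    dz <- dz + rep(as.numeric(ds / HW), each = HW)
  }
  dim(dz) <- d
  dz
}

#' Fuse branch feature maps
#'
#' Channel concatenation (branch order Q1..Q4, sup) -> per-channel attention
#' weights in (0,1) -> compression convolution 1 -> rectifier -> compression
#' convolution 2. Spatial size is preserved end-to-end.
#'
#' @param model an `hmtnet`.
#' @param feature_maps list of arrays `(h, w, C, N)` (or `(h, w, C)` for a
#'   single image), one per branch, all sharing `h x w`.
#' @param gate_override optionally clamp all attention gates to a constant.
#' @return fused array `(h, w, c2, N)`.
#' @export
fuse <- function(model, feature_maps, gate_override = NULL) {
  feature_maps <- lapply(feature_maps, function(m) {
    if (length(dim(m)) == 3L) dim(m) <- c(dim(m), 1L)
    m
  })
  z <- concat_channels(feature_maps)
  if (dim(z)[3] != model$c_total)
    stop("expected ", model$c_total, " concatenated channels, got ", dim(z)[3])
  fusion_forward(model, z, training = FALSE, gate_override = gate_override)
}

hmtnet_branch_features <- function(model, images, sup_training = FALSE) {
  maps <- lapply(model$branches, function(b) extract_features(b, images))
  sup_map <- extract_features(model$sup, images, training = sup_training)
  c(maps, list(sup_map))
}

# Full forward pass. Returns probabilities (N x 2) plus intermediates.
hmtnet_forward <- function(model, images, training = FALSE,
                           frozen_maps = NULL) {
  if (is.null(frozen_maps)) {
    maps <- hmtnet_branch_features(model, images, sup_training = training)
    z <- concat_channels(maps)
  } else {
    sup_map <- extract_features(model$sup, images, training = training)
    z <- concat_channels(c(frozen_maps, list(sup_map)))
  }
  fused <- fusion_forward(model, z, training = training)
  pooled <- gap_pool(fused)
  logits <- fc_forward(model$fusion$head_fc, pooled)
  if (training) model$fusion$head_cache <- list(pooled = pooled, fdim = dim(fused))
  list(p = t(softmax_cols(logits)), logits = logits,
       concat_channels = dim(z)[3], fused_channels = dim(fused)[3],
       fused_dim = dim(fused))
}

# Backward from dlogits down to the sup-branch input gradient; accumulates
# gradients in head, fusion and sup-branch parameters.
hmtnet_backward <- function(model, dlogits) {
  fus <- model$fusion
  hc <- fus$head_cache
  fus$head_fc$W$g <- acc_grad(fus$head_fc$W$g, dlogits %*% t(hc$pooled))
  fus$head_fc$b$g <- acc_grad(fus$head_fc$b$g, rowSums(dlogits))
  dpooled <- t(fus$head_fc$W$v) %*% dlogits
  d <- hc$fdim; HW <- d[1] * d[2]
  dfused <- array(rep(as.numeric(dpooled / HW), each = HW), d)
  dz <- fusion_backward(model, dfused)
  # only the sup branch (last channel block) is trainable
  ch <- model$sup$config$channels
  sup_slice <- dz[, , model$c_total - ch + seq_len(ch), , drop = FALSE]
  net_backward(model$sup$extractor, sup_slice)
  invisible(NULL)
}

#' Predict disease probability with an HMT-Net
#'
#' @param model an `hmtnet`.
#' @param images array `(H, W, 3)` or `(H, W, 3, N)`.
#' @return numeric vector of P(diabetic) per image, in (0,1); the
#'   complementary P(healthy) is `1 - value`.
#' @export
predict_q5 <- function(model, images) {
  out <- hmtnet_forward(model, images, training = FALSE)
  as.numeric(out$p[, 2])
}

#' @export
predict.hmtnet <- function(object, newdata, ...) predict_q5(object, newdata)

hmtnet_params <- function(model, part = "all") {
  fus <- model$fusion
  fusion_ps <- c(list(fus$W1, fus$b1, fus$W2, fus$b2),
                 collect_params(list(fus$conv1, fus$conv2)),
                 list(fus$head_fc$W, fus$head_fc$b))
  switch(part,
    all = c(unlist(lapply(model$branches, fnet_params)),
            fnet_params(model$sup), fusion_ps),
    branches = unlist(lapply(model$branches, fnet_params)),
    sup = fnet_params(model$sup),
    fusion = fusion_ps,
    stop("unknown part: ", part))
}

#' @export
print.hmtnet <- function(x, ...) {
  cat("HMT-Net: ", x$n_branches, " parallel branches (",
      length(x$branches), " frozen sub-question + 1 sup)\n", sep = "")
  cat("  concatenated channels:", x$c_total,
      "-> conv1:", x$c1, "-> conv2:", x$c2, "\n")
  cat("  backbone:", x$sup$config$variant, "variant, input",
      x$sup$config$input_size, "\n")
  invisible(x)
}

#' Save / load an HMT-Net archive
#'
#' Bundles branch parameters, fusion/head parameters and the full
#' configuration; reloads to an inference-identical model.
#'
#' @param model an `hmtnet`.
#' @param path file path.
#' @export
save_hmtnet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_hmtnet
#' @export
load_hmtnet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "hmtnet")) stop("not an HMT-Net archive: ", path)
  obj
}
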