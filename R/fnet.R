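#' Backbone configuration for an F-Net
#'
#' An F-Net is a residual convolutional feature extractor with a global
#' average pooling (GAP) + fully connected (FC) binary head, trained for one
#' binary question about a conjunctival image. Two variants are provided:
#' \describe{
#'   \item{\code{"full"}}{a ResNet50-style 4-stage bottleneck network:
#'     2048 terminal feature channels, total spatial downsampling x32.}
#'   \item{\code{"tiny"}}{a reduced-depth residual network for desk-scale
#'     experiments: 64 terminal channels, downsampling x8.}
#' }
#'
#' @param variant `"tiny"` or `"full"`.
#' @param input_size input image side length in pixels; must be divisible by
#'   the variant's downsampling factor (8 for tiny, 32 for full).
#' @param weight_init `"random"` (He initialisation), `"external_checkpoint"`
#'   (supply `checkpoint`), or `"pretext"` (initialise from a self-contained
#'   vessel/no-vessel pretext task; see [pretext_pretrain()]).
#' @param checkpoint path to a checkpoint file when
#'   `weight_init = "external_checkpoint"`.
#' @param seed integer seed controlling parameter initialisation.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(variant = c("tiny", "full"),
                            input_size = NULL,
                            weight_init = c("random", "external_checkpoint", "pretext"),
                            checkpoint = NULL,
                            seed = 1L) {
  variant <- match.arg(variant)
  weight_init <- match.arg(weight_init)
  down <- if (variant == "tiny") 8L else 32L
  if (is.null(input_size)) input_size <- if (variant == "tiny") 64L else 224L
  input_size <- as.integer(input_size)
  if (input_size %% down != 0)
    stop("input_size (", input_size, ") must be divisible by the ",
         variant, " variant's downsampling factor (", down, ")")
  structure(list(variant = variant, input_size = input_size,
                 downsampling = down,
                 channels = if (variant == "tiny") 64L else 2048L,
                 weight_init = weight_init, checkpoint = checkpoint,
                 seed = as.integer(seed)),
            class = "backbone_config")
}

basic_block <- function(in_ch, out_ch, stride) {
  branch <- list(
    nn_conv(in_ch, out_ch, k = 3L, stride = stride),
    nn_bn(out_ch), nn_relu(),
    nn_conv(out_ch, out_ch, k = 3L, stride = 1L),
    nn_bn(out_ch))
  shortcut <- NULL
  if (stride != 1L || in_ch != out_ch)
    shortcut <- list(nn_conv(in_ch, out_ch, k = 1L, stride = stride, pad = 0L),
                     nn_bn(out_ch))
  nn_resblock(branch, shortcut)
}

bottleneck_block <- function(in_ch, mid_ch, out_ch, stride) {
  branch <- list(
    nn_conv(in_ch, mid_ch, k = 1L, stride = 1L, pad = 0L),
    nn_bn(mid_ch), nn_relu(),
    nn_conv(mid_ch, mid_ch, k = 3L, stride = stride),
    nn_bn(mid_ch), nn_relu(),
    nn_conv(mid_ch, out_ch, k = 1L, stride = 1L, pad = 0L),
    nn_bn(out_ch))
  shortcut <- NULL
  if (stride != 1L || in_ch != out_ch)
    shortcut <- list(nn_conv(in_ch, out_ch, k = 1L, stride = stride, pad = 0L),
                     nn_bn(out_ch))
  nn_resblock(branch, shortcut)
}

build_extractor <- function(config) {
  if (config$variant == "tiny") {
    layers <- list(nn_conv(3L, 16L, k = 3L, stride = 2L), nn_bn(16L), nn_relu(),
                   basic_block(16L, 32L, 2L),
                   basic_block(32L, 64L, 2L))
  } else {
    layers <- list(nn_conv(3L, 64L, k = 7L, stride = 2L, pad = 3L),
                   nn_bn(64L), nn_relu(),
                   nn_maxpool(k = 3L, stride = 2L, pad = 1L))
    stage <- function(in_ch, mid, out, n, stride) {
      blocks <- list(bottleneck_block(in_ch, mid, out, stride))
      for (i in seq_len(n - 1L))
        blocks <- c(blocks, list(bottleneck_block(out, mid, out, 1L)))
      blocks
    }
    layers <- c(layers,
                stage(64L, 64L, 256L, 3L, 1L),
                stage(256L, 128L, 512L, 4L, 2L),
                stage(512L, 256L, 1024L, 6L, 2L),
                stage(1024L, 512L, 2048L, 3L, 2L))
  }
  layers
}

#' Build an F-Net
#'
#' Constructs the residual feature extractor plus GAP+FC binary head.
#' Parameter initialisation is deterministic under `config$seed`.
#'
#' @param config a [backbone_config()].
#' @param provenance which question the network is (to be) trained for,
#'   e.g. `"Q1"`..`"Q4"`, `"Q5"` or `"sup"`.
#' @return An object of class `fnet`.
#' @export
build_fnet <- function(config, provenance = NA_character_) {
  stopifnot(inherits(config, "backbone_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  extractor <- build_extractor(config)
  head_fc <- nn_fc(config$channels, 2L)
  net <- structure(list(config = config, extractor = extractor,
                        head_fc = head_fc, frozen = FALSE,
                        provenance = provenance),
                   class = "fnet")
  if (config$weight_init == "external_checkpoint") {
    if (is.null(config$checkpoint)) stop("external_checkpoint requires a checkpoint path")
    net <- load_fnet_weights(net, config$checkpoint)
  }
  net
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Scale 8-bit or [0,1] images to roughly [-1, 1] network inputs.
prep_images <- function(images) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  x <- images
  storage.mode(x) <- "double"
  if (max(x) > 1.5) x <- x / 255
  (x - 0.5) * 2
}

#' Extract feature maps from an F-Net
#'
#' Runs the feature extractor (no head) in inference mode.
#'
#' @param fnet an [build_fnet()] object.
#' @param images array `(H, W, 3)` or `(H, W, 3, N)`, 8-bit or `[0,1]` scale.
#' @param training internal flag: use batch statistics and keep caches.
#' @return array `(h, w, C, N)` of feature maps.
#' @export
extract_features <- function(fnet, images, training = FALSE) {
  x <- prep_images(images)
  d <- dim(x)
  if (d[1] != fnet$config$input_size || d[2] != fnet$config$input_size)
    stop("input spatial size ", d[1], "x", d[2], " does not match configured ",
         fnet$config$input_size)
  net_forward(fnet$extractor, x, training = training)
}

gap_pool <- function(feat) {
  d <- dim(feat)
  matrix(.colMeans(matrix(feat, nrow = d[1] * d[2]), d[1] * d[2], d[3] * d[4]),
         d[3], d[4])
}

fc_forward <- function(fc, pooled) fc$W$v %*% pooled + fc$b$v

softmax_cols <- function(logits) {
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

#' Classify images with an F-Net
#'
#' Full forward pass: features, GAP, FC, softmax.
#'
#' @inheritParams extract_features
#' @return matrix `N x 2` of class probabilities, columns `p0` (negative)
#'   and `p1` (positive); rows sum to 1.
#' @export
classify <- function(fnet, images) {
  feat <- extract_features(fnet, images)
  p <- softmax_cols(fc_forward(fnet$head_fc, gap_pool(feat)))
  out <- t(p)
  colnames(out) <- c("p0", "p1")
  out
}

#' Freeze an F-Net
#'
#' Marks every parameter (and batch-norm statistics) as frozen: subsequent
#' training steps leave them bitwise unchanged. Idempotent.
#'
#' @param fnet an F-Net.
#' @return the frozen F-Net.
#' @export
freeze <- function(fnet) {
  set_frozen(fnet$extractor, TRUE)
  fnet$head_fc$frozen <- TRUE
  fnet$head_fc$W$frozen <- TRUE
  fnet$head_fc$b$frozen <- TRUE
  fnet$frozen <- TRUE
  fnet
}

fnet_params <- function(fnet) {
  c(collect_params(fnet$extractor),
    list(fnet$head_fc$W, fnet$head_fc$b))
}

#' Parameter checksum of a model
#'
#' Deterministic scalar fingerprint over all parameters (order-sensitive);
#' used to verify freeze conservation across training runs.
#'
#' @param model an `fnet` or `hmtnet` object, or a layer list.
#' @param part for `hmtnet`: `"all"`, `"branches"`, `"sup"` or `"fusion"`.
#' @return numeric scalar.
#' @export
param_checksum <- function(model, part = "all") {
  if (inherits(model, "fnet")) return(checksum_params(fnet_params(model)))
  if (inherits(model, "hmtnet")) return(checksum_params(hmtnet_params(model, part)))
  checksum_params(collect_params(model))
}

#' @export
print.fnet <- function(x, ...) {
  cat("F-Net (", x$config$variant, " variant, ", x$config$channels,
      " terminal channels, input ", x$config$input_size, "x",
      x$config$input_size, ")\n", sep = "")
  cat("  provenance:", x$provenance, " frozen:", x$frozen, "\n")
  invisible(x)
}

#' Save / load F-Net checkpoints
#'
#' Checkpoints are single-file archives embedding the `backbone_config`
#' fingerprint; loading into a mismatched architecture is refused with an
#' error naming the offending shapes.
#'
#' @param fnet an F-Net.
#' @param path file path.
#' @return `save_fnet` returns `path` invisibly; `load_fnet` returns the
#'   restored F-Net.
#' @export
save_fnet <- function(fnet, path) {
  saveRDS(fnet, path)
  invisible(path)
}

#' @rdname save_fnet
#' @export
load_fnet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "fnet")) stop("not an F-Net checkpoint: ", path)
  obj
}

load_fnet_weights <- function(net, path) {
  src <- load_fnet(path)
  if (!identical(src$config$variant, net$config$variant) ||
      !identical(src$config$input_size, net$config$input_size))
    stop("checkpoint/architecture mismatch: checkpoint is ",
         src$config$variant, "/", src$config$input_size,
         ", target is ", net$config$variant, "/", net$config$input_size)
  tp <- fnet_params(net); sp <- fnet_params(src)
  for (i in seq_along(tp)) {
    if (!identical(dim(tp[[i]]$v), dim(sp[[i]]$v)) ||
        length(tp[[i]]$v) != length(sp[[i]]$v))
      stop("checkpoint/architecture mismatch at parameter ", i,
           ": shapes ", paste(dim(sp[[i]]$v), collapse = "x"), " vs ",
           paste(dim(tp[[i]]$v), collapse = "x"))
    tp[[i]]$v <- sp[[i]]$v
  }
  copy_bn_stats(src$extractor, net$extractor)
  net
}

copy_bn_stats <- function(from, to) {
  for (i in seq_along(from)) {
    f <- from[[i]]; t <- to[[i]]
    if (f$type == "bn") { t$run_mean <- f$run_mean; t$run_var <- f$run_var }
    if (f$type == "resblock") {
      copy_bn_stats(f$branch, t$branch)
      if (!is.null(f$shortcut)) copy_bn_stats(f$shortcut, t$shortcut)
    }
  }
  invisible(to)
}
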