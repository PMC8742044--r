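# Class activation maps (CAM) for GAP+FC-headed models.

#' Compute a class activation map
#'
#' Classic GAP-weight CAM: the raw map is the sum over final-stage feature
#' channels of (FC weight for the target category x channel activation),
#' negatives clipped to 0, normalised to [0,1], and bilinearly upsampled to
#' the input size. Both the F-Net and the HMT-Net end in a GAP+FC head, the
#' exact setting in which this construction applies; for the HMT-Net the
#' map is computed on the fused (post-compression) features.
#'
#' @param model an `fnet` or `hmtnet`.
#' @param image a single `(H, W, 3)` image.
#' @param target_category 1 (abnormal / diseased) or 0.
#' @return object of class `cam_heatmap`: `values` (H x W in [0,1]),
#'   `raw` (pre-upsampling map), `target_category`, `model_id`,
#'   `constant` flag. A constant raw map is reported as all 0.5 with
#'   `constant = TRUE`.
#' @export
compute_cam <- function(model, image, target_category = 1L) {
  if (inherits(model, "fnet")) {
    feat <- extract_features(model, image)
    w <- model$head_fc$W$v[target_category + 1L, ]
    model_id <- paste0("fnet:", model$provenance)
    input_size <- model$config$input_size
  } else if (inherits(model, "hmtnet")) {
    feat <- fusion_forward(model, concat_channels(
      hmtnet_branch_features(model, image)), training = FALSE)
    w <- model$fusion$head_fc$W$v[target_category + 1L, ]
    model_id <- "hmtnet"
    input_size <- model$sup$config$input_size
  } else {
    stop("unsupported model: CAM requires a GAP+FC head (fnet or hmtnet)")
  }
  d <- dim(feat)
  fm <- matrix(feat[, , , 1], nrow = d[1] * d[2])  # (h*w) x C
  raw <- matrix(fm %*% w, d[1], d[2])
  raw[raw < 0] <- 0
  rng <- max(raw) - min(raw)
  if (rng < 1e-12) {
    norm <- matrix(0.5, d[1], d[2])
    constant <- TRUE
  } else {
    norm <- (raw - min(raw)) / rng
    constant <- FALSE
  }
  up <- bilinear_upsample(norm, input_size, input_size)
  if (constant) {
    up <- matrix(0.5, input_size, input_size)
  } else {
    # re-normalise after interpolation so min = 0 and max = 1 exactly
    up <- (up - min(up)) / (max(up) - min(up))
  }
  structure(list(values = up, raw = raw, target_category = target_category,
                 model_id = model_id, constant = constant),
            class = "cam_heatmap")
}

bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  # map output pixel centres onto input pixel centres
  ry <- (seq_len(H) - 0.5) * h / H + 0.5
  rx <- (seq_len(W) - 0.5) * w / W + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(rx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
       m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
       m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
       m[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

#' Lesion localization score of a heatmap
#'
#' The fraction of total heatmap mass falling inside a ground-truth lesion
#' mask. Under uniform attention the score equals the mask's area fraction,
#' which is therefore the natural baseline to beat.
#'
#' @param heatmap a [compute_cam()] result (or plain numeric matrix).
#' @param mask logical (or 0/1) matrix of the same size.
#' @return numeric in [0,1]; `NA` with a warning when the heatmap sums to 0.
#' @export
localization_score <- function(heatmap, mask) {
  v <- if (inherits(heatmap, "cam_heatmap")) heatmap$values else heatmap
  if (!all(dim(v) == dim(mask)))
    stop("heatmap/mask size mismatch: ", paste(dim(v), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"))
  tot <- sum(v)
  if (tot == 0) { warning("zero heatmap: localization undefined"); return(NA_real_) }
  sum(v[mask > 0]) / tot
}

#' Write CAM heatmap PNGs
#'
#' Writes the heatmap as a single-channel PNG plus an RGB overlay blending
#' the heatmap (red channel) onto the image at the given opacity.
#'
#' @param heatmap a `cam_heatmap`.
#' @param image the `(H, W, 3)` source image.
#' @param path_heat,path_overlay output PNG paths.
#' @param opacity overlay opacity in [0,1].
#' @export
write_cam <- function(heatmap, image, path_heat, path_overlay = NULL,
                      opacity = 0.5) {
  png::writePNG(heatmap$values, path_heat)
  if (!is.null(path_overlay)) {
    img <- image
    storage.mode(img) <- "double"
    if (max(img) > 1.5) img <- img / 255
    ov <- img
    ov[, , 1] <- (1 - opacity) * img[, , 1] + opacity * heatmap$values
    ov[, , 2] <- (1 - opacity) * img[, , 2]
    ov[, , 3] <- (1 - opacity) * img[, , 3]
    png::writePNG(pmin(pmax(ov, 0), 1), path_overlay)
  }
  invisible(path_heat)
}
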