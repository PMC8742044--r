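# Manifest I/O, image quality filtering, valid-region segmentation,
# augmentation and dataset splitting.

MANIFEST_CORE <- c("path", "subject_id", "q1", "q2", "q3", "q4", "q5",
                   "occlusion_fraction", "fold")

#' Read / write an image manifest
#'
#' The manifest is a comma-delimited text file with a header row and one row
#' per image: `path`, `subject_id`, binary labels `q1`..`q5` (empty =
#' unlabeled), `occlusion_fraction`, optional `fold`. Unknown columns are
#' preserved on a round trip.
#'
#' @param path manifest file path.
#' @return `load_manifest` returns a `data.frame`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "subject_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed manifest header: missing column(s) ",
         paste(miss, collapse = ", "))
  for (q in c("q1", "q2", "q3", "q4", "q5")) {
    if (!q %in% names(df)) { df[[q]] <- rep(NA_integer_, nrow(df)); next }
    v <- df[[q]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad))
      stop("parse error: non-binary label in column ", q, ", row ", bad[1])
    df[[q]] <- as.integer(v)
  }
  if (!"occlusion_fraction" %in% names(df))
    df$occlusion_fraction <- rep(NA_real_, nrow(df))
  if (!"fold" %in% names(df)) df$fold <- rep(NA_integer_, nrow(df))
  df
}

#' @rdname load_manifest
#' @param records manifest `data.frame`.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Image quality metrics
#'
#' Contrast is the standard deviation of grayscale pixel intensity; the blur
#' score is the variance of a Laplacian response (sharper images score
#' higher).
#'
#' @param image `H x W x 3` array, 8-bit or `[0,1]`.
#' @return numeric scalar.
#' @export
image_contrast <- function(image) {
  g <- to_gray(image)
  stats::sd(g)
}

#' @rdname image_contrast
#' @export
image_blur_score <- function(image) {
  g <- to_gray(image)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  r <- EBImage::filter2(g, lap)
  stats::var(as.numeric(r))
}

to_gray <- function(image) {
  x <- image
  storage.mode(x) <- "double"
  if (max(x) > 1.5) x <- x / 255
  if (length(dim(x)) == 3L)
    0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  else x
}

#' Filter out poor-quality images
#'
#' Reproduces the study-style exclusion rules: an image is excluded iff its
#' eyelid occlusion exceeds `occlusion_max` of the whole image (default the
#' 1/10 rule), OR its contrast is below `contrast_min`, OR its blur score is
#' below `blur_min`. Metrics missing from the manifest are computed from the
#' images on disk. Each exclusion carries its triggering rule.
#'
#' @param records manifest `data.frame`.
#' @param occlusion_max maximum tolerated occlusion fraction (default 0.1).
#' @param contrast_min,blur_min minimum scores; `NULL` disables the rule.
#' @return list with elements `kept` (data.frame) and `excluded`
#'   (data.frame with a `reason` column).
#' @export
quality_filter <- function(records, occlusion_max = 0.1,
                           contrast_min = NULL, blur_min = NULL) {
  n <- nrow(records)
  occ <- records$occlusion_fraction
  occ[is.na(occ)] <- 0
  contrast <- records$contrast_score
  blur <- records$blur_score
  need_contrast <- !is.null(contrast_min) &&
    (is.null(contrast) || anyNA(contrast))
  need_blur <- !is.null(blur_min) && (is.null(blur) || anyNA(blur))
  if (need_contrast || need_blur) {
    if (is.null(contrast)) contrast <- rep(NA_real_, n)
    if (is.null(blur)) blur <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if ((need_contrast && is.na(contrast[i])) ||
          (need_blur && is.na(blur[i]))) {
        if (!file.exists(records$path[i]))
          stop("missing quality metrics and unreadable image: ",
               records$path[i])
        img <- png::readPNG(records$path[i])
        if (is.na(contrast[i])) contrast[i] <- image_contrast(img)
        if (is.na(blur[i])) blur[i] <- image_blur_score(img)
      }
    }
  }
  reason <- rep(NA_character_, n)
  reason[!is.null(blur_min) & !is.na(blur) & blur < blur_min] <- "blur"
  if (!is.null(contrast_min))
    reason[!is.na(contrast) & contrast < contrast_min] <- "contrast"
  reason[occ > occlusion_max] <- "occlusion"
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  else excluded$reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' Quality thresholds from a reference pool
#'
#' Default contrast/blur thresholds: the 5th percentile of the scores of a
#' reference (e.g. healthy) image pool.
#'
#' @param records manifest rows whose images define the reference pool.
#' @return list with `contrast_min` and `blur_min`.
#' @export
default_quality_thresholds <- function(records) {
  sc <- vapply(records$path, function(p) {
    img <- png::readPNG(p)
    c(image_contrast(img), image_blur_score(img))
  }, numeric(2))
  list(contrast_min = unname(stats::quantile(sc[1, ], 0.05)),
       blur_min = unname(stats::quantile(sc[2, ], 0.05)))
}

#' Segment the valid (vessel-bearing) region of an image
#'
#' Heuristic segmentation of the region that carries usable vasculature:
#' a local-contrast statistic (5x5 windowed standard deviation of the
#' grayscale image) is thresholded adaptively (Otsu), the largest connected
#' component is kept, and the mask is closed morphologically and
#' hole-filled. Flat areas such as eyelid occluders fall below the
#' threshold. A constant image yields an empty mask with
#' `attr(mask, "constant") = TRUE`.
#'
#' @param image `H x W x 3` (or grayscale matrix), 8-bit or `[0,1]`.
#' @return logical matrix mask with attribute `constant`.
#' @export
segment_valid_region <- function(image) {
  g <- to_gray(image)
  if (stats::sd(g) < 1e-10) {
    m <- matrix(FALSE, nrow(g), ncol(g))
    attr(m, "constant") <- TRUE
    warning("constant image: returning empty valid-region mask")
    return(m)
  }
  k <- matrix(1 / 25, 5, 5)
  m1 <- EBImage::filter2(g, k)
  m2 <- EBImage::filter2(g * g, k)
  s <- sqrt(pmax(m2 - m1 * m1, 0))
  s <- s / max(s)
  th <- EBImage::otsu(EBImage::Image(s), range = c(0, 1))
  # Otsu always splits the histogram somewhere; on homogeneously textured
  # images that split would separate vessel edges from the (equally valid)
  # rest. Bounding the threshold by half the median texture keeps the whole
  # textured area while flat occluders still fall below it.
  th <- min(th, 0.5 * stats::median(s))
  mask <- s > th
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  brush <- EBImage::makeBrush(7, shape = "disc")
  mask <- EBImage::closing(mask * 1, brush)
  mask <- EBImage::fillHull(mask) > 0
  m <- matrix(as.logical(mask), nrow(g), ncol(g))
  attr(m, "constant") <- FALSE
  m
}

#' Augmentation configuration
#'
#' @param rotation_angles rotation angles in degrees.
#' @param horizontal_flip,vertical_flip include flipped copies.
#' @param background_noise_sd Gaussian noise sd (8-bit units) added outside
#'   the valid-region mask; the masked (valid) pixels stay bitwise
#'   unchanged.
#' @param mask_source `"provided"` (caller passes the mask) or
#'   `"heuristic"` ([segment_valid_region()] is applied).
#' @param fill_color length-3 RGB used to fill out-of-frame pixels after
#'   rotation; defaults to the image border mean.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_angles = c(90, 180, 270),
                                horizontal_flip = TRUE, vertical_flip = TRUE,
                                background_noise_sd = 10,
                                mask_source = c("provided", "heuristic"),
                                fill_color = NULL) {
  if (any(!is.finite(rotation_angles))) stop("rotation angles must be finite")
  if (background_noise_sd < 0) stop("background_noise_sd must be >= 0")
  structure(list(rotation_angles = rotation_angles,
                 horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip,
                 background_noise_sd = background_noise_sd,
                 mask_source = match.arg(mask_source),
                 fill_color = fill_color),
            class = "augmentation_config")
}

rotate_image <- function(image, angle, fill) {
  a <- angle %% 360
  if (a == 0) return(image)
  if (a %% 90 == 0) {
    rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
    out <- image
    for (k in seq_len(a %/% 90)) {
      out <- simplify2array(lapply(1:3, function(ch) rot90(out[, , ch])))
    }
    return(out)
  }
  # general angle: inverse nearest-neighbour mapping about the centre
  H <- dim(image)[1]; W <- dim(image)[2]
  th <- -a * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gr <- expand.grid(r = seq_len(H), c = seq_len(W))
  sr <- round(cy + (gr$r - cy) * cos(th) - (gr$c - cx) * sin(th))
  sc <- round(cx + (gr$r - cy) * sin(th) + (gr$c - cx) * cos(th))
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out <- array(rep(fill, each = H * W), dim(image))
  for (ch in 1:3) {
    pl <- matrix(fill[ch], H, W)
    src <- image[, , ch]
    pl[cbind(gr$r[ok], gr$c[ok])] <- src[cbind(sr[ok], sc[ok])]
    out[, , ch] <- pl
  }
  out
}

#' Augment an image
#'
#' Produces the identity image, one copy per configured rotation and flip,
#' and one background-noise copy in which pixels inside the valid-region
#' mask are bitwise unchanged while noise is added elsewhere. Rotated
#' out-of-frame pixels are filled with the background color.
#'
#' @param image `H x W x 3` 8-bit integer array.
#' @param mask logical valid-region mask of the same spatial size (required
#'   when `config$mask_source = "provided"`).
#' @param config an [augmentation_config()].
#' @return named list of augmented images (`identity`, `rot<angle>`...,
#'   `hflip`, `vflip`, `noise`).
#' @export
augment <- function(image, mask = NULL, config = augmentation_config()) {
  if (config$mask_source == "heuristic" || is.null(mask))
    mask <- segment_valid_region(image)
  d <- dim(image)
  if (!all(dim(mask) == d[1:2]))
    stop("mask/image size mismatch: ", paste(dim(mask), collapse = "x"),
         " vs ", paste(d[1:2], collapse = "x"))
  fill <- config$fill_color
  if (is.null(fill))
    fill <- round(c(mean(image[, , 1]), mean(image[, , 2]), mean(image[, , 3])))
  out <- list(identity = image)
  for (a in config$rotation_angles) {
    im <- rotate_image(image, a, fill)
    storage.mode(im) <- storage.mode(image)
    out[[paste0("rot", a)]] <- im
  }
  if (config$horizontal_flip)
    out$hflip <- image[, d[2]:1, , drop = FALSE]
  if (config$vertical_flip)
    out$vflip <- image[d[1]:1, , , drop = FALSE]
  noisy <- image
  storage.mode(noisy) <- "integer"
  bg <- !mask
  nbg <- sum(bg)
  for (ch in 1:3) {
    pl <- noisy[, , ch]
    v <- pl[bg] + as.integer(round(stats::rnorm(nbg, sd = config$background_noise_sd)))
    pl[bg] <- pmin(pmax(v, 0L), 255L)
    noisy[, , ch] <- pl
  }
  out$noise <- noisy
  out
}

#' Assign cross-validation folds
#'
#' Folds are stratified by the disease label `q5` (balanced to within one
#' unit per stratum). With `unit = "subject"` (the default) all images of a
#' subject land in the same fold, preventing same-eye leakage across folds;
#' `unit = "image"` deals images independently. Deterministic under `seed`.
#'
#' @param records manifest `data.frame`.
#' @param k number of folds (default 5, the study protocol).
#' @param unit `"subject"` or `"image"`.
#' @param seed integer seed.
#' @return An object of class `split_plan`: `data.frame` mapping `path` to
#'   `fold`, with attributes `k`, `unit`, `seed`.
#' @export
make_folds <- function(records, k = 5L, unit = c("subject", "image"),
                       seed = 1L) {
  unit <- match.arg(unit)
  if (k < 2) stop("k must be at least 2")
  if (!nrow(records)) stop("no records to split")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (unit == "image") {
    if (k > nrow(records)) stop("k exceeds the number of images")
    fold <- integer(nrow(records))
    for (s in unique(records$q5)) {
      idx <- which(records$q5 == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    subj <- unique(records[, c("subject_id", "q5")])
    if (k > nrow(subj)) stop("k exceeds the number of subjects")
    sfold <- integer(nrow(subj))
    for (s in unique(subj$q5)) {
      idx <- which(subj$q5 == s)
      idx <- idx[sample.int(length(idx))]
      sfold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold <- sfold[match(records$subject_id, subj$subject_id)]
  }
  plan <- data.frame(path = records$path, fold = fold,
                     stringsAsFactors = FALSE)
  structure(plan, k = as.integer(k), unit = unit, seed = as.integer(seed),
            class = c("split_plan", "data.frame"))
}

#' Partition records into Stage-I and Stage-II datasets
#'
#' Disjoint, q5-stratified partition of the records into Dataset-I (used to
#' train the sub-question networks) and Dataset-II (used to train the fused
#' disease classifier). Deterministic under `seed`.
#'
#' @param records manifest `data.frame`.
#' @param fraction_stage1 fraction assigned to Dataset-I, in (0, 1).
#' @param unit `"subject"` or `"image"`.
#' @param seed integer seed.
#' @return `data.frame` mapping `path` to `stage` (`"I"` or `"II"`).
#' @export
split_stage_datasets <- function(records, fraction_stage1 = 0.5,
                                 unit = c("subject", "image"), seed = 1L) {
  unit <- match.arg(unit)
  if (!(fraction_stage1 > 0 && fraction_stage1 < 1))
    stop("fraction_stage1 must lie strictly between 0 and 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assign_units <- function(ids, strata) {
    stage <- character(length(ids))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      n1 <- round(length(idx) * fraction_stage1)
      stage[idx] <- c(rep("I", n1), rep("II", length(idx) - n1))
    }
    stage
  }
  if (unit == "image") {
    stage <- assign_units(records$path, records$q5)
  } else {
    subj <- unique(records[, c("subject_id", "q5")])
    sstage <- assign_units(subj$subject_id, subj$q5)
    stage <- sstage[match(records$subject_id, subj$subject_id)]
  }
  if (!any(stage == "I") || !any(stage == "II"))
    stop("degenerate partition: one side is empty")
  data.frame(path = records$path, stage = stage, stringsAsFactors = FALSE)
}

#' Serialize / read a split plan sidecar
#'
#' @param plan a [make_folds()] plan, optionally with a `stage` column.
#' @param path sidecar file path (comma-delimited text).
#' @export
write_split_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

# Load manifest images into an (H, W, 3, N) 8-bit array.
load_images <- function(records) {
  imgs <- lapply(records$path, function(p) png::readPNG(p) * 255)
  d <- dim(imgs[[1]])
  arr <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- imgs[[i]][, , 1:3]
  arr
}
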