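#' Synthetic conjunctiva dataset specification
#'
#' Describes a corpus of synthetic conjunctiva-like images: pale-sclera
#' backgrounds crossed by dark-red vessels rendered as smoothed random
#' curves, with four controllable vascular abnormalities mirroring the
#' sub-questions of the screening task:
#' Q1 vessel widening, Q2 abnormal perivascular color, Q3 tortuosity /
#' morphological distortion, Q4 microaneurysms. The disease label Q5 is a
#' subject-level status linked to the abnormalities statistically (each
#' abnormality is a Bernoulli draw whose rate depends on the subject's
#' status), never deterministically.
#'
#' The default corpus shape emulates a screening study of 611 images:
#' 405 images from 68 diseased subjects and 206 from 62 healthy subjects,
#' at desk scale (64 x 64 pixels).
#'
#' @param image_size square image side in pixels (>= 32).
#' @param n_diseased_subjects,n_healthy_subjects subject counts.
#' @param n_images_diseased,n_images_healthy total image counts per group,
#'   allocated near-evenly across subjects; set to `NULL` to draw
#'   per-subject counts from `images_per_subject_range` instead.
#' @param images_per_subject_range integer range for per-subject draws when
#'   totals are `NULL`.
#' @param vessels_per_image_range integer range of vessels per image.
#' @param base_vessel_width stroke width in pixels for normal vessels.
#' @param width_factor_abnormal multiplier (> 1) applied when Q1 is present.
#' @param perivascular_color_shift length-3 per-channel 8-bit delta applied
#'   to a band around vessels when Q2 is present.
#' @param tortuosity_amplitude_normal,tortuosity_amplitude_abnormal maximum
#'   perpendicular wiggle in pixels (Q3 uses the abnormal value).
#' @param microaneurysm_count_range_abnormal integer range of dark dots when
#'   Q4 is present (0 dots when absent).
#' @param p_abnormal_given_diseased,p_abnormal_given_healthy probability
#'   that each abnormality (independently) is present on an image of a
#'   diseased / healthy subject.
#' @param background_mean_color length-3 RGB background mean (0-255).
#' @param pixel_noise_sd additive Gaussian pixel noise, 8-bit units.
#' @param occlusion_probability,occlusion_fraction_range probability and
#'   area-fraction range of a flat eyelid-like occluder painted over one
#'   image edge (quality-filter fixtures).
#' @param seed master seed; identical spec + seed reproduce the dataset
#'   byte-for-byte.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 64L,
                           n_diseased_subjects = 68L,
                           n_healthy_subjects = 62L,
                           n_images_diseased = 405L,
                           n_images_healthy = 206L,
                           images_per_subject_range = c(2L, 6L),
                           vessels_per_image_range = c(2L, 4L),
                           base_vessel_width = 2.5,
                           width_factor_abnormal = 1.9,
                           perivascular_color_shift = c(35, -25, -25),
                           tortuosity_amplitude_normal = 1.5,
                           tortuosity_amplitude_abnormal = 6,
                           microaneurysm_count_range_abnormal = c(3L, 6L),
                           p_abnormal_given_diseased = 0.75,
                           p_abnormal_given_healthy = 0.15,
                           background_mean_color = c(205, 175, 165),
                           pixel_noise_sd = 6,
                           occlusion_probability = 0,
                           occlusion_fraction_range = c(0.02, 0.3),
                           seed = 1L) {
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  probs <- c(spec$p_abnormal_given_diseased, spec$p_abnormal_given_healthy,
             spec$occlusion_probability)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (spec$width_factor_abnormal <= 1)
    stop("configuration error: width_factor_abnormal must exceed 1")
  if (spec$image_size < 32)
    stop("configuration error: image_size must be at least 32")
  if (length(spec$perivascular_color_shift) != 3)
    stop("configuration error: perivascular_color_shift must have 3 channels")
  invisible(spec)
}

#' Draw abnormality presence flags
#'
#' Each of the four abnormalities is present independently with probability
#' `p_abnormal_given_diseased` for a diseased subject's image, or
#' `p_abnormal_given_healthy` for a healthy one. Uses the current RNG state.
#'
#' @param spec a [synthetic_spec()].
#' @param diseased logical (or 0/1) subject disease status.
#' @return integer vector of four 0/1 flags (Q1..Q4).
#' @export
sample_abnormality_flags <- function(spec, diseased) {
  validate_synthetic_spec(spec)
  p <- if (isTRUE(as.logical(diseased))) spec$p_abnormal_given_diseased
       else spec$p_abnormal_given_healthy
  as.integer(stats::runif(4) < p)
}

# Stamp a disc of the given radius at each continuous (x, y) centre into a
# logical mask; pixels are included by distance to the true (subpixel)
# centre so that measured stroke widths track the requested radius.
stamp_discs <- function(mask, xs, ys, radius) {
  S <- nrow(mask)
  r <- max(radius, 0.5)
  ri <- ceiling(r + 0.5)
  off <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  m <- nrow(off)
  n <- length(xs)
  px <- outer(off$dx, round(xs), "+")
  py <- outer(off$dy, round(ys), "+")
  ddx <- px - rep(xs, each = m)
  ddy <- py - rep(ys, each = m)
  keep <- ddx * ddx + ddy * ddy <= r * r &
    px >= 1 & px <= S & py >= 1 & py <= S
  mask[cbind(as.integer(px[keep]), as.integer(py[keep]))] <- TRUE
  mask
}

# A smoothed random curve crossing the canvas; returns dense (x, y) points
# plus the rounded centreline pixel set.
vessel_path <- function(S, amplitude) {
  n <- 4L * S
  side <- sample.int(2L, 1L)  # 1: left-right, 2: top-bottom
  a <- stats::runif(1, 0.15, 0.85) * S
  b <- stats::runif(1, 0.15, 0.85) * S
  t <- seq(0, 1, length.out = n)
  if (side == 1L) { x0 <- t * (S - 1) + 1; y0 <- a + t * (b - a) }
  else { y0 <- t * (S - 1) + 1; x0 <- a + t * (b - a) }
  # random-walk offset smoothed with a fixed moving-average kernel
  w <- max(5L, as.integer(S / 4))
  raw <- cumsum(stats::rnorm(n))
  kern <- rep(1 / w, w)
  sm <- stats::filter(raw, kern, sides = 2)
  sm[is.na(sm)] <- 0
  sm <- sm - mean(sm)
  mx <- max(abs(sm))
  if (mx > 0) sm <- sm / mx * amplitude
  # offset perpendicular to the main direction
  if (side == 1L) { x <- x0; y <- y0 + as.numeric(sm) }
  else { x <- x0 + as.numeric(sm); y <- y0 }
  x <- pmin(pmax(x, 1), S); y <- pmin(pmax(y, 1), S)
  list(x = x, y = y,
       centerline = unique(cbind(round(x), round(y))))
}

#' Render one synthetic conjunctiva image
#'
#' Vessels are drawn as smoothed random curves stroked at
#' `base_vessel_width`; Q1 widens every stroke by `width_factor_abnormal`,
#' Q2 tints a dilated perivascular band, Q3 switches to the abnormal
#' tortuosity amplitude, Q4 places dark microaneurysm dots adjacent to
#' vessels. A ground-truth mask is recorded per applied abnormality, plus
#' the overall vessel and centreline masks. Additive Gaussian noise and an
#' optional flat edge occluder complete the image. Uses the current RNG
#' state; see [generate_dataset()] for per-image seeding.
#'
#' @param spec a [synthetic_spec()].
#' @param flags integer vector of four 0/1 abnormality flags (Q1..Q4).
#' @param subject_id opaque subject identifier.
#' @param q5 subject disease status (0/1).
#' @return An object of class `generated_sample`: fields `image`
#'   (H x W x 3 integer, 0-255), `q1`..`q5`, `subject_id`, `vessel_mask`,
#'   `centerline_mask`, `lesion_masks` (list of 4 logical matrices),
#'   `occlusion_fraction`, `rng_seed_used`.
#' @export
render_conjunctiva <- function(spec, flags, subject_id = "s1", q5 = NA_integer_) {
  validate_synthetic_spec(spec)
  S <- as.integer(spec$image_size)
  flags <- as.integer(flags)
  stopifnot(length(flags) == 4)
  width <- spec$base_vessel_width * if (flags[1]) spec$width_factor_abnormal else 1
  if (width >= S / 2)
    stop("generation error: image_size too small for requested vessel width")
  amp <- if (flags[3]) spec$tortuosity_amplitude_abnormal
         else spec$tortuosity_amplitude_normal

  img <- array(rep(spec$background_mean_color, each = S * S), c(S, S, 3))
  vessel_mask <- matrix(FALSE, S, S)
  center_mask <- matrix(FALSE, S, S)
  nv <- sample(seq(spec$vessels_per_image_range[1],
                   spec$vessels_per_image_range[2]), 1L)
  centers <- NULL
  for (v in seq_len(nv)) {
    p <- vessel_path(S, amp)
    vessel_mask <- stamp_discs(vessel_mask, p$x, p$y, width / 2)
    center_mask[p$centerline] <- TRUE
    centers <- rbind(centers, p$centerline)
  }
  vessel_color <- c(120, 25, 35) + stats::rnorm(3, sd = 5)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[vessel_mask] <- vessel_color[ch]
    img[, , ch] <- pl
  }

  lesion <- list(q1 = matrix(FALSE, S, S), q2 = matrix(FALSE, S, S),
                 q3 = matrix(FALSE, S, S), q4 = matrix(FALSE, S, S))
  if (flags[1]) lesion$q1 <- vessel_mask
  if (flags[3]) lesion$q3 <- vessel_mask
  if (flags[2]) {
    band <- dilate_mask(vessel_mask, 2L) & !vessel_mask
    if (!any(band)) band <- dilate_mask(vessel_mask, 3L) & !vessel_mask
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[band] <- pl[band] + spec$perivascular_color_shift[ch]
      img[, , ch] <- pl
    }
    lesion$q2 <- band
  }
  if (flags[4]) {
    k <- sample(seq(spec$microaneurysm_count_range_abnormal[1],
                    spec$microaneurysm_count_range_abnormal[2]), 1L)
    idx <- sample(nrow(centers), min(k, nrow(centers)))
    ang <- stats::runif(length(idx), 0, 2 * pi)
    dist <- spec$base_vessel_width / 2 + stats::runif(length(idx), 1.5, 3)
    mx <- centers[idx, 1] + cos(ang) * dist
    my <- centers[idx, 2] + sin(ang) * dist
    dots <- matrix(FALSE, S, S)
    dots <- stamp_discs(dots, mx, my, 1.2)
    if (!any(dots)) dots[pmin(pmax(round(mx[1]), 1), S),
                         pmin(pmax(round(my[1]), 1), S)] <- TRUE
    dot_color <- c(70, 15, 25)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[dots] <- dot_color[ch]
      img[, , ch] <- pl
    }
    lesion$q4 <- dots
  }

  img <- img + stats::rnorm(length(img), sd = spec$pixel_noise_sd)

  occ_frac <- 0
  if (spec$occlusion_probability > 0 &&
      stats::runif(1) < spec$occlusion_probability) {
    f <- stats::runif(1, spec$occlusion_fraction_range[1],
                      spec$occlusion_fraction_range[2])
    rows <- max(1L, round(f * S))
    edge <- sample.int(4L, 1L)
    sel <- switch(edge,
                  list(seq_len(rows), seq_len(S)),
                  list(S - seq_len(rows) + 1L, seq_len(S)),
                  list(seq_len(S), seq_len(rows)),
                  list(seq_len(S), S - seq_len(rows) + 1L))
    img[sel[[1]], sel[[2]], ] <- rep(c(28, 22, 22), each = length(sel[[1]]) * length(sel[[2]]))
    occ_frac <- length(sel[[1]]) * length(sel[[2]]) / (S * S)
  }

  storage.mode(img) <- "integer"
  img[img < 0L] <- 0L
  img[img > 255L] <- 255L

  structure(list(image = img,
                 q1 = flags[1], q2 = flags[2], q3 = flags[3], q4 = flags[4],
                 q5 = as.integer(q5), subject_id = subject_id,
                 vessel_mask = vessel_mask, centerline_mask = center_mask,
                 lesion_masks = lesion, occlusion_fraction = occ_frac,
                 rng_seed_used = NA_integer_),
            class = "generated_sample")
}

dilate_mask <- function(mask, radius) {
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  EBImage::dilate(mask * 1, kern) > 0
}

#' Generate a synthetic dataset on disk
#'
#' Draws subject statuses and per-subject image counts, renders every image
#' under a per-image seed derived from the master seed, writes images (and
#' optionally ground-truth masks) as 8-bit PNG, and returns the manifest.
#' Identical spec + seed reproduce the output byte-for-byte.
#'
#' @param spec a [synthetic_spec()].
#' @param output_dir writable directory; created if absent.
#' @param write_masks also write per-abnormality mask PNGs (0/255 single
#'   channel) under `masks/`.
#' @param keep_images additionally return the rendered samples in memory
#'   (used by the training drivers to avoid re-reading PNGs).
#' @param write_images write the image PNGs (default); disable for purely
#'   in-memory corpora (requires `keep_images = TRUE`), where manifest paths
#'   are then identifiers rather than files.
#' @return the manifest `data.frame` (columns `path`, `subject_id`,
#'   `q1`..`q5`, `occlusion_fraction`, `fold`), invisibly carrying the
#'   samples in `attr(, "samples")` when `keep_images = TRUE`.
#' @export
generate_dataset <- function(spec, output_dir, write_masks = FALSE,
                             keep_images = FALSE, write_images = TRUE) {
  if (!write_images && !keep_images)
    stop("write_images = FALSE requires keep_images = TRUE")
  validate_synthetic_spec(spec)
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", output_dir)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  alloc <- function(n_sub, total, prefix) {
    if (is.null(total)) {
      counts <- sample(seq(spec$images_per_subject_range[1],
                           spec$images_per_subject_range[2]),
                       n_sub, replace = TRUE)
    } else {
      base <- total %/% n_sub
      counts <- rep(base, n_sub)
      extra <- total - base * n_sub
      if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    }
    data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n_sub)),
               n = counts, stringsAsFactors = FALSE)
  }
  dsub <- alloc(spec$n_diseased_subjects, spec$n_images_diseased, "D")
  hsub <- alloc(spec$n_healthy_subjects, spec$n_images_healthy, "H")
  subjects <- rbind(cbind(dsub, q5 = 1L), cbind(hsub, q5 = 0L))

  plan <- subjects[rep(seq_len(nrow(subjects)), subjects$n),
                   c("subject_id", "q5")]
  n_img <- nrow(plan)
  seeds <- sample.int(.Machine$integer.max - 1L, n_img)

  rows <- vector("list", n_img)
  samples <- if (keep_images) vector("list", n_img) else NULL
  if (write_masks) dir.create(file.path(output_dir, "masks"), showWarnings = FALSE)
  for (i in seq_len(n_img)) {
    set.seed(seeds[i])
    flags <- sample_abnormality_flags(spec, plan$q5[i] == 1L)
    smp <- render_conjunctiva(spec, flags, plan$subject_id[i], plan$q5[i])
    smp$rng_seed_used <- seeds[i]
    fname <- sprintf("img_%05d.png", i)
    path <- file.path(output_dir, fname)
    if (write_images) png::writePNG(smp$image / 255, path)
    if (write_masks) {
      for (q in 1:4)
        png::writePNG(smp$lesion_masks[[q]] * 1,
                      file.path(output_dir, "masks",
                                sprintf("img_%05d_q%d.png", i, q)))
      png::writePNG(smp$vessel_mask * 1,
                    file.path(output_dir, "masks",
                              sprintf("img_%05d_vessel.png", i)))
    }
    rows[[i]] <- data.frame(path = path, subject_id = plan$subject_id[i],
                            q1 = smp$q1, q2 = smp$q2, q3 = smp$q3, q4 = smp$q4,
                            q5 = smp$q5,
                            occlusion_fraction = smp$occlusion_fraction,
                            fold = NA_integer_, stringsAsFactors = FALSE)
    if (keep_images) samples[[i]] <- smp
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(output_dir, "manifest.csv"))
  if (keep_images) attr(manifest, "samples") <- samples
  manifest
}

#' Stack kept-in-memory samples into an image array
#'
#' @param manifest a [generate_dataset()] result produced with
#'   `keep_images = TRUE`.
#' @return `(H, W, 3, N)` numeric array of 8-bit images.
#' @export
samples_to_array <- function(manifest) {
  smps <- attr(manifest, "samples")
  if (is.null(smps)) stop("manifest carries no in-memory samples")
  d <- dim(smps[[1]]$image)
  arr <- array(0, c(d[1], d[2], 3, length(smps)))
  for (i in seq_along(smps)) arr[, , , i] <- smps[[i]]$image
  arr
}

#' Measure mean stroke width of a rendered vessel mask
#'
#' Mask area divided by centreline length (centreline pixel count), the
#' geometry used to verify the Q1 widening factor.
#'
#' @param sample a `generated_sample`.
#' @return numeric mean width in pixels.
#' @export
mean_stroke_width <- function(sample) {
  sum(sample$vessel_mask) / sum(sample$centerline_mask)
}
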