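# Shared fixtures, memoised so expensive objects build once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# A small labelled corpus: 16 subjects, 48 images, with masks on disk.
fix_small_spec <- function() {
  synthetic_spec(n_diseased_subjects = 8L, n_healthy_subjects = 8L,
                 n_images_diseased = 24L, n_images_healthy = 24L,
                 seed = 101L)
}

fix_small_corpus <- function() {
  memo("small_corpus", function() {
    dir <- file.path(tempdir(), "hmtnet_small_corpus")
    man <- generate_dataset(fix_small_spec(), dir, write_masks = TRUE,
                            keep_images = TRUE)
    list(dir = dir, manifest = man, images = samples_to_array(man),
         samples = attr(man, "samples"))
  })
}

# A tiny backbone at reduced input size for fast structural tests.
fix_tiny_cfg <- function(seed = 1L, input = 32L)
  backbone_config("tiny", input_size = input, seed = seed)

# Strongly separable mini dataset for a given question.
fix_separable <- function(question = "q2", n_per_class = 8L, seed = 11L,
                          image_size = 64L) {
  spec <- synthetic_spec(image_size = image_size, seed = seed)
  imgs <- array(0, c(image_size, image_size, 3, 2L * n_per_class))
  labs <- integer(2L * n_per_class)
  qi <- match(question, c("q1", "q2", "q3", "q4"))
  for (i in seq_len(2L * n_per_class)) {
    flags <- c(0L, 0L, 0L, 0L)
    lab <- as.integer(i <= n_per_class)
    flags[qi] <- lab
    set.seed(seed * 1000L + i)
    smp <- render_conjunctiva(spec, flags, "s", 0L)
    imgs[, , , i] <- smp$image
    labs[i] <- lab
  }
  rec <- data.frame(path = sprintf("sep_%s_%02d", question,
                                   seq_along(labs)))
  rec[[question]] <- labs
  list(records = rec, images = imgs, labels = labs)
}

# Trained tiny Q2 network shared by training/CAM tests.
fix_trained_q2 <- function() {
  memo("trained_q2", function() {
    co <- fix_small_corpus()
    train_stage1(co$manifest, "q2",
                 backbone = backbone_config("tiny", 64, seed = 5L),
                 config = train_config(epochs = 8L, batch_size = 16L,
                                       lr = 2e-3, seed = 5L),
                 images = co$images)
  })
}

fix_frozen_branches <- function(input = 32L) {
  memo(paste0("frozen_branches_", input), function() {
    br <- lapply(1:4, function(i)
      freeze(build_fnet(fix_tiny_cfg(seed = i, input = input),
                        paste0("Q", i))))
    names(br) <- paste0("q", 1:4)
    br
  })
}
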