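# Shared fixtures, built in code at test time.

# small random slide with reproducible pixels
random_slide <- function(w = 64, h = 64, seed = 1, id = "fixture") {
  set.seed(seed)
  px <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
  slide_image(px, id)
}

# slide filled with one RGB colour
flat_slide <- function(rgb, w = 32, h = 32, id = "flat") {
  px <- array(0L, c(h, w, 3))
  for (c in 1:3) px[, , c] <- rgb[c]
  slide_image(px, id)
}

square_region <- function(x0, y0, side, pattern = "GP3", id = "fixture") {
  annotation_region(id, cbind(c(x0, x0 + side, x0 + side, x0),
                              c(y0, y0, y0 + side, y0 + side)), pattern)
}

# random simple (star-shaped) polygon around a centre; jittered regular
# angles keep every angular gap below pi, which guarantees simplicity
random_simple_polygon <- function(n = 8, cx = 50, cy = 50, rmin = 10, rmax = 40) {
  ang <- sort((seq_len(n) - 1) * 2 * pi / n + stats::runif(n, 0, 1.6 * pi / n))
  rad <- stats::runif(n, rmin, rmax)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# The shared synthetic dataset for end-to-end tests: generated once per test
# session into a temp directory and reused. 30 slides: 12 train / 6
# validation / 12 test, balanced over the three labels.
demo_dataset <- local({
  manifest <- NULL
  function() {
    if (is.null(manifest)) {
      dir <- file.path(tempdir(), "wsitriage_demo_ds")
      if (!file.exists(file.path(dir, "manifest.csv")))
        generate_dataset(10, dir, seed = 20260930)
      manifest <<- read_manifest(file.path(dir, "manifest.csv"))
    }
    manifest
  }
})

# desk-scale training configuration used by the end-to-end tests: 128-px
# tiles, published optimizer settings, warmup long enough for a cold-started
# (non-pretrained) backbone to rank tiles sensibly before hard mining, and
# epochs dense enough for the fixed fine-tuning learning rate to converge on
# 12 train slides
desk_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(tile_size = 128L, stride = 128L, subset_size = 96L,
         draws_per_epoch = 16L, warmup_epochs = 15L, max_epochs = 100L,
         seed = seed),
    list(...))
  do.call(training_config, args)
}

# shuffle slide labels within each split (keeps per-split label balance)
shuffle_manifest_labels <- function(manifest, seed) {
  set.seed(seed)
  for (sp in unique(manifest$split)) {
    idx <- which(manifest$split == sp)
    manifest$label[idx] <- sample(manifest$label[idx])
  }
  manifest
}

# slide-level aggressive/indolent scores for a split of a manifest
score_split <- function(classifier, manifest, split = "test") {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  preds <- lapply(seq_len(nrow(rows)), function(i) {
    grid <- score_slide(classifier, read_slide(rows$path[i]), stride = 128L)
    aggregate_wsi(grid)
  })
  list(rows = rows, preds = preds,
       score_aggressive = vapply(preds, `[[`, numeric(1), "score_aggressive"),
       score_indolent = vapply(preds, `[[`, numeric(1), "score_indolent"))
}
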