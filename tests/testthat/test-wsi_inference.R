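test_that("aggregate_wsi takes per-head maxima and applies the threshold", {
  g <- tile_score_grid(cbind(c(0L, 16L), c(0L, 0L)), c(0.1, 0.7), c(0.2, 0.3),
                       tile_size = 16L, slide_id = "s",
                       slide_width = 32L, slide_height = 16L)
  p <- aggregate_wsi(g, 0.5)
  expect_equal(p$score_indolent, 0.7)
  expect_equal(p$score_aggressive, 0.3)
  expect_equal(p$label_set, "indolent")
  expect_equal(p$exclusive_label, "indolent")
  # both maxima above threshold: a double-label slide
  g2 <- tile_score_grid(cbind(0L, 0L), 0.8, 0.6, 16L, slide_id = "s")
  p2 <- aggregate_wsi(g2)
  expect_setequal(p2$label_set, c("indolent", "aggressive"))
  expect_equal(p2$exclusive_label, "indolent")
  # nothing above threshold: benign
  g3 <- tile_score_grid(cbind(0L, 0L), 0.2, 0.3, 16L, slide_id = "s")
  expect_equal(aggregate_wsi(g3)$label_set, character(0))
  expect_equal(aggregate_wsi(g3)$exclusive_label, "benign")
  # exact score ties break toward aggressive
  g4 <- tile_score_grid(cbind(0L, 0L), 0.8, 0.8, 16L, slide_id = "s")
  expect_equal(aggregate_wsi(g4)$exclusive_label, "aggressive")
})

test_that("label sets are antitone in the threshold and scores monotone in tiles", {
  set.seed(14)
  pi_ <- runif(9); pa <- runif(9)
  g <- tile_score_grid(cbind(rep(c(0L, 16L, 32L), 3), rep(c(0L, 16L, 32L), each = 3)),
                       pi_, pa, 16L, slide_id = "s",
                       slide_width = 48L, slide_height = 48L)
  prev <- c("indolent", "aggressive")
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    ls <- aggregate_wsi(g, th)$label_set
    expect_true(all(ls %in% prev))  # raising the threshold never adds labels
    prev <- ls
    expect_true(aggregate_wsi(g, th)$exclusive_label %in% c(ls, "benign"))
  }
  # adding a tile never decreases either score
  g_more <- tile_score_grid(rbind(g$positions, c(0L, 32L)), c(pi_, 0.01),
                            c(pa, 0.99), 16L, slide_id = "s",
                            slide_width = 48L, slide_height = 48L)
  expect_gte(aggregate_wsi(g_more)$score_indolent, aggregate_wsi(g)$score_indolent)
  expect_gte(aggregate_wsi(g_more)$score_aggressive, aggregate_wsi(g)$score_aggressive)
})

test_that("score_slide produces one deterministic score pair per tissue tile", {
  gen <- generate_slide(slide_spec(width = 768L, height = 512L,
                                   class_mix = c(benign = 0.33, gp3 = 0, gp45 = 0),
                                   seed = 31), "one_frag")
  clf <- tile_classifier(input_size = 128L, seed = 1)
  g1 <- score_slide(clf, gen$slide, stride = 128L)
  g2 <- score_slide(clf, gen$slide, stride = 128L)
  expect_identical(g1$p_indolent, g2$p_indolent)
  expect_identical(g1$p_aggressive, g2$p_aggressive)
  expect_equal(length(g1$p_indolent), nrow(g1$positions))
  expect_true(all(g1$p_indolent >= 0 & g1$p_indolent <= 1))
  # a pure white slide has nothing to score
  white <- flat_slide(c(255, 255, 255), w = 256, h = 256)
  expect_error(score_slide(clf, white, stride = 128L), "no tissue")
  # a slide whose tissue is too sparse for any tile is an empty-tissue error
  sparse <- flat_slide(c(255, 255, 255), w = 256, h = 256)
  sparse$pixels[1:8, 1:8, ] <- 40L
  expect_error(score_slide(clf, sparse, stride = 128L), "no tissue tiles")
})

test_that("heatmaps color tile footprints by probability with per-pixel max", {
  pos <- cbind(c(0L, 8L), c(0L, 0L))  # overlapping 16-px tiles at stride 8
  g <- tile_score_grid(pos, c(0, 0), c(0.2, 0.9), tile_size = 16L, stride = 8L,
                       slide_id = "s", slide_width = 24L, slide_height = 16L)
  hm <- render_heatmap(g, "aggressive")
  expect_equal(dim(hm), c(16L, 24L, 3L))
  jet <- function(v) as.integer(round(pmin(pmax(1.5 - abs(4 * v - c(3, 2, 1)), 0), 1) * 255))
  # overlap zone (columns 9..16) takes the hotter tile's color
  expect_equal(as.integer(hm[4, 12, ]), jet(0.9))
  expect_equal(as.integer(hm[4, 4, ]), jet(0.2))
  # all-zero and all-one grids are uniform at the colormap extremes
  g0 <- tile_score_grid(pos, c(0, 0), c(0, 0), 16L, 8L, slide_id = "s",
                        slide_width = 24L, slide_height = 16L)
  hm0 <- render_heatmap(g0, "aggressive")
  expect_true(all(hm0[, , 1] == jet(0)[1]))
  expect_true(all(hm0[, , 3] == jet(0)[3]))
  g1 <- tile_score_grid(pos, c(1, 1), c(1, 1), 16L, 8L, slide_id = "s",
                        slide_width = 24L, slide_height = 16L)
  hm1 <- render_heatmap(g1, "indolent")
  expect_true(all(hm1[1:16, 1:24, 1] == jet(1)[1]))
})

test_that("a single hot tile renders exactly its footprint hot", {
  pos <- cbind(c(0L, 32L), c(0L, 0L))
  g <- tile_score_grid(pos, c(0, 0), c(0, 1), tile_size = 16L, stride = 16L,
                       slide_id = "s", slide_width = 48L, slide_height = 16L)
  hm <- render_heatmap(g, "aggressive")
  jet <- function(v) as.integer(round(pmin(pmax(1.5 - abs(4 * v - c(3, 2, 1)), 0), 1) * 255))
  hot <- hm[, , 1] == jet(1)[1] & hm[, , 2] == jet(1)[2] & hm[, , 3] == jet(1)[3]
  expect_true(all(hot[1:16, 33:48]))
  expect_false(any(hot[, 1:32]))
})
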