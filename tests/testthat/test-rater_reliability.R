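# brute-force pairwise agreement enumeration over all rater pairs per item
s_score_oracle <- function(m, c_cat = 3) {
  r <- ncol(m)
  po <- mean(apply(m, 1, function(row) {
    agree <- 0; tot <- 0
    for (i in 1:(r - 1)) for (j in (i + 1):r) {
      agree <- agree + (row[i] == row[j]); tot <- tot + 1
    }
    agree / tot
  }))
  (c_cat * po - 1) / (c_cat - 1)
}

cats <- c("benign", "indolent", "aggressive")

test_that("s_score matches closed forms and the enumeration oracle", {
  all_agree <- rating_matrix(matrix("indolent", 6, 4))
  expect_equal(s_score(all_agree)$value, 1)
  # chance-level observed agreement (Po = 1/3) gives S = 0: with 2 raters,
  # make 1/3 of items agree
  m <- rating_matrix(cbind(rep(cats, 3), c(cats, cats[c(2, 3, 1)], cats[c(3, 1, 2)])))
  expect_equal(mean(m[, 1] == m[, 2]), 1 / 3)
  expect_equal(s_score(m)$value, 0)
  expect_error(s_score(rating_matrix(matrix("benign", 5, 1))), "two raters")
  set.seed(21)
  for (i in 1:20) {
    mm <- rating_matrix(matrix(sample(cats, 100, replace = TRUE), 10, 10))
    expect_equal(s_score(mm)$value, s_score_oracle(mm), tolerance = 1e-12)
  }
})

test_that("s_score is invariant to permuting raters and items", {
  set.seed(22)
  m <- matrix(sample(cats, 60, replace = TRUE), 10, 6)
  base <- s_score(rating_matrix(m))$value
  expect_equal(s_score(rating_matrix(m[sample(10), ]))$value, base)
  expect_equal(s_score(rating_matrix(m[, sample(6)]))$value, base)
})

test_that("two-rater s_score reduces to the classic Bennett closed form", {
  set.seed(23)
  s1 <- sample(cats, 40, replace = TRUE)
  s2 <- sample(cats, 40, replace = TRUE)
  po <- mean(s1 == s2)
  expect_equal(s_score(rating_matrix(cbind(s1, s2)))$value, (3 * po - 1) / 2)
})

test_that("weighted kappa matches a hand-evaluated contingency table", {
  # sessions with joint counts (rows s1, cols s2, order benign<indolent<aggressive):
  #   4 1 0 / 1 3 1 / 0 1 4
  s1 <- c(rep("benign", 5), rep("indolent", 5), rep("aggressive", 5))
  s2 <- c(rep("benign", 4), "indolent",
          "benign", rep("indolent", 3), "aggressive",
          "indolent", rep("aggressive", 4))
  o <- table(factor(s1, cats), factor(s2, cats)) / 15
  w_lin <- abs(outer(1:3, 1:3, "-")) / 2
  e <- outer(rowSums(o), colSums(o))
  k_hand <- 1 - sum(w_lin * o) / sum(w_lin * e)
  expect_equal(weighted_kappa(s1, s2, "linear")$value, k_hand, tolerance = 1e-12)
  k_hand_q <- 1 - sum(w_lin^2 * o) / sum(w_lin^2 * e)
  expect_equal(weighted_kappa(s1, s2, "quadratic")$value, k_hand_q, tolerance = 1e-12)
})

test_that("weighted kappa is 1 for identical sessions and ~0 under independence", {
  set.seed(24)
  x <- sample(cats, 30, replace = TRUE)
  expect_equal(weighted_kappa(x, x)$value, 1)
  # null simulation: independent uniform sessions average to zero
  ks <- vapply(1:20, function(i) {
    a <- sample(cats, 10000, replace = TRUE)
    b <- sample(cats, 10000, replace = TRUE)
    weighted_kappa(a, b)$value
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.02)
  expect_error(weighted_kappa(x, x[-1]), "equal length")
})

test_that("the interpretation scale bands every value exactly once", {
  expect_equal(interpret_agreement(0.93), "almost perfect agreement")
  expect_equal(interpret_agreement(0.18), "slight agreement")
  expect_equal(interpret_agreement(-0.1), "poor agreement")
  expect_equal(interpret_agreement(0), "poor agreement")
  # the gap between the printed bands (0, 0.01) maps to slight
  expect_equal(interpret_agreement(0.005), "slight agreement")
  expect_equal(interpret_agreement(0.205), "fair agreement")
  expect_equal(interpret_agreement(1), "almost perfect agreement")
  expect_error(interpret_agreement(1.2), "exceed")
})

test_that("synthetic rating matrices hit their designed agreement levels", {
  perfect <- generate_rating_matrix(50, 5, 1, seed = 1)
  expect_equal(s_score(perfect)$value, 1)
  # uniform reporting is chance level
  chance <- generate_rating_matrix(10000, 3, 1 / 3, seed = 2)
  expect_lt(abs(s_score(chance)$value), 0.03)
  expect_identical(generate_rating_matrix(20, 4, 0.8, seed = 5),
                   generate_rating_matrix(20, 4, 0.8, seed = 5))
})

test_that("rating matrices validate categories and read from CSV", {
  expect_error(rating_matrix(matrix("maybe", 2, 2)), "must all be one of")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(item = c("s1", "s2"), r1 = c("benign", "indolent"),
                              r2 = c("benign", "aggressive")),
                   path, row.names = FALSE)
  m <- read_ratings(path)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m["s2", "r2"]), "aggressive")
})

test_that("the rater-study cohort helper fills four cohorts from predictions", {
  design <- rater_cohort_design()
  expect_equal(sum(design$n), 100)
  set.seed(25)
  preds <- list(); truths <- c()
  specs <- list(list("benign", 0.1, 0.1), list("indolent", 0.9, 0.1),
                list("indolent", 0.8, 0.8), list("aggressive", 0.1, 0.9),
                list("aggressive", 0.9, 0.8))
  for (i in 1:40) for (sp in specs) {
    grid <- tile_score_grid(cbind(0L, 0L), sp[[2]], sp[[3]], tile_size = 16L,
                            slide_id = paste0("s", length(preds) + 1),
                            slide_width = 16L, slide_height = 16L)
    preds[[length(preds) + 1]] <- aggregate_wsi(grid)
    truths <- c(truths, sp[[1]])
  }
  cohort <- sample_rater_cohort(preds, truths, n_per_group = 25, seed = 3)
  expect_equal(nrow(cohort), 100)
  expect_equal(as.integer(table(cohort$cohort)[design$cohort]), rep(25L, 4))
  # every double-label slide really carries both labels
  dbl <- cohort[cohort$cohort == "double_label", ]
  expect_true(all(dbl$predicted == "indolent&aggressive"))
})
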