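# O(n^2) Mann-Whitney pair-counting reference with ties counted one half
auc_pair_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

test_that("confusion counts and rates follow the defining equations", {
  cc <- confusion(c(rep(1, 10), rep(0, 10)), c(rep(1, 9), 0, rep(0, 10)))
  expect_equal(cc$TP, 9); expect_equal(cc$FN, 1)
  expect_equal(cc$tpr, 0.9)
  expect_equal(cc$fpr, 0)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 20)
  # all-positive truth leaves the FPR undefined, flagged
  cc2 <- confusion(rep(1, 5), c(1, 1, 0, 1, 1))
  expect_false(cc2$fpr_defined)
  expect_true(is.nan(cc2$fpr))
  expect_error(confusion(c(1, 0), c(1)), "equal")
})

test_that("roc_auc handles perfect separation, ties, and matches the pair oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.8)), "one class")
  set.seed(30)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 7), 1))  # coarse rounding forces ties
    r <- roc_auc(y, s)
    expect_equal(r$auc, auc_pair_oracle(y, s), tolerance = 1e-12)
    expect_equal(wsitriage:::.auc_rank(y, s), r$auc, tolerance = 1e-12)
    # curve endpoints and monotonicity
    expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
})

test_that("roc_auc is invariant under strictly monotone score transforms", {
  set.seed(31)
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(20)
  base <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, log(s + 1))$auc, base)
  expect_equal(roc_auc(y, s^3)$auc, base)
  expect_equal(roc_auc(y, 10 * s - 4)$auc, base)
})

test_that("log loss matches the closed form and direct summation", {
  expect_lt(log_loss(1, 1), 1e-12)
  expect_equal(log_loss(c(1, 0, 1), rep(0.5, 3)), log(2))
  set.seed(32)
  y <- rbinom(50, 1, 0.4); p <- runif(50)
  direct <- -sum(y * log(p) + (1 - y) * log(1 - p)) / 50
  expect_equal(log_loss(y, p), direct, tolerance = 1e-12)
})

test_that("bootstrap intervals are deterministic under seed and collapse for constants", {
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(40)
  ci1 <- bootstrap_ci(function(yt, st) wsitriage:::.auc_rank(yt, st), y, s,
                      n_iter = 200, seed = 7)
  ci2 <- bootstrap_ci(function(yt, st) wsitriage:::.auc_rank(yt, st), y, s,
                      n_iter = 200, seed = 7)
  expect_identical(ci1, ci2)
  const <- bootstrap_ci(function(yt, st) 0.42, y, s, n_iter = 50, seed = 1)
  expect_equal(unname(const[1]), 0.42)
  expect_equal(unname(const[2]), 0.42)
})

make_pred <- function(id, s_ind, s_agg, threshold = 0.5) {
  grid <- tile_score_grid(cbind(0L, 0L), s_ind, s_agg, tile_size = 16L,
                          slide_id = id, slide_width = 16L, slide_height = 16L)
  aggregate_wsi(grid, threshold)
}

test_that("evaluate_set scores heads by truth binarization and mode", {
  truths <- c("benign", "indolent", "aggressive", "indolent")
  preds <- list(make_pred("a", 0.1, 0.2), make_pred("b", 0.9, 0.1),
                make_pred("c", 0.2, 0.95), make_pred("d", 0.8, 0.7))
  # slide d is double-labelled; the larger score wins the exclusive call
  expect_setequal(preds[[4]]$label_set, c("indolent", "aggressive"))
  expect_equal(preds[[4]]$exclusive_label, "indolent")  # 0.8 > 0.7
  ex <- evaluate_set(preds, truths, "exclusive", n_bootstrap = 50, seed = 3)
  dl <- evaluate_set(preds, truths, "double_label_accept", n_bootstrap = 50, seed = 3)
  acc <- function(rep, h) rep$estimate[rep$head == h & rep$metric == "accuracy"]
  # acceptance of double labels can only help hard-call accuracy
  expect_gte(acc(dl, "indolent"), acc(ex, "indolent"))
  expect_gte(acc(dl, "aggressive"), acc(ex, "aggressive"))
  # AUC is call-free: identical across modes
  auc <- function(rep, h) rep$estimate[rep$head == h & rep$metric == "roc_auc"]
  expect_equal(auc(dl, "indolent"), auc(ex, "indolent"))
  expect_error(evaluate_set(preds, c("benign", "x", "aggressive", "indolent")),
               "unknown truth")
})

test_that("double-label acceptance dominates exclusive accuracy on random sets", {
  set.seed(33)
  for (i in 1:10) {
    n <- 30
    truths <- sample(c("benign", "indolent", "aggressive"), n, replace = TRUE)
    preds <- lapply(seq_len(n), function(j)
      make_pred(paste0("s", j), runif(1), runif(1)))
    ex <- evaluate_set(preds, truths, "exclusive", n_bootstrap = 10, seed = i)
    dl <- evaluate_set(preds, truths, "double_label_accept", n_bootstrap = 10, seed = i)
    for (h in c("indolent", "aggressive")) {
      expect_gte(dl$estimate[dl$head == h & dl$metric == "accuracy"],
                 ex$estimate[ex$head == h & ex$metric == "accuracy"])
    }
  }
})

test_that("permuted truths give chance-level AUC", {
  set.seed(34)
  n <- 200
  s <- runif(n)
  y <- as.integer(s + rnorm(n, 0, 0.2) > 0.5)  # correlated truth
  y_perm <- sample(y)
  expect_gt(roc_auc(y, s)$auc, 0.8)
  expect_lt(abs(roc_auc(y_perm, s)$auc - 0.5), 0.12)
})
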