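#' Confusion counts with TPR and FPR
#'
#' Standard 2x2 cross-tabulation of binary truth against binary calls, with
#' the true positive rate `TP / (TP + FN)` and false positive rate
#' `FP / (FP + TN)`. A rate whose denominator is zero is reported as `NaN`
#' with the matching `*_defined` flag set to `FALSE`.
#'
#' @param y_true,y_pred binary vectors (0/1 or logical) of equal length.
#' @return List with `TP`, `FP`, `TN`, `FN`, `tpr`, `fpr`, `tpr_defined`,
#'   `fpr_defined`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L)
    stop("y_true and y_pred must have equal positive length", call. = FALSE)
  yt <- as.integer(as.logical(y_true)); yp <- as.integer(as.logical(y_pred))
  tp <- sum(yt == 1 & yp == 1); fp <- sum(yt == 0 & yp == 1)
  tn <- sum(yt == 0 & yp == 0); fn <- sum(yt == 1 & yp == 0)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NaN,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NaN,
       tpr_defined = tp + fn > 0, fpr_defined = fp + tn > 0)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over all distinct scores (calls are
#' `score >= threshold`), computing TPR and FPR at each cut, and integrates
#' the curve by the trapezoidal rule. The resulting AUC equals the
#' probability that a random positive outranks a random negative, counting
#' ties as one half.
#'
#' @param y_true binary vector; both classes must be present.
#' @param scores numeric scores, higher = more positive.
#' @return List with `curve` (data.frame `fpr`, `tpr`, endpoints `(0,0)` and
#'   `(1,1)` included) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch", call. = FALSE)
  yt <- as.integer(as.logical(y_true))
  n1 <- sum(yt == 1); n0 <- sum(yt == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: only one class present in y_true", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tprs <- vapply(thr, function(t) sum(scores >= t & yt == 1) / n1, numeric(1))
  fprs <- vapply(thr, function(t) sum(scores >= t & yt == 0) / n0, numeric(1))
  curve <- data.frame(fpr = c(0, fprs, 1), tpr = c(0, tprs, 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

# rank-based AUC (Mann-Whitney with ties counted one half); equal to the
# trapezoidal sweep above, but O(n log n) for bootstrap loops
.auc_rank <- function(y_true, scores) {
  yt <- as.integer(as.logical(y_true))
  n1 <- sum(yt == 1); n0 <- sum(yt == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[yt == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary log loss
#'
#' Mean negative log-likelihood `-(y log p + (1-y) log(1-p))` with
#' probabilities clipped away from 0 and 1.
#'
#' @param y_true binary vector.
#' @param scores predicted probabilities.
#' @param clip clipping bound (default `1e-15`).
#' @return Scalar log loss.
#' @export
log_loss <- function(y_true, scores, clip = 1e-15) {
  if (length(y_true) != length(scores)) stop("length mismatch", call. = FALSE)
  y <- as.numeric(as.logical(y_true))
  p <- pmin(pmax(scores, clip), 1 - clip)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples slides with replacement `n_iter` times and returns the
#' percentile interval of the statistic over the resamples. Resamples on
#' which the statistic is undefined (returns `NA` or errors, e.g. a
#' single-class AUC resample) are skipped and counted; more than half
#' undefined is an error.
#'
#' @param statistic function of `(y_true, scores)` returning a scalar.
#' @param y_true,scores the full sample, resampled jointly.
#' @param n_iter bootstrap iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the same seed reproduces the same interval.
#' @return Numeric `c(low, high)` with attribute `n_skipped`.
#' @export
bootstrap_ci <- function(statistic, y_true, scores, n_iter = 1000L,
                         level = 0.95, seed = 1L) {
  stopifnot(n_iter >= 1, level > 0, level < 1)
  n <- length(y_true)
  vals <- .with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(statistic(y_true[idx], scores[idx])),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_skipped <- sum(is.na(vals))
  if (n_skipped > n_iter / 2)
    stop("statistic undefined on more than half of the bootstrap resamples", call. = FALSE)
  alpha <- (1 - level) / 2
  ci <- stats::quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  attr(ci, "n_skipped") <- n_skipped
  ci
}

#' Evaluate slide-level predictions against truth labels
#'
#' For each head (indolent, aggressive) the truth is binarized as
#' `truth == head` and the continuous score is the head's max-aggregated
#' probability. Hard calls depend on the scoring mode: `"exclusive"` uses the
#' single exclusive label (`exclusive_label == head`). In
#' `"double_label_accept"`, a slide that carries both labels is accepted as a
#' call of the *true* class whenever the truth is one of its two labels;
#' every other slide keeps its exclusive call. Acceptance therefore only
#' relaxes correctness, so accuracy under it always dominates the exclusive
#' accuracy. ROC-AUC is threshold-free and uses the scores in both modes;
#' accuracy, sensitivity and specificity use the hard calls. All metrics
#' carry percentile bootstrap confidence intervals resampled at the slide
#' level.
#'
#' @param predictions list of `wsi_prediction` objects (see
#'   [aggregate_wsi()]).
#' @param truths character vector of true labels
#'   (benign/indolent/aggressive), aligned with `predictions`.
#' @param mode `"exclusive"` or `"double_label_accept"`.
#' @param n_bootstrap bootstrap iterations (default 1000).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return A data.frame of class `metric_report` with columns `head`,
#'   `metric`, `estimate`, `ci_low`, `ci_high`; attributes `scoring_mode`,
#'   `n_bootstrap`, `ci_level`.
#' @export
evaluate_set <- function(predictions, truths,
                         mode = c("exclusive", "double_label_accept"),
                         n_bootstrap = 1000L, ci_level = 0.95, seed = 1L) {
  mode <- match.arg(mode)
  if (length(predictions) != length(truths)) stop("length mismatch", call. = FALSE)
  if (!all(truths %in% .wsi_labels))
    stop("unknown truth label(s): ",
         paste(setdiff(truths, .wsi_labels), collapse = ","), call. = FALSE)
  rows <- list()
  for (head in c("indolent", "aggressive")) {
    y <- as.integer(truths == head)
    scores <- vapply(predictions, function(p)
      if (head == "indolent") p$score_indolent else p$score_aggressive, numeric(1))
    calls <- vapply(seq_along(predictions), function(i) {
      p <- predictions[[i]]
      if (mode == "double_label_accept" && length(p$label_set) == 2L &&
          truths[i] %in% p$label_set) {
        as.integer(head == truths[i])  # double label accepted as the truth
      } else {
        as.integer(p$exclusive_label == head)
      }
    }, integer(1))
    stats_list <- list(
      roc_auc = list(v = .auc_rank(y, scores), x = scores,
                     f = function(yt, s) .auc_rank(yt, s)),
      log_loss = list(v = log_loss(y, scores), x = scores,
                      f = function(yt, s) log_loss(yt, s)),
      accuracy = list(v = mean(y == calls), x = calls,
                      f = function(yt, s) mean(yt == s)),
      sensitivity = list(v = confusion(y, calls)$tpr, x = calls,
                         f = function(yt, s) {
                           cc <- confusion(yt, s)
                           if (!cc$tpr_defined) NA_real_ else cc$tpr
                         }),
      specificity = list(v = 1 - confusion(y, calls)$fpr, x = calls,
                         f = function(yt, s) {
                           cc <- confusion(yt, s)
                           if (!cc$fpr_defined) NA_real_ else 1 - cc$fpr
                         })
    )
    for (mn in names(stats_list)) {
      st <- stats_list[[mn]]
      ci <- bootstrap_ci(st$f, y, st$x, n_iter = n_bootstrap, level = ci_level,
                         seed = seed + match(head, c("indolent", "aggressive")))
      rows[[length(rows) + 1L]] <- data.frame(
        head = head, metric = mn, estimate = st$v,
        ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scoring_mode") <- mode
  attr(out, "n_bootstrap") <- as.integer(n_bootstrap)
  attr(out, "ci_level") <- ci_level
  class(out) <- c("metric_report", class(out))
  out
}
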