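# Agreement statistics for the rater-reliability studies: Bennett's S across
# multiple raters (inter-rater) and weighted kappa between two sessions of
# one rater (intra-rater), with the conventional interpretation scale.

.rating_categories <- c("benign", "indolent", "aggressive")

#' Construct a rating matrix
#'
#' Items (slides) in rows, raters in columns, every cell a category from
#' benign/indolent/aggressive; no missing cells.
#'
#' @param x character matrix or data.frame of ratings.
#' @return A character matrix of class `rating_matrix` with attribute
#'   `categories`.
#' @export
rating_matrix <- function(x) {
  m <- as.matrix(x)
  if (any(is.na(m)) || !all(m %in% .rating_categories))
    stop("ratings must all be one of ", paste(.rating_categories, collapse = "/"),
         call. = FALSE)
  structure(m, class = c("rating_matrix", class(m)), categories = .rating_categories)
}

#' Read a rating matrix from CSV
#'
#' Rows are items and columns raters; an optional first column named `item`
#' supplies row names.
#'
#' @param path CSV path.
#' @return A [rating_matrix()].
#' @export
read_ratings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if ("item" %in% names(d)) {
    rownames(d) <- d$item
    d$item <- NULL
  }
  rating_matrix(d)
}

.agreement_result <- function(value) {
  structure(list(value = value, interpretation = interpret_agreement(value)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement %.3f (%s)\n", x$value, x$interpretation))
  invisible(x)
}

#' Bennett's S score across multiple raters
#'
#' Computes the mean observed pairwise agreement over items,
#' `Po = mean over items of (agreeing rater pairs / total rater pairs)`,
#' then chance-corrects against uniform chance `1/c`:
#' `S = (c Po - 1) / (c - 1)` with `c = 3` categories. With two raters this
#' reduces to the classic two-rater Bennett S.
#'
#' @param matrix a [rating_matrix()] with at least two raters.
#' @return An `agreement_result` with `value` and `interpretation`.
#' @export
s_score <- function(matrix) {
  stopifnot(inherits(matrix, "rating_matrix"))
  r <- ncol(matrix)
  if (r < 2L) stop("S score needs at least two raters", call. = FALSE)
  if (nrow(matrix) < 1L) stop("S score needs at least one item", call. = FALSE)
  c_cat <- length(attr(matrix, "categories"))
  pairs_total <- r * (r - 1) / 2
  po_items <- apply(matrix, 1, function(row) {
    counts <- table(row)
    sum(counts * (counts - 1) / 2) / pairs_total
  })
  po <- mean(po_items)
  .agreement_result((c_cat * po - 1) / (c_cat - 1))
}

#' Weighted kappa between two rating sessions
#'
#' Chance-corrected agreement for ordered categories
#' (benign < indolent < aggressive):
#' `kappa_w = 1 - sum(w o) / sum(w e)` where `o` is the observed joint
#' proportion table, `e` the chance-expected table from the marginal
#' products, and `w[i, j] = |i - j| / (c - 1)` (linear) or its square
#' (quadratic).
#'
#' @param session1,session2 aligned category vectors from one rater's two
#'   sessions.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @return An `agreement_result`. Perfect observed agreement gives 1 even
#'   when expected disagreement is zero; zero expected with nonzero observed
#'   disagreement is flagged as degenerate (`NaN` value).
#' @export
weighted_kappa <- function(session1, session2, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(session1) != length(session2))
    stop("sessions must have equal length", call. = FALSE)
  if (!all(c(session1, session2) %in% .rating_categories))
    stop("ratings must all be one of ", paste(.rating_categories, collapse = "/"),
         call. = FALSE)
  f1 <- factor(session1, levels = .rating_categories)
  f2 <- factor(session2, levels = .rating_categories)
  o <- table(f1, f2) / length(f1)
  e <- outer(rowSums(o), colSums(o))
  cc <- length(.rating_categories)
  d <- abs(outer(seq_len(cc), seq_len(cc), "-")) / (cc - 1)
  w <- if (weights == "linear") d else d^2
  num <- sum(w * o); den <- sum(w * e)
  value <- if (den == 0) {
    if (num == 0) 1 else NaN  # degenerate: no expected disagreement
  } else 1 - num / den
  .agreement_result(value)
}

#' Interpret an agreement value on the conventional scale
#'
#' Bands: at or below 0, poor; up to 0.20, slight; up to 0.40, fair; up to
#' 0.60, moderate; up to 0.80, substantial; up to 1.00, almost perfect.
#' Intervals are left-open/right-closed so every value at or below 1 maps to
#' exactly one band.
#'
#' @param value finite agreement value, at most 1.
#' @return Interpretation string.
#' @export
interpret_agreement <- function(value) {
  if (!is.finite(value)) return(NA_character_)
  if (value > 1 + 1e-12) stop("agreement value cannot exceed 1", call. = FALSE)
  if (value <= 0) "poor agreement"
  else if (value <= 0.20) "slight agreement"
  else if (value <= 0.40) "fair agreement"
  else if (value <= 0.60) "moderate agreement"
  else if (value <= 0.80) "substantial agreement"
  else "almost perfect agreement"
}

#' Cohort design of the rater-reliability study
#'
#' The reading study draws four cohorts of slides from model outputs crossed
#' with the consensus truth: true negatives (benign/benign), true-positive
#' indolent, double-label outputs (model calls both indolent and aggressive),
#' and true-positive aggressive.
#'
#' @param n_per_group slides per cohort (default 25).
#' @return data.frame with `cohort`, `consensus`, `predicted`, `n`.
#' @export
rater_cohort_design <- function(n_per_group = 25L) {
  data.frame(
    cohort = c("true_negative", "true_positive_indolent", "double_label",
               "true_positive_aggressive"),
    consensus = c("benign", "indolent", "indolent|aggressive", "aggressive"),
    predicted = c("benign", "indolent", "indolent&aggressive", "aggressive"),
    n = as.integer(n_per_group), stringsAsFactors = FALSE)
}

#' Sample a rater-study cohort from prediction outputs
#'
#' Selects up to `n_per_group` slides for each cohort of
#' [rater_cohort_design()] from a set of slide predictions and consensus
#' truths, warning when a cohort is under-filled.
#'
#' @param predictions list of `wsi_prediction` objects.
#' @param truths aligned character truth labels.
#' @param n_per_group target slides per cohort (default 25).
#' @param seed integer seed for the random draw.
#' @return data.frame with `slide_id`, `cohort`, `consensus`, `predicted`.
#' @export
sample_rater_cohort <- function(predictions, truths, n_per_group = 25L, seed = 1L) {
  stopifnot(length(predictions) == length(truths))
  pred_lab <- vapply(predictions, function(p) {
    if (length(p$label_set) == 2L) "indolent&aggressive"
    else if (length(p$label_set) == 1L) p$label_set
    else "benign"
  }, character(1))
  sid <- vapply(predictions, `[[`, character(1), "slide_id")
  eligible <- list(
    true_negative = which(truths == "benign" & pred_lab == "benign"),
    true_positive_indolent = which(truths == "indolent" & pred_lab == "indolent"),
    double_label = which(truths != "benign" & pred_lab == "indolent&aggressive"),
    true_positive_aggressive = which(truths == "aggressive" & pred_lab == "aggressive"))
  .with_seed(seed, {
    rows <- lapply(names(eligible), function(ch) {
      idx <- eligible[[ch]]
      if (length(idx) < n_per_group)
        warning("cohort '", ch, "' under-filled: ", length(idx), " of ",
                n_per_group, " slides", call. = FALSE)
      take <- if (length(idx) <= n_per_group) idx
              else idx[sample.int(length(idx), n_per_group)]
      if (length(take) == 0L) return(NULL)
      data.frame(slide_id = sid[take], cohort = ch, consensus = truths[take],
                 predicted = pred_lab[take], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
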