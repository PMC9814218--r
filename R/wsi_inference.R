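#' Score every tissue tile of a slide
#'
#' Runs the full sliding-window pipeline on one slide: Otsu tissue detection,
#' tile enumeration, classifier inference. Deterministic given a fixed
#' classifier.
#'
#' @param classifier a [tile_classifier()].
#' @param slide a [slide_image()].
#' @param stride tile stride in pixels (default: half the classifier's input
#'   size, the published sliding-window setting).
#' @param min_tissue_fraction minimum tissue coverage per tile.
#' @param mask_downsample tissue-mask cell size in pixels.
#' @return An object of class `tile_score_grid`: `positions` (n x 2 matrix),
#'   `tile_size`, `stride`, `p_indolent`, `p_aggressive`, `slide_id`,
#'   `slide_width`, `slide_height`.
#' @export
score_slide <- function(classifier, slide, stride = NULL,
                        min_tissue_fraction = 0.25, mask_downsample = 16L) {
  stopifnot(inherits(classifier, "tile_classifier"), inherits(slide, "slide_image"))
  tile_size <- classifier$input_size
  stride <- as.integer(stride %||% (tile_size %/% 2L))
  th <- tryCatch(otsu_threshold(luminance_histogram(slide)),
                 error = function(e) stop("slide '", slide$slide_id,
                   "' has no tissue/background contrast to threshold",
                   call. = FALSE))
  mask <- compute_tissue_mask(slide, th, mask_downsample)
  grid <- enumerate_tiles(mask, tile_size, stride, min_tissue_fraction)
  n <- nrow(grid$positions)
  if (n == 0L)
    stop("slide '", slide$slide_id, "' has no tissue tiles to score", call. = FALSE)
  tiles <- lapply(seq_len(n), function(t)
    extract_tile(slide, grid$positions[t, 1], grid$positions[t, 2], tile_size))
  p <- predict_tiles(classifier, tiles)
  structure(list(positions = grid$positions, tile_size = tile_size,
                 stride = stride, p_indolent = unname(p[, 1]),
                 p_aggressive = unname(p[, 2]), slide_id = slide$slide_id,
                 slide_width = slide$width, slide_height = slide$height),
            class = "tile_score_grid")
}

#' Construct a tile score grid
#'
#' Mostly produced by [score_slide()]; the constructor is exported so score
#' grids can be rebuilt from saved per-tile scores.
#'
#' @param positions n x 2 integer matrix of tile `(x, y)` origins.
#' @param p_indolent,p_aggressive per-tile probabilities in `[0, 1]`.
#' @param tile_size,stride grid geometry in pixels.
#' @param slide_id slide identifier.
#' @param slide_width,slide_height slide size in pixels (used by heatmaps).
#' @return A `tile_score_grid`.
#' @export
tile_score_grid <- function(positions, p_indolent, p_aggressive,
                            tile_size, stride = tile_size,
                            slide_id = "slide",
                            slide_width = max(positions[, 1]) + tile_size,
                            slide_height = max(positions[, 2]) + tile_size) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (length(p_indolent) != n || length(p_aggressive) != n)
    stop("per-tile probabilities must match the number of positions", call. = FALSE)
  if (any(c(p_indolent, p_aggressive) < 0) || any(c(p_indolent, p_aggressive) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(positions = positions, tile_size = as.integer(tile_size),
                 stride = as.integer(stride), p_indolent = p_indolent,
                 p_aggressive = p_aggressive, slide_id = slide_id,
                 slide_width = as.integer(slide_width),
                 slide_height = as.integer(slide_height)),
            class = "tile_score_grid")
}

#' Aggregate tile scores into a slide-level prediction
#'
#' The slide score for each head is the maximum tile probability for that
#' head. The label set contains every head whose score reaches the decision
#' threshold (both: a double-label slide; neither: benign). The exclusive
#' label collapses the set to the single larger-scoring member for legacy
#' single-label evaluation, breaking exact ties toward aggressive.
#'
#' @param grid a `tile_score_grid`.
#' @param threshold decision threshold in `(0, 1)` (default 0.5).
#' @return An object of class `wsi_prediction`: `slide_id`,
#'   `score_indolent`, `score_aggressive`, `label_set` (character vector,
#'   possibly empty), `exclusive_label`.
#' @export
aggregate_wsi <- function(grid, threshold = 0.5) {
  stopifnot(inherits(grid, "tile_score_grid"))
  if (length(grid$p_indolent) == 0L)
    stop("cannot aggregate an empty score grid", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  s_ind <- max(grid$p_indolent)
  s_agg <- max(grid$p_aggressive)
  label_set <- c(if (s_ind >= threshold) "indolent", if (s_agg >= threshold) "aggressive")
  exclusive <- if (length(label_set) == 0L) "benign"
               else if (length(label_set) == 1L) label_set
               else if (s_agg >= s_ind) "aggressive" else "indolent"
  structure(list(slide_id = grid$slide_id, score_indolent = s_ind,
                 score_aggressive = s_agg, label_set = label_set %||% character(0),
                 exclusive_label = exclusive),
            class = "wsi_prediction")
}

#' @export
print.wsi_prediction <- function(x, ...) {
  ls <- if (length(x$label_set)) paste(x$label_set, collapse = "+") else "(none)"
  cat(sprintf("<wsi_prediction '%s'> indolent %.3f, aggressive %.3f, labels %s -> %s\n",
              x$slide_id, x$score_indolent, x$score_aggressive, ls, x$exclusive_label))
  invisible(x)
}

# piecewise-linear jet colormap; v in [0,1] -> n x 3 in [0,1]
.jet <- function(v) {
  clamp <- function(x) pmin(pmax(x, 0), 1)
  cbind(clamp(1.5 - abs(4 * v - 3)),
        clamp(1.5 - abs(4 * v - 2)),
        clamp(1.5 - abs(4 * v - 1)))
}

#' Render a per-tile probability heatmap
#'
#' Colors each tile footprint by its probability for the requested head using
#' a jet-style colormap (blue = low, red = high). Where strides overlap, the
#' per-pixel maximum probability wins, consistent with max aggregation.
#' Pixels outside every tile footprint take the lowest color.
#'
#' @param grid a `tile_score_grid`.
#' @param head `"indolent"` or `"aggressive"`.
#' @return `height x width x 3` integer RGB array (0-255).
#' @export
render_heatmap <- function(grid, head = c("indolent", "aggressive")) {
  head <- match.arg(head)
  stopifnot(inherits(grid, "tile_score_grid"))
  if (length(grid$p_indolent) == 0L) stop("cannot render an empty score grid", call. = FALSE)
  scores <- if (head == "indolent") grid$p_indolent else grid$p_aggressive
  H <- grid$slide_height; W <- grid$slide_width
  val <- matrix(0, H, W)
  ts <- grid$tile_size
  for (t in seq_along(scores)) {
    x <- grid$positions[t, 1]; y <- grid$positions[t, 2]
    rows <- (y + 1):(y + ts); cols <- (x + 1):(x + ts)
    val[rows, cols] <- pmax(val[rows, cols], scores[t])
  }
  rgb <- .jet(as.vector(val))
  out <- array(0L, c(H, W, 3))
  out[, , 1] <- as.integer(round(rgb[, 1] * 255))
  out[, , 2] <- as.integer(round(rgb[, 2] * 255))
  out[, , 3] <- as.integer(round(rgb[, 3] * 255))
  out
}
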