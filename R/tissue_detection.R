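#' Luminance histogram of a slide
#'
#' Counts pixels by rounded ITU-R 601 luminance
#' (`0.299 R + 0.587 G + 0.114 B`), the grayscale used for tissue detection
#' on H&E slides scanned against a white background.
#'
#' @param slide a [slide_image()].
#' @return Integer vector of length 256; element `b + 1` counts pixels of
#'   luminance `b`. Sums to `width * height`.
#' @export
luminance_histogram <- function(slide) {
  stopifnot(inherits(slide, "slide_image"))
  lum <- .luminance(slide$pixels)
  tabulate(as.integer(round(lum)) + 1L, nbins = 256L)
}

.luminance <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Otsu's threshold from a 256-bin histogram
#'
#' Returns the threshold `t` in `[0, 254]` maximizing the between-class
#' variance `w0(t) w1(t) (mu0(t) - mu1(t))^2` of the split into bins
#' `[0..t]` and `[t+1..255]`. Ties are broken toward the smallest `t`.
#'
#' @param histogram integer vector of length 256 with at least two nonzero
#'   bins.
#' @return Integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256L) stop("histogram must have 256 bins", call. = FALSE)
  if (sum(histogram > 0) < 2L)
    stop("degenerate histogram: need at least two nonzero bins", call. = FALSE)
  p <- histogram / sum(histogram)
  lev <- 0:255
  w0 <- cumsum(p)[1:255]                    # class weight for t = 0..254
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  w1 <- 1 - w0
  # between-class variance; undefined splits (empty class) get -Inf
  num <- (mu_t * w0 - mu[1:255])^2
  bcv <- ifelse(w0 > 0 & w1 > 0, num / (w0 * w1), -Inf)
  which.max(bcv) - 1L                       # which.max takes the first maximum
}

#' Compute a downsampled tissue mask
#'
#' A cell of the downsampled grid is tissue iff the majority (strictly more
#' than half) of its pixels have luminance at or below the threshold: tissue
#' is darker than the white scanning background.
#'
#' @param slide a [slide_image()].
#' @param threshold integer in `[0, 254]`, typically from [otsu_threshold()].
#' @param downsample integer cell size `d >= 1`; the grid has
#'   `ceil(height/d) x ceil(width/d)` cells.
#' @return An object of class `tissue_mask` with fields `grid` (logical
#'   matrix), `downsample`, `slide_width`, `slide_height`, `source_slide_id`.
#' @export
compute_tissue_mask <- function(slide, threshold, downsample = 16L) {
  stopifnot(inherits(slide, "slide_image"))
  if (threshold < 0 || threshold > 254) stop("threshold must lie in [0, 254]", call. = FALSE)
  if (downsample < 1) stop("downsample must be >= 1", call. = FALSE)
  d <- as.integer(downsample)
  dark <- .luminance(slide$pixels) <= threshold
  if (d == 1L) {
    return(structure(
      list(grid = dark, downsample = 1L,
           slide_width = slide$width, slide_height = slide$height,
           source_slide_id = slide$slide_id),
      class = "tissue_mask"))
  }
  gh <- ceiling(slide$height / d)
  gw <- ceiling(slide$width / d)
  ri <- rep(seq_len(gh), each = d, length.out = slide$height)
  ci <- rep(seq_len(gw), each = d, length.out = slide$width)
  # per-cell dark-pixel count vs cell pixel count (edge cells are smaller)
  cell <- matrix(0L, gh, gw)
  cnt <- matrix(0L, gh, gw)
  idx <- cbind(rep(ri, times = slide$width), rep(ci, each = slide$height))
  dark_sum <- rowsum(as.integer(dark), group = (idx[, 2] - 1L) * gh + idx[, 1])
  tot_sum <- rowsum(rep(1L, length(dark)), group = (idx[, 2] - 1L) * gh + idx[, 1])
  cell[as.integer(rownames(dark_sum))] <- dark_sum
  cnt[as.integer(rownames(tot_sum))] <- tot_sum
  structure(
    list(grid = cell > cnt / 2, downsample = d,
         slide_width = slide$width, slide_height = slide$height,
         source_slide_id = slide$slide_id),
    class = "tissue_mask"
  )
}

#' Enumerate candidate tile positions over tissue
#'
#' Slides a `tile_size` window over the regular stride grid
#' `x in {0, stride, 2 stride, ...}` (likewise `y`), keeps windows fully
#' inside the slide whose tissue coverage, measured on the mask grid, is at
#' least `min_tissue_fraction`. Positions are returned in row-major order
#' (increasing `y`, then `x`).
#'
#' @param mask a `tissue_mask` from [compute_tissue_mask()].
#' @param tile_size tile side in pixels (default 512).
#' @param stride step between tile origins, `0 < stride <= tile_size`
#'   (default 256).
#' @param min_tissue_fraction minimum tissue coverage of a window, in
#'   `[0, 1]` (default 0.25).
#' @return An object of class `tile_grid`: fields `positions` (n x 2 integer
#'   matrix of `(x, y)`), `tile_size`, `stride`. Empty (zero rows) when the
#'   tile is larger than the slide or no window qualifies.
#' @export
enumerate_tiles <- function(mask, tile_size = 512L, stride = 256L,
                            min_tissue_fraction = 0.25) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (tile_size <= 0) stop("tile_size must be positive", call. = FALSE)
  if (stride <= 0 || stride > tile_size)
    stop("stride must satisfy 0 < stride <= tile_size", call. = FALSE)
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1)
    stop("min_tissue_fraction must lie in [0, 1]", call. = FALSE)
  xs <- seq(0L, by = as.integer(stride), length.out =
              max(0L, (mask$slide_width - tile_size) %/% stride + 1L))
  ys <- seq(0L, by = as.integer(stride), length.out =
              max(0L, (mask$slide_height - tile_size) %/% stride + 1L))
  if (length(xs) == 0L || length(ys) == 0L || mask$slide_width < tile_size ||
      mask$slide_height < tile_size) {
    return(structure(list(positions = matrix(integer(), 0, 2,
                                             dimnames = list(NULL, c("x", "y"))),
                          tile_size = as.integer(tile_size),
                          stride = as.integer(stride)),
                     class = "tile_grid"))
  }
  # integral image of the mask grid for O(1) window sums
  g <- mask$grid
  cs <- apply(g, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = nrow(g))
  cs2 <- if (ncol(cs) == 1L) cs else t(apply(cs, 1, cumsum))
  sat <- matrix(0, nrow(g) + 1L, ncol(g) + 1L)
  sat[-1, -1] <- cs2  # sat[i+1, j+1] = sum g[1..i, 1..j]
  d <- mask$downsample
  keep <- matrix(FALSE, length(ys), length(xs))
  frac <- function(x0, y0) {
    # mask cells overlapped by window [x0, x0+tile) x [y0, y0+tile)
    c0 <- x0 %/% d; c1 <- (x0 + tile_size - 1L) %/% d
    r0 <- y0 %/% d; r1 <- (y0 + tile_size - 1L) %/% d
    s <- sat[r1 + 2L, c1 + 2L] - sat[r0 + 1L, c1 + 2L] -
         sat[r1 + 2L, c0 + 1L] + sat[r0 + 1L, c0 + 1L]
    s / ((r1 - r0 + 1L) * (c1 - c0 + 1L))
  }
  for (i in seq_along(ys)) for (j in seq_along(xs))
    keep[i, j] <- frac(xs[j], ys[i]) >= min_tissue_fraction
  sel <- which(keep, arr.ind = TRUE)
  # row-major: sort by y then x
  sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
  pos <- cbind(x = xs[sel[, 2]], y = ys[sel[, 1]])
  structure(list(positions = pos, tile_size = as.integer(tile_size),
                 stride = as.integer(stride)),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d positions, tile %d px, stride %d px\n",
              nrow(x$positions), x$tile_size, x$stride))
  invisible(x)
}
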