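#' Polygon area of an annotation region
#'
#' Shoelace (Gauss) area in squared pixels, non-negative regardless of vertex
#' winding.
#'
#' @param region an [annotation_region()].
#' @return Numeric area in squared pixels.
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "annotation_region"))
  .shoelace(region$vertices)
}

.shoelace <- function(v) {
  n <- nrow(v)
  if (nrow(unique(v)) < 3L) stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Map a Gleason pattern to its management class
#'
#' Gleason pattern 3 is grouped as indolent (active-surveillance morphology);
#' patterns 4 and 5 as aggressive (definitive-therapy morphology).
#'
#' @param pattern one of `"GP3"`, `"GP4"`, `"GP5"` (vectorized).
#' @return Character vector of `"indolent"` / `"aggressive"`.
#' @export
pattern_to_class <- function(pattern) {
  if (!all(pattern %in% .gp_patterns))
    stop("unknown Gleason pattern: ", paste(setdiff(pattern, .gp_patterns), collapse = ","),
         call. = FALSE)
  ifelse(pattern == "GP3", "indolent", "aggressive")
}

#' Summarize Gleason-pattern areas on a slide
#'
#' Computes the annotated carcinoma area per pattern group (GP3 vs GP4+GP5)
#' and the GP4/5 fraction of the total carcinoma area. Overlapping polygons of
#' the same pattern group are unioned before measuring so free-hand
#' annotations are not double counted; polygons of different pattern groups
#' that overlap are each counted for their own group.
#'
#' @param regions list of [annotation_region()] objects from one slide.
#' @return A list with `area_gp3`, `area_gp45` (squared pixels) and
#'   `fraction_gp45` (`NA` when there is no carcinoma area).
#' @export
gleason_area_summary <- function(regions) {
  cls <- vapply(regions, function(r) pattern_to_class(r$pattern), character(1))
  a3 <- .group_union_area(regions[cls == "indolent"])
  a45 <- .group_union_area(regions[cls == "aggressive"])
  tot <- a3 + a45
  list(area_gp3 = a3, area_gp45 = a45,
       fraction_gp45 = if (tot > 0) a45 / tot else NA_real_)
}

# Union area of a set of simple polygons. Exact (shoelace sum) when bounding
# boxes are pairwise disjoint; overlapping clusters fall back to supersampled
# rasterization of the cluster's bounding box (documented approximation).
.group_union_area <- function(regions) {
  n <- length(regions)
  if (n == 0L) return(0)
  if (n == 1L) return(region_area(regions[[1]]))
  bb <- t(vapply(regions, function(r) c(range(r$vertices[, 1]), range(r$vertices[, 2])),
                 numeric(4)))  # xmin xmax ymin ymax
  overlap <- function(i, j)
    bb[i, 1] <= bb[j, 2] && bb[j, 1] <= bb[i, 2] && bb[i, 3] <= bb[j, 4] && bb[j, 3] <= bb[i, 4]
  # connected components under bbox overlap
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) if (overlap(i, j)) {
    ci <- comp[i]; cj <- comp[j]
    if (ci != cj) comp[comp == cj] <- ci
  }
  total <- 0
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1L) {
      total <- total + region_area(regions[[idx]])
    } else {
      total <- total + .raster_union_area(regions[idx], bb[idx, , drop = FALSE])
    }
  }
  total
}

.raster_union_area <- function(regions, bb, max_cells = 4e6) {
  x0 <- min(bb[, 1]); x1 <- max(bb[, 2]); y0 <- min(bb[, 3]); y1 <- max(bb[, 4])
  w <- x1 - x0; h <- y1 - y0
  if (w <= 0 || h <= 0) return(0)
  # sample at ~2x pixel pitch, capped
  res <- min(2, sqrt(max_cells / (w * h)))
  nx <- max(8L, ceiling(w * res)); ny <- max(8L, ceiling(h * res))
  px <- x0 + (seq_len(nx) - 0.5) * w / nx
  py <- y0 + (seq_len(ny) - 0.5) * h / ny
  gx <- rep(px, times = ny); gy <- rep(py, each = nx)
  inside <- rep(FALSE, nx * ny)
  for (r in regions) inside <- inside | .point_in_polygon(gx, gy, r$vertices)
  sum(inside) * (w / nx) * (h / ny)
}

# even-odd ray casting, vectorized over points
.point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assign a slide-level label from its annotations
#'
#' Implements the area-fraction rule: a slide with no carcinoma annotations is
#' benign; otherwise the slide is aggressive when Gleason pattern 4 and 5
#' regions occupy at least 20% of the total annotated carcinoma area, and
#' indolent when they occupy less. The 20% boundary is inclusive (exactly 20%
#' is aggressive).
#'
#' @param regions list of [annotation_region()] objects from one slide.
#' @param cutoff aggressive cut-off on the GP4/5 area fraction (default 0.20).
#' @return `"benign"`, `"indolent"` or `"aggressive"`.
#' @export
assign_wsi_label <- function(regions, cutoff = 0.20) {
  if (length(regions) == 0L) return("benign")
  s <- gleason_area_summary(regions)
  if (is.na(s$fraction_gp45)) return("benign")
  if (s$fraction_gp45 >= cutoff) "aggressive" else "indolent"
}
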