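#' Construct a slide image object
#'
#' A `slide_image` is the unit of inference in the pipeline: an 8-bit RGB
#' raster plus identifying metadata. Pixels are stored as an integer array of
#' dimension `height x width x 3` with values in `[0, 255]`. Coordinates used
#' throughout the package are 0-based with the origin at the top-left corner,
#' `x` increasing rightward (columns) and `y` downward (rows); windows are
#' half-open, so a tile of size `s` at `(x, y)` covers `[x, x+s) x [y, y+s)`.
#'
#' @param pixels numeric or integer array `height x width x 3`, values 0-255.
#' @param slide_id character scalar identifying the slide.
#' @param microns_per_pixel optional numeric scalar; physical pixel pitch.
#' @param magnification optional character tag such as `"x20"` (metadata only).
#' @return An object of class `slide_image` with fields `slide_id`, `pixels`,
#'   `width`, `height`, `microns_per_pixel`, `magnification`.
#' @export
slide_image <- function(pixels, slide_id = "slide",
                        microns_per_pixel = NULL, magnification = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("slide must have positive width and height", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(
    list(
      slide_id = as.character(slide_id),
      pixels = pixels,
      width = dim(pixels)[2],
      height = dim(pixels)[1],
      microns_per_pixel = if (is.null(microns_per_pixel)) NULL else as.numeric(microns_per_pixel),
      magnification = if (is.null(magnification)) NULL else as.character(magnification)
    ),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image '%s'> %d x %d px", x$slide_id, x$width, x$height))
  if (!is.null(x$microns_per_pixel)) cat(sprintf(", %.3f um/px", x$microns_per_pixel))
  if (!is.null(x$magnification)) cat(sprintf(" (%s)", x$magnification))
  cat("\n")
  invisible(x)
}

.slide_meta_path <- function(path) paste0(path, ".meta.json")

#' Read a slide raster from disk
#'
#' Supports 8-bit RGB TIFF and PNG. If a JSON sidecar (`<path>.meta.json`,
#' as written by [write_slide()]) is present, slide id and physical metadata
#' are restored from it; otherwise the slide id defaults to the file name and
#' `microns_per_pixel` is absent.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return A [slide_image()].
#' @export
read_slide <- function(path) {
  if (!file.exists(path)) stop("slide file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "tif" = , "tiff" = tryCatch(tiff::readTIFF(path),
      error = function(e) stop("cannot decode '", path, "' as TIFF: ", conditionMessage(e), call. = FALSE)),
    "png" = tryCatch(png::readPNG(path),
      error = function(e) stop("cannot decode '", path, "' as PNG: ", conditionMessage(e), call. = FALSE)),
    stop("unsupported slide codec '.", ext, "' (supported: tiff, png)", call. = FALSE)
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  px <- array(as.integer(round(raw * 255)), dim(raw))
  meta <- list(slide_id = tools::file_path_sans_ext(basename(path)),
               microns_per_pixel = NULL, magnification = NULL)
  mp <- .slide_meta_path(path)
  if (file.exists(mp)) {
    m <- jsonlite::read_json(mp, simplifyVector = TRUE)
    for (f in intersect(names(m), names(meta))) meta[[f]] <- m[[f]]
  }
  slide_image(px, meta$slide_id, meta$microns_per_pixel, meta$magnification)
}

#' Write a slide raster to disk
#'
#' Writes an 8-bit RGB TIFF (uncompressed) or PNG according to the file
#' extension, plus a JSON metadata sidecar when the slide carries metadata, so
#' that `read_slide(write_slide(s, p))` is lossless.
#'
#' @param slide a [slide_image()].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide_image"))
  img <- slide$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "tif" = , "tiff" = tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none"),
    "png" = png::writePNG(img, path),
    stop("unsupported output codec '.", ext, "'", call. = FALSE)
  )
  meta <- list(slide_id = slide$slide_id)
  if (!is.null(slide$microns_per_pixel)) meta$microns_per_pixel <- slide$microns_per_pixel
  if (!is.null(slide$magnification)) meta$magnification <- slide$magnification
  jsonlite::write_json(meta, .slide_meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract a square tile from a slide
#'
#' @param slide a [slide_image()].
#' @param x,y 0-based pixel coordinates of the tile's top-left corner.
#' @param size tile side length in pixels.
#' @return A `size x size x 3` integer array.
#' @export
extract_tile <- function(slide, x, y, size) {
  stopifnot(inherits(slide, "slide_image"))
  if (x < 0 || y < 0 || x + size > slide$width || y + size > slide$height)
    stop(sprintf(
      "tile window [%d,%d) x [%d,%d) out of slide bounds %d x %d",
      x, x + size, y, y + size, slide$width, slide$height), call. = FALSE)
  slide$pixels[(y + 1):(y + size), (x + 1):(x + size), , drop = FALSE]
}

# ---- annotations -----------------------------------------------------------

.gp_patterns <- c("GP3", "GP4", "GP5")

#' Construct a Gleason-pattern annotation region
#'
#' A simple (non-self-intersecting) polygon in slide pixel coordinates with a
#' Gleason pattern class. Vertices are given as an `n x 2` matrix of `(x, y)`
#' pairs; the polygon is closed implicitly (do not repeat the first vertex).
#'
#' @param slide_id character scalar.
#' @param vertices numeric `n x 2` matrix, `n >= 3`.
#' @param pattern one of `"GP3"`, `"GP4"`, `"GP5"`.
#' @return An object of class `annotation_region`.
#' @export
annotation_region <- function(slide_id, vertices, pattern) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    stop("`vertices` must be an n x 2 numeric matrix", call. = FALSE)
  # drop a repeated closing vertex if present
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (nrow(unique(vertices)) < 3L)
    stop("polygon must have at least 3 distinct vertices", call. = FALSE)
  if (!pattern %in% .gp_patterns)
    stop("unknown Gleason pattern '", pattern, "' (expected GP3/GP4/GP5)", call. = FALSE)
  if (any(vertices < 0))
    stop("polygon vertices must be non-negative slide coordinates", call. = FALSE)
  if (.polygon_self_intersects(vertices))
    stop("polygon is self-intersecting", call. = FALSE)
  structure(list(slide_id = as.character(slide_id), vertices = unname(vertices),
                 pattern = pattern),
            class = "annotation_region")
}

# Proper-crossing test between non-adjacent edges of the closed polygon.
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])  # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # edge n is adjacent to edge 1
    for (j in js) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Load annotation polygons from a GeoJSON file
#'
#' Expects a `FeatureCollection` whose features carry `Polygon` geometry
#' (exterior ring only) and a `pattern` property (`GP3`/`GP4`/`GP5`). Each
#' polygon is validated: at least 3 distinct vertices, simple (not
#' self-intersecting), known pattern.
#'
#' @param path path to a GeoJSON file.
#' @param slide_id slide id to attach when the file does not carry one.
#' @return A list of [annotation_region()] objects (possibly empty: a benign
#'   slide has no carcinoma annotations).
#' @export
load_annotations <- function(path, slide_id = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  sid <- slide_id %||% gj$slide_id %||% tools::file_path_sans_ext(basename(path))
  feats <- gj$features %||% list()
  out <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon"))
      stop("feature ", i, ": only Polygon geometry is supported", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    verts <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    pat <- f$properties$pattern
    if (is.null(pat) || !pat %in% .gp_patterns)
      stop("feature ", i, ": unknown or missing pattern '",
           if (is.null(pat)) "" else pat, "'", call. = FALSE)
    out[[i]] <- tryCatch(annotation_region(sid, verts, pat),
      error = function(e) stop("feature ", i, ": ", conditionMessage(e), call. = FALSE))
  }
  out
}

#' Write annotation polygons as GeoJSON
#'
#' @param regions list of [annotation_region()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(regions, path) {
  feats <- lapply(regions, function(r) {
    ring <- lapply(seq_len(nrow(r$vertices)), function(i) as.list(unname(r$vertices[i, ])))
    ring[[length(ring) + 1L]] <- ring[[1L]]  # close the ring
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(pattern = r$pattern))
  })
  sid <- if (length(regions)) regions[[1]]$slide_id else NULL
  gj <- list(type = "FeatureCollection", slide_id = sid, features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# ---- manifest --------------------------------------------------------------

.wsi_labels <- c("benign", "indolent", "aggressive")
.wsi_splits <- c("train", "validation", "test")

#' Read a slide manifest CSV
#'
#' The manifest lists one slide per row with columns
#' `slide_id,path,label,split,annotation_path` (annotation_path may be empty
#' for slides without region annotations). Labels and splits are validated
#' against their enums and slide ids must be unique.
#'
#' @param path CSV path.
#' @param check_paths validate that referenced files exist (resolved relative
#'   to the manifest's directory when not absolute).
#' @return A data.frame with the five manifest columns.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("slide_id", "path", "label", "split", "annotation_path")
  if (!all(req %in% names(m)))
    stop("manifest must have columns ", paste(req, collapse = ","), call. = FALSE)
  m <- m[, req]
  if (anyDuplicated(m$slide_id)) stop("duplicate slide_id in manifest", call. = FALSE)
  if (!all(m$label %in% .wsi_labels))
    stop("unknown label(s): ", paste(setdiff(m$label, .wsi_labels), collapse = ","), call. = FALSE)
  if (!all(m$split %in% .wsi_splits))
    stop("unknown split(s): ", paste(setdiff(m$split, .wsi_splits), collapse = ","), call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(p == "" | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$path <- resolve(m$path)
  m$annotation_path <- resolve(m$annotation_path)
  if (check_paths) {
    missing <- c(m$path[!file.exists(m$path)],
                 m$annotation_path[m$annotation_path != "" & !file.exists(m$annotation_path)])
    if (length(missing)) stop("manifest references missing file(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
  }
  m
}

#' Write a slide manifest CSV
#'
#' @param manifest data.frame with manifest columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
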