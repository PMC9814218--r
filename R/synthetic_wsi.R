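# Seeded generator of synthetic core-needle-biopsy slides.
#
# Slides are composed of elongated tissue fragments (biopsy cores) on a pure
# white background. Three procedural textures stand in for the visual
# classes the pipeline must separate: benign tissue (smooth light-pink field
# with sparse round voids), GP3-like carcinoma (regular small ring motif, the
# well-formed-gland pattern, mid-tone purple) and GP4/5-like carcinoma
# (fused irregular dark blobs). Carcinoma is painted inside rectangular
# regions that double as the annotation polygons, so the emitted slide label
# follows from the same 20% area-fraction rule the labeling module applies.
# Textures are tuned for separability by a small classifier, not for
# histological realism; mean luminance is ordered
# benign > GP3-like > GP4/5-like, and every tissue pixel is strictly darker
# than the white background so Otsu tissue detection is exact by
# construction.

#' Specification of one synthetic slide
#'
#' @param width,height slide size in pixels (desk-scale default 1536 x 1024).
#' @param n_fragments number of tissue fragments (biopsy cores).
#' @param class_mix named numeric vector `c(benign, gp3, gp45)`: target area
#'   fractions of the whole slide covered by benign tissue texture, GP3-like
#'   and GP4/5-like carcinoma. The remainder is white background.
#' @param gp45_fraction_of_carcinoma optional override in `[0, 1]`; when
#'   given, the carcinoma total `gp3 + gp45` is re-split so that the GP4/5
#'   share of carcinoma equals this value (the quantity the 20% labelling
#'   rule thresholds).
#' @param seed integer seed fixing all randomness of the slide.
#' @return A list of class `slide_spec`.
#' @export
slide_spec <- function(width = 1536L, height = 1024L, n_fragments = 3L,
                       class_mix = c(benign = 0.18, gp3 = 0.10, gp45 = 0.05),
                       gp45_fraction_of_carcinoma = NULL, seed = 1L) {
  stopifnot(width > 0, height > 0, n_fragments >= 1)
  cm <- class_mix[c("benign", "gp3", "gp45")]
  if (anyNA(cm)) stop("class_mix must name benign, gp3 and gp45 fractions", call. = FALSE)
  if (any(cm < 0) || sum(cm) > 1) stop("class_mix fractions must be >= 0 and sum to <= 1", call. = FALSE)
  if (!is.null(gp45_fraction_of_carcinoma)) {
    f <- gp45_fraction_of_carcinoma
    if (f < 0 || f > 1) stop("gp45_fraction_of_carcinoma must lie in [0, 1]", call. = FALSE)
    carc <- cm[["gp3"]] + cm[["gp45"]]
    cm[["gp45"]] <- carc * f
    cm[["gp3"]] <- carc * (1 - f)
  }
  if (sum(cm) > 0.6)
    stop("infeasible class_mix: tissue fractions sum to more than 0.6 of the slide", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_fragments = as.integer(n_fragments), class_mix = cm,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

# fragment geometry: vertical capsules (segment + radius) sized so the
# painted tissue area matches the requested fractions
.fragment_layout <- function(spec) {
  W <- spec$width; H <- spec$height; n <- spec$n_fragments
  target <- sum(spec$class_mix) * W * H
  a_frag <- target / n
  # capsule area 2 r len + pi r^2 = a_frag at a target straight length ~0.7 H
  len_t <- 0.7 * H
  r <- (-len_t + sqrt(len_t^2 + pi * a_frag)) / pi
  r <- min(r, 0.35 * W / n)
  len <- (a_frag - pi * r^2) / (2 * r)   # straight-section length
  if (r < 4 || len <= 0 || len + 2 * r > 0.94 * H)
    stop("infeasible class_mix: fragments do not fit on the slide", call. = FALSE)
  frags <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- W * (i - 0.5) / n + stats::runif(1, -0.03, 0.03) * W / n
    cy <- H / 2 + stats::runif(1, -0.02, 0.02) * H
    frags[[i]] <- list(cx = cx, cy = cy, r = r, len = len)
  }
  frags
}

# rectangular carcinoma regions stacked along each fragment axis; areas are
# exact so the annotation-derived GP4/5 fraction matches the requested value
.carcinoma_layout <- function(spec, frags) {
  W <- spec$width; H <- spec$height
  a3 <- spec$class_mix[["gp3"]] * W * H
  a45 <- spec$class_mix[["gp45"]] * W * H
  if (a3 + a45 <= 0) return(list())
  n <- length(frags)
  regions <- list()
  for (i in seq_len(n)) {
    fr <- frags[[i]]
    w_r <- 1.4 * fr$r
    h45 <- (a45 / n) / w_r
    h3 <- (a3 / n) / w_r
    gap <- if (h45 > 0 && h3 > 0) 6 else 0
    stack_h <- h45 + h3 + gap
    if (stack_h > 0.95 * fr$len)
      stop("infeasible class_mix: carcinoma does not fit inside the fragments", call. = FALSE)
    jit <- stats::runif(1, -0.5, 0.5) * (0.9 * fr$len - stack_h)
    y0 <- fr$cy - stack_h / 2 + jit
    x0 <- fr$cx - w_r / 2; x1 <- fr$cx + w_r / 2
    if (h45 > 0) {
      regions[[length(regions) + 1L]] <- list(
        pattern = "GP4",
        verts = cbind(c(x0, x1, x1, x0), c(y0, y0, y0 + h45, y0 + h45)))
      y0 <- y0 + h45 + gap
    }
    if (h3 > 0) {
      regions[[length(regions) + 1L]] <- list(
        pattern = "GP3",
        verts = cbind(c(x0, x1, x1, x0), c(y0, y0, y0 + h3, y0 + h3)))
    }
  }
  regions
}

# ---- procedural textures ---------------------------------------------------
# xs, ys are 0-based pixel coordinate vectors; each returns an n x 3 matrix

.tex_benign <- function(xs, ys) {
  base <- cbind(225 + 6 * sin(xs / 41) + 4 * cos(ys / 53),
                170 + 7 * sin(xs / 37 + 1) + 5 * cos(ys / 47),
                200 + 5 * sin(xs / 43 + 2) + 5 * cos(ys / 59))
  base
}

.tex_gp3 <- function(xs, ys) {
  p <- 14
  cx <- (xs %% p) - p / 2 + 0.5
  cy <- (ys %% p) - p / 2 + 0.5
  d <- sqrt(cx^2 + cy^2)
  ring <- abs(d - 4.5) < 1.3          # gland wall
  lumen <- d < 2.2                    # gland lumen
  base <- cbind(rep(205, length(xs)), rep(150, length(xs)), rep(195, length(xs)))
  base[ring, ] <- sweep(base[ring, , drop = FALSE], 2, c(48, 52, 44), "-")
  base[lumen, ] <- sweep(base[lumen, , drop = FALSE], 2, c(18, 22, 16), "+")
  base
}

.tex_gp45 <- function(xs, ys) {
  blob <- sin(xs / 7.3 + 1.7 * sin(ys / 11.1)) * cos(ys / 8.7 + 1.3 * sin(xs / 13.7))
  base <- cbind(rep(150, length(xs)), rep(105, length(xs)), rep(160, length(xs)))
  dark <- blob > 0.15
  base[dark, ] <- sweep(base[dark, , drop = FALSE], 2, c(42, 40, 36), "-")
  light <- blob < -0.85
  base[light, ] <- sweep(base[light, , drop = FALSE], 2, c(15, 15, 15), "+")
  base
}

#' Generate one synthetic slide
#'
#' Renders the slide described by a [slide_spec()]: tissue fragments on a
#' white background, carcinoma regions wrapped in matching GP3/GP4 annotation
#' polygons, and the ground-truth label derived from those annotations via
#' [assign_wsi_label()]. Output is byte-identical under an identical spec and
#' seed.
#'
#' @param spec a [slide_spec()].
#' @param slide_id identifier for the emitted slide.
#' @return A list with `slide` (a [slide_image()]), `annotations` (list of
#'   [annotation_region()]) and `label`.
#' @export
generate_slide <- function(spec, slide_id = sprintf("synthetic_%d", spec$seed)) {
  stopifnot(inherits(spec, "slide_spec"))
  W <- spec$width; H <- spec$height
  .with_seed(spec$seed, {
    frags <- .fragment_layout(spec)
    carc <- .carcinoma_layout(spec, frags)
    R <- matrix(255, H, W); G <- matrix(255, H, W); B <- matrix(255, H, W)
    xs_col <- rep(0:(W - 1L), each = H)     # column-major coordinate fields
    ys_col <- rep(0:(H - 1L), times = W)
    tissue_idx <- integer(0)
    for (fr in frags) {
      dy <- pmax(0, abs(ys_col - fr$cy) - fr$len / 2)
      idx <- which((xs_col - fr$cx)^2 + dy^2 <= fr$r^2)
      tex <- .tex_benign(xs_col[idx], ys_col[idx])
      R[idx] <- tex[, 1]; G[idx] <- tex[, 2]; B[idx] <- tex[, 3]
      tissue_idx <- c(tissue_idx, idx)
      # sparse round voids
      n_void <- max(1L, round(length(idx) / 9000))
      vx <- stats::runif(n_void, fr$cx - fr$r, fr$cx + fr$r)
      vy <- stats::runif(n_void, fr$cy - fr$len / 2 - fr$r, fr$cy + fr$len / 2 + fr$r)
      for (v in seq_len(n_void)) {
        vi <- idx[(xs_col[idx] - vx[v])^2 + (ys_col[idx] - vy[v])^2 <= 49]
        R[vi] <- R[vi] + 20; G[vi] <- G[vi] + 25; B[vi] <- B[vi] + 20
      }
    }
    for (rg in carc) {
      v <- rg$verts
      idx <- which(xs_col >= min(v[, 1]) & xs_col < max(v[, 1]) &
                   ys_col >= min(v[, 2]) & ys_col < max(v[, 2]))
      tex <- if (rg$pattern == "GP3") .tex_gp3(xs_col[idx], ys_col[idx])
             else .tex_gp45(xs_col[idx], ys_col[idx])
      R[idx] <- tex[, 1]; G[idx] <- tex[, 2]; B[idx] <- tex[, 3]
    }
    tissue_idx <- unique(tissue_idx)
    noise <- stats::rnorm(length(tissue_idx), 0, 4)
    R[tissue_idx] <- R[tissue_idx] + noise
    G[tissue_idx] <- G[tissue_idx] + stats::rnorm(length(tissue_idx), 0, 4)
    B[tissue_idx] <- B[tissue_idx] + stats::rnorm(length(tissue_idx), 0, 4)
    # tissue stays strictly darker than the pure-white background
    # clip tissue well below the pure-white background so the global Otsu
    # threshold always lands in the empty luminance gap above the tissue
    R[tissue_idx] <- pmin(pmax(R[tissue_idx], 0), 235)
    G[tissue_idx] <- pmin(pmax(G[tissue_idx], 0), 235)
    B[tissue_idx] <- pmin(pmax(B[tissue_idx], 0), 235)
    px <- array(0L, c(H, W, 3))
    px[, , 1] <- round(R); px[, , 2] <- round(G); px[, , 3] <- round(B)
    slide <- slide_image(px, slide_id, microns_per_pixel = 0.5, magnification = "x20")
    ann <- lapply(carc, function(rg) annotation_region(slide_id, rg$verts, rg$pattern))
    list(slide = slide, annotations = ann, label = assign_wsi_label(ann))
  })
}

#' Generate a balanced synthetic dataset on disk
#'
#' Writes `3 * n_per_label` slides (TIFF), their annotation files (GeoJSON;
#' empty FeatureCollection for benign slides) and a manifest CSV, balanced
#' across the three labels and across train/validation/test splits. Indolent
#' slides are drawn with a GP4/5 carcinoma fraction below 0.2 and aggressive
#' slides at or above it, both cycles including near-boundary values
#' (0.15-0.25) so double-label behaviour is exercised.
#'
#' @param n_per_label slides per label (>= 1).
#' @param dir output directory (created if needed).
#' @param split_fractions named fractions for train/validation/test; each
#'   label is split the same way, with at least one slide per non-zero split.
#' @param seed integer master seed.
#' @param width,height slide size in pixels.
#' @return The manifest data.frame (absolute paths), invisibly also written
#'   to `dir/manifest.csv`.
#' @export
generate_dataset <- function(n_per_label, dir,
                             split_fractions = c(train = 0.4, validation = 0.2, test = 0.4),
                             seed = 1L, width = 1536L, height = 1024L) {
  stopifnot(n_per_label >= 1)
  sf <- split_fractions[c("train", "validation", "test")]
  if (anyNA(sf) || any(sf < 0) || abs(sum(sf) - 1) > 1e-8)
    stop("split_fractions must name train/validation/test and sum to 1", call. = FALSE)
  dir.create(file.path(dir, "slides"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
  # per-label split counts: floor then distribute remainder, keeping >= 1
  # slide in every split with positive fraction when possible
  counts <- floor(sf * n_per_label)
  while (sum(counts) < n_per_label) {
    short <- which.max(sf * n_per_label - counts)
    counts[short] <- counts[short] + 1
  }
  for (s in names(counts)) if (sf[[s]] > 0 && counts[[s]] == 0 && any(counts > 1)) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1
    counts[[s]] <- counts[[s]] + 1
  }
  gp45_indolent <- c(0, 0.06, 0.12, 0.17)
  gp45_aggressive <- c(0.25, 0.45, 0.70, 1.00)
  rows <- list()
  .with_seed(seed, {
    for (label in .wsi_labels) {
      splits <- sample(rep(names(counts), times = counts))
      for (i in seq_len(n_per_label)) {
        sid <- sprintf("%s_%02d", label, i)
        slide_seed <- (seed * 1000L + length(rows) * 7L + i) %% .Machine$integer.max
        spec <- switch(label,
          benign = slide_spec(width, height,
                              class_mix = c(benign = 0.33, gp3 = 0, gp45 = 0),
                              seed = slide_seed),
          indolent = slide_spec(width, height,
                                class_mix = c(benign = 0.18, gp3 = 0.10, gp45 = 0.05),
                                gp45_fraction_of_carcinoma =
                                  gp45_indolent[(i - 1L) %% length(gp45_indolent) + 1L],
                                seed = slide_seed),
          aggressive = slide_spec(width, height,
                                  class_mix = c(benign = 0.18, gp3 = 0.10, gp45 = 0.05),
                                  gp45_fraction_of_carcinoma =
                                    gp45_aggressive[(i - 1L) %% length(gp45_aggressive) + 1L],
                                  seed = slide_seed))
        gen <- generate_slide(spec, sid)
        if (gen$label != label)
          stop("internal: generated label '", gen$label, "' does not match '", label, "'")
        spath <- file.path(dir, "slides", paste0(sid, ".tiff"))
        apath <- file.path(dir, "annotations", paste0(sid, ".geojson"))
        write_slide(gen$slide, spath)
        if (length(gen$annotations)) {
          write_annotations(gen$annotations, apath)
        } else {
          jsonlite::write_json(list(type = "FeatureCollection", slide_id = sid,
                                    features = list()),
                               apath, auto_unbox = TRUE, null = "null")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          slide_id = sid, path = normalizePath(spath), label = label,
          split = splits[i], annotation_path = normalizePath(apath),
          stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Generate a synthetic rating matrix
#'
#' Each item carries a latent category drawn uniformly from
#' benign/indolent/aggressive; each rater reports the latent category with
#' probability `agreement_level` and otherwise a uniformly chosen *other*
#' category. `agreement_level = 1` yields perfect agreement;
#' `agreement_level = 1/3` makes every report uniform, i.e. chance-level
#' agreement.
#'
#' @param n_items,n_raters matrix size.
#' @param agreement_level probability in `[0, 1]` of reporting the latent
#'   category.
#' @param seed integer seed.
#' @return A [rating_matrix()].
#' @export
generate_rating_matrix <- function(n_items, n_raters, agreement_level, seed = 1L) {
  stopifnot(agreement_level >= 0, agreement_level <= 1)
  .with_seed(seed, {
    latent <- sample(.wsi_labels, n_items, replace = TRUE)
    m <- matrix("", n_items, n_raters,
                dimnames = list(paste0("item_", seq_len(n_items)),
                                paste0("rater_", seq_len(n_raters))))
    for (j in seq_len(n_raters)) {
      agree <- stats::runif(n_items) < agreement_level
      other <- vapply(latent, function(l) sample(setdiff(.wsi_labels, l), 1L), character(1))
      m[, j] <- ifelse(agree, latent, other)
    }
    rating_matrix(m)
  })
}
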