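# Orchestration of the two training modes: WS (hard-example mining driven by
# slide labels only) and FS+WS (initial sampling restricted to annotated
# regions, followed by the same hard mining).

#' Training configuration
#'
#' Defaults follow the published training recipe: k = 8 mined tiles per slide
#' per head, a training subset of N = 256 tiles, batches of 32, Adam with
#' learning rate 0.001 (beta1 0.9, beta2 0.999), early stopping after 10
#' epochs without validation improvement, 512-px tiles at stride 256.
#'
#' @param k hard-mined tiles per slide per head.
#' @param subset_size pool size `N` that triggers a training round.
#' @param batch_size tiles per optimization step.
#' @param lr,beta1,beta2 Adam parameters.
#' @param patience early-stopping patience in epochs.
#' @param warmup_epochs epochs of random balanced sampling before hard mining
#'   starts.
#' @param tiles_per_wsi_warmup tiles sampled per slide during warmup (a
#'   balanced 3-slide draw therefore yields `3 *` this many tiles; batches
#'   are assembled across draws).
#' @param tile_size,stride sliding-window geometry in pixels.
#' @param min_tissue_fraction minimum tissue coverage for a candidate tile.
#' @param mask_downsample tissue-mask grid cell size in pixels.
#' @param max_epochs hard cap on training epochs.
#' @param cross_label supervision of a mined tile for the head *not* matching
#'   its slide's label: `"negative"` (default; a slide is a negative example
#'   for every head other than its own, so an indolent slide supplies mined
#'   negatives to the aggressive head and vice versa) or `"masked"` (the
#'   opposite head receives no gradient from carcinoma slides).
#' @param policy trainable-parameter policy passed to [tile_classifier()].
#' @param draws_per_epoch balanced 3-slide draws per epoch; `NULL` (default)
#'   means one pass over the train split (`ceiling(n_train / 3)`). Raising it
#'   packs more optimization steps into each epoch, which small desk-scale
#'   datasets need for the fixed fine-tuning learning rate to make progress
#'   within the early-stopping patience.
#' @param seed integer seed fixing sampling, initialization and pool
#'   shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(k = 8L, subset_size = 256L, batch_size = 32L,
                            lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                            patience = 10L, warmup_epochs = 2L,
                            tiles_per_wsi_warmup = 8L,
                            tile_size = 512L, stride = 256L,
                            min_tissue_fraction = 0.25, mask_downsample = 16L,
                            max_epochs = 100L,
                            cross_label = c("negative", "masked"),
                            policy = c("partial", "all"),
                            draws_per_epoch = NULL, seed = 1L) {
  cross_label <- match.arg(cross_label)
  policy <- match.arg(policy)
  cfg <- list(k = as.integer(k), subset_size = as.integer(subset_size),
              batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
              beta2 = beta2, patience = as.integer(patience),
              warmup_epochs = as.integer(warmup_epochs),
              tiles_per_wsi_warmup = as.integer(tiles_per_wsi_warmup),
              tile_size = as.integer(tile_size), stride = as.integer(stride),
              min_tissue_fraction = min_tissue_fraction,
              mask_downsample = as.integer(mask_downsample),
              max_epochs = as.integer(max_epochs), cross_label = cross_label,
              policy = policy,
              draws_per_epoch = if (is.null(draws_per_epoch)) NULL else as.integer(draws_per_epoch),
              seed = as.integer(seed))
  if (cfg$k < 1 || cfg$subset_size < 1 || cfg$batch_size < 1 ||
      cfg$patience < 1 || cfg$max_epochs < 1 || cfg$tiles_per_wsi_warmup < 1)
    stop("all counts in training_config must be positive", call. = FALSE)
  if (cfg$k > cfg$subset_size) stop("k must not exceed subset_size", call. = FALSE)
  if (cfg$batch_size > cfg$subset_size)
    stop("batch_size must not exceed subset_size", call. = FALSE)
  structure(cfg, class = "training_config")
}

# weak labels (indolent, aggressive) for a tile from a slide with the given
# label; the head matching the slide label is positive, benign is negative
# for both, and the opposite head on carcinoma slides follows cross_label
.weak_labels <- function(slide_label, cross_label) {
  other <- if (cross_label == "negative") 0 else NA_real_
  switch(slide_label,
    benign = c(0, 0),
    indolent = c(1, other),
    aggressive = c(other, 1))
}

# ---- slide cache -----------------------------------------------------------
# Per slide: tissue-tile positions, their pooled representations, and which
# tiles sit inside a matching-class annotation (for FS warmup sampling).

.build_slide_cache <- function(rows, config, need_annotations = FALSE) {
  cache <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    slide <- read_slide(rows$path[i])
    th <- otsu_threshold(luminance_histogram(slide))
    mask <- compute_tissue_mask(slide, th, config$mask_downsample)
    grid <- enumerate_tiles(mask, config$tile_size, config$stride,
                            config$min_tissue_fraction)
    n <- nrow(grid$positions)
    if (n == 0L)
      stop("slide '", rows$slide_id[i], "' has no tissue tiles at tile size ",
           config$tile_size, call. = FALSE)
    tiles <- lapply(seq_len(n), function(t)
      extract_tile(slide, grid$positions[t, 1], grid$positions[t, 2], config$tile_size))
    pooled <- .pool_tiles(tiles, config$tile_size)
    ann_ok <- rep(FALSE, n)
    if (need_annotations && rows$label[i] != "benign" &&
        !is.na(rows$annotation_path[i]) && rows$annotation_path[i] != "") {
      anns <- load_annotations(rows$annotation_path[i], rows$slide_id[i])
      match_cls <- rows$label[i]
      cx <- grid$positions[, 1] + config$tile_size / 2
      cy <- grid$positions[, 2] + config$tile_size / 2
      for (a in anns) {
        if (pattern_to_class(a$pattern) == match_cls)
          ann_ok <- ann_ok | .point_in_polygon(cx, cy, a$vertices)
      }
    }
    cache[[i]] <- list(slide_id = rows$slide_id[i], label = rows$label[i],
                       positions = grid$positions, pooled = pooled,
                       ann_ok = ann_ok, n = n)
  }
  names(cache) <- rows$slide_id
  cache
}

# draw one balanced 3-slide sample of tile indices from a cache
.sample_balanced_indices <- function(cache, mode, config) {
  labels <- vapply(cache, `[[`, character(1), "label")
  draw <- list()
  for (lab in .wsi_labels) {
    ids <- which(labels == lab)
    if (length(ids) == 0L)
      stop("no train slides with label '", lab, "'", call. = FALSE)
    ci <- ids[[sample.int(length(ids), 1L)]]
    entry <- cache[[ci]]
    pool_from <- seq_len(entry$n)
    if (mode == "FS+WS" && lab != "benign") {
      pool_from <- which(entry$ann_ok)
      if (length(pool_from) == 0L)
        stop("FS+WS sampling: slide '", entry$slide_id,
             "' has no tiles centred in a matching-class annotation", call. = FALSE)
    }
    idx <- pool_from[sample.int(length(pool_from), config$tiles_per_wsi_warmup,
                                replace = length(pool_from) < config$tiles_per_wsi_warmup)]
    draw[[lab]] <- list(cache_index = ci, tile_index = idx)
  }
  draw
}

#' Draw one balanced warmup batch of tiles
#'
#' Samples three slides from the train split, one per label, and an equal
#' number of tiles from each. In `"WS"` mode tiles come from all tissue of
#' every slide; in `"FS+WS"` mode, tiles of carcinoma slides are restricted
#' to positions whose centre lies inside an annotation polygon of the class
#' matching the slide's label (benign tiles always come from all tissue).
#' Weak labels follow the slide label: the matching head is positive, benign
#' slides are negative for both heads, and the opposite head on carcinoma
#' slides follows `config$cross_label`.
#'
#' Sampling uses the current RNG state; seed it (or use [run_training()],
#' which does) for reproducibility.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param mode `"WS"` or `"FS+WS"`.
#' @param config a [training_config()].
#' @return A [tile_batch()] of `3 * config$tiles_per_wsi_warmup` tiles.
#' @export
sample_balanced_batch <- function(manifest, mode = c("WS", "FS+WS"),
                                  config = training_config()) {
  mode <- match.arg(mode)
  rows <- manifest[manifest$split == "train", , drop = FALSE]
  for (lab in .wsi_labels)
    if (!any(rows$label == lab))
      stop("no train slides with label '", lab, "'", call. = FALSE)
  cache <- .build_slide_cache(rows, config, need_annotations = (mode == "FS+WS"))
  draw <- .sample_balanced_indices(cache, mode, config)
  pooled <- NULL; labs <- NULL; sids <- character(0)
  for (lab in names(draw)) {
    e <- cache[[draw[[lab]]$cache_index]]
    pooled <- .abind_pooled(pooled, e$pooled[draw[[lab]]$tile_index, , , , drop = FALSE])
    wl <- .weak_labels(lab, config$cross_label)
    labs <- rbind(labs, matrix(wl, length(draw[[lab]]$tile_index), 2, byrow = TRUE))
    sids <- c(sids, rep(e$slide_id, length(draw[[lab]]$tile_index)))
  }
  tile_batch(labels = labs, slide_ids = sids, pooled = pooled)
}

.abind_pooled <- function(a, b) {
  if (is.null(a)) return(b)
  na <- dim(a)[1]; nb <- dim(b)[1]
  m <- rbind(matrix(a, na, prod(dim(a)[-1])), matrix(b, nb, prod(dim(b)[-1])))
  array(m, c(na + nb, dim(a)[-1]))
}

#' Select the k hardest tiles of a slide for one head
#'
#' Scores every grid position with the classifier and returns the `k`
#' positions with the highest probability for the requested head (all
#' positions when the grid holds fewer than `k`). Ties are broken by
#' row-major position order.
#'
#' @param classifier a [tile_classifier()].
#' @param slide a [slide_image()].
#' @param grid a `tile_grid` over the slide (see [enumerate_tiles()]).
#' @param head `"indolent"` or `"aggressive"`.
#' @param k number of tiles to select.
#' @return Integer matrix of `(x, y)` positions, `min(k, n)` rows.
#' @export
mine_hard_tiles <- function(classifier, slide, grid,
                            head = c("indolent", "aggressive"), k) {
  head <- match.arg(head)
  stopifnot(inherits(grid, "tile_grid"))
  if (nrow(grid$positions) == 0L) stop("cannot mine an empty tile grid", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  tiles <- lapply(seq_len(nrow(grid$positions)), function(t)
    extract_tile(slide, grid$positions[t, 1], grid$positions[t, 2], grid$tile_size))
  scores <- predict_tiles(classifier, tiles)[, paste0("p_", head)]
  grid$positions[.top_k(scores, k), , drop = FALSE]
}

# indices of the k largest scores; ties broken by position (ascending index)
.top_k <- function(scores, k) {
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(min(k, length(scores)))]
}

#' Best epoch and stopping epoch under early stopping
#'
#' Scans a validation-loss sequence as [run_training()] does: the best epoch
#' is the first epoch attaining the lowest loss so far, and training stops at
#' the first epoch lying `patience` epochs after the current best (or at the
#' end of the sequence).
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience integer patience in epochs.
#' @return List with `best_epoch` and `stopped_epoch`.
#' @export
early_stopping <- function(val_losses, patience) {
  best <- Inf; best_epoch <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
    }
    if (e - best_epoch >= patience)
      return(list(best_epoch = best_epoch, stopped_epoch = e))
  }
  list(best_epoch = best_epoch, stopped_epoch = length(val_losses))
}

# WSI-level validation loss: max-aggregated scores vs the slide's label,
# mean binary cross-entropy over both heads
.validation_loss <- function(classifier, cache, clip = 1e-15) {
  tot <- 0; n <- 0
  for (e in cache) {
    p <- .predict_pooled(classifier, e$pooled)
    s <- pmin(pmax(c(max(p[, 1]), max(p[, 2])), clip), 1 - clip)
    y <- c(as.numeric(e$label == "indolent"), as.numeric(e$label == "aggressive"))
    tot <- tot - sum(y * log(s) + (1 - y) * log(1 - s))
    n <- n + 2L
  }
  tot / n
}

#' Train a tile classifier by (weakly) supervised hard-example mining
#'
#' Epochs `1..warmup_epochs` draw random balanced tile batches (in `"FS+WS"`
#' mode restricted to annotated regions on carcinoma slides). Subsequent
#' epochs alternate inference and training: for each balanced 3-slide draw,
#' every slide's tissue tiles are scored, the `k` highest-probability tiles
#' per relevant head are added to a training pool with weak labels, and
#' whenever the pool reaches `subset_size` tiles it is shuffled and consumed
#' in batches of `batch_size` (leftover tiles persist to the next round).
#' After every epoch the WSI-level validation loss is evaluated; training
#' stops when it has not improved for `patience` epochs (or at `max_epochs`)
#' and the parameters from the best-validation-loss epoch are returned.
#'
#' @param manifest manifest data.frame with non-empty train and validation
#'   splits.
#' @param config a [training_config()].
#' @param mode `"WS"` (hard mining only) or `"FS+WS"` (annotated-region
#'   warmup, then hard mining).
#' @return A list of class `training_run`: `classifier` (best-epoch model),
#'   `history` (per-epoch data.frame with train/validation losses and a
#'   parameter checksum), `best_epoch`, `stopped_epoch`, `mode`, `config`.
#' @export
run_training <- function(manifest, config = training_config(),
                         mode = c("WS", "FS+WS")) {
  mode <- match.arg(mode)
  tr_rows <- manifest[manifest$split == "train", , drop = FALSE]
  va_rows <- manifest[manifest$split == "validation", , drop = FALSE]
  if (nrow(tr_rows) == 0L || nrow(va_rows) == 0L)
    stop("manifest needs non-empty train and validation splits", call. = FALSE)
  .with_seed(config$seed, {
    tr_cache <- .build_slide_cache(tr_rows, config, need_annotations = (mode == "FS+WS"))
    va_cache <- .build_slide_cache(va_rows, config, need_annotations = FALSE)
    clf <- tile_classifier(config$tile_size, config$policy, seed = config$seed)
    opt <- adam_config(lr = config$lr, beta1 = config$beta1, beta2 = config$beta2)
    labels <- vapply(tr_cache, `[[`, character(1), "label")
    n_draws <- config$draws_per_epoch %||% max(1L, ceiling(length(tr_cache) / 3))
    pool_x <- NULL; pool_y <- NULL
    history <- NULL
    best_epoch <- 0L; best_loss <- Inf; best_state <- NULL
    stopped_epoch <- config$max_epochs

    consume_pool <- function(min_fill) {
      # consume the pool in full batches once it holds >= min_fill tiles
      losses <- c()
      if (is.null(pool_x) || dim(pool_x)[1] < min_fill) return(losses)
      n <- dim(pool_x)[1]
      perm <- sample.int(n)
      pool_x <<- pool_x[perm, , , , drop = FALSE]
      pool_y <<- pool_y[perm, , drop = FALSE]
      n_batches <- n %/% config$batch_size
      for (b in seq_len(n_batches)) {
        sel <- ((b - 1L) * config$batch_size + 1L):(b * config$batch_size)
        batch <- tile_batch(labels = pool_y[sel, , drop = FALSE], pooled =
                              pool_x[sel, , , , drop = FALSE])
        st <- train_step(clf, batch, opt)
        clf <<- st$classifier
        losses <- c(losses, st$loss)
      }
      used <- n_batches * config$batch_size
      if (used == n) { pool_x <<- NULL; pool_y <<- NULL }
      else {
        pool_x <<- pool_x[-seq_len(used), , , , drop = FALSE]
        pool_y <<- pool_y[-seq_len(used), , drop = FALSE]
      }
      losses
    }

    for (epoch in seq_len(config$max_epochs)) {
      step_losses <- c()
      if (epoch <= config$warmup_epochs) {
        for (d in seq_len(n_draws)) {
          draw <- .sample_balanced_indices(tr_cache, mode, config)
          for (lab in names(draw)) {
            e <- tr_cache[[draw[[lab]]$cache_index]]
            pool_x <- .abind_pooled(pool_x,
              e$pooled[draw[[lab]]$tile_index, , , , drop = FALSE])
            wl <- .weak_labels(lab, config$cross_label)
            pool_y <- rbind(pool_y,
              matrix(wl, length(draw[[lab]]$tile_index), 2, byrow = TRUE))
          }
          step_losses <- c(step_losses, consume_pool(config$batch_size))
        }
      } else {
        for (d in seq_len(n_draws)) {
          slide_ids <- vapply(.wsi_labels, function(lab) {
            ids <- which(labels == lab)
            ids[[sample.int(length(ids), 1L)]]
          }, integer(1))
          for (ci in slide_ids) {
            e <- tr_cache[[ci]]
            scores <- .predict_pooled(clf, e$pooled)
            wl <- .weak_labels(e$label, config$cross_label)
            for (h in 1:2) {
              if (is.na(wl[h])) next  # masked cross-head: do not mine it
              top <- .top_k(scores[, h], config$k)
              lab_rows <- matrix(NA_real_, length(top), 2)
              lab_rows[, h] <- wl[h]
              pool_x <- .abind_pooled(pool_x, e$pooled[top, , , , drop = FALSE])
              pool_y <- rbind(pool_y, lab_rows)
            }
          }
          step_losses <- c(step_losses, consume_pool(config$subset_size))
        }
      }
      val_loss <- .validation_loss(clf, va_cache)
      if (!is.finite(val_loss) || (length(step_losses) && !all(is.finite(step_losses))))
        stop("non-finite loss at epoch ", epoch, call. = FALSE)
      train_loss <- if (length(step_losses)) mean(step_losses) else NA_real_
      checksum <- sum(unlist(clf$params)^2)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        pool_size = if (is.null(pool_x)) 0L else dim(pool_x)[1],
        param_checksum = checksum))
      if (val_loss < best_loss) {
        best_loss <- val_loss
        best_epoch <- epoch
        best_state <- list(params = clf$params, buffers = clf$buffers)
      }
      if (epoch - best_epoch >= config$patience) {
        stopped_epoch <- epoch
        break
      }
      stopped_epoch <- epoch
    }
    clf$params <- best_state$params
    clf$buffers <- best_state$buffers
    structure(list(classifier = clf, history = history,
                   best_epoch = best_epoch, stopped_epoch = stopped_epoch,
                   mode = mode, config = config),
              class = "training_run")
  })
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf("<training_run> mode %s, stopped at epoch %d (best epoch %d, val loss %.4f)\n",
              x$mode, x$stopped_epoch, x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}
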