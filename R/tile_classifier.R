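# Tile-scoring model: a small two-head convolutional network.
#
# Tiles are average-pooled to a fixed 16x16x3 representation, then pass
# through two 3x3 convolution blocks (conv -> batch norm with affine
# parameters -> ReLU), a 2x2 average pool between them, global average
# pooling, and a dense layer with two independent sigmoid outputs
# (p_indolent, p_aggressive). Because the heads are independent sigmoids a
# tile may legitimately score high on both; benign is the absence of both.
# All arithmetic is plain R matrix algebra so training is exactly
# reproducible on one CPU.

.POOL_P <- 16L   # side of the pooled input representation
.C1 <- 8L        # channels after conv block 1
.C2 <- 16L       # channels after conv block 2
.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

#' Adam optimizer configuration
#'
#' @param lr learning rate (default 0.001, the fine-tuning rate used
#'   throughout the pipeline).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9 / 0.999).
#' @param eps numerical stabilizer.
#' @return A list of class `adam_config`.
#' @export
adam_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_config")
}

#' Construct a tile classifier
#'
#' @param input_size tile side length in pixels the model accepts; must be a
#'   multiple of 16 (default 512).
#' @param policy trainable-parameter policy: `"partial"` (only batch-norm
#'   affine parameters and the final classification layer are trainable;
#'   convolution weights stay frozen at their initial values) or `"all"`.
#' @param seed integer seed fixing the parameter initialization.
#' @return An object of class `tile_classifier`.
#' @export
tile_classifier <- function(input_size = 512L, policy = c("partial", "all"),
                            seed = 1L) {
  policy <- match.arg(policy)
  input_size <- as.integer(input_size)
  if (input_size < .POOL_P || input_size %% .POOL_P != 0L)
    stop("input_size must be a positive multiple of ", .POOL_P, call. = FALSE)
  params <- .with_seed(seed, {
    list(
      conv1_w = matrix(stats::rnorm(27 * .C1, sd = sqrt(2 / 27)), 27, .C1),
      conv1_b = numeric(.C1),
      bn1_gamma = rep(1, .C1), bn1_beta = numeric(.C1),
      conv2_w = matrix(stats::rnorm(9 * .C1 * .C2, sd = sqrt(2 / (9 * .C1))), 9 * .C1, .C2),
      conv2_b = numeric(.C2),
      bn2_gamma = rep(1, .C2), bn2_beta = numeric(.C2),
      head_w = matrix(stats::rnorm(.C2 * 2, sd = sqrt(1 / .C2)), .C2, 2),
      head_b = numeric(2)
    )
  })
  structure(
    list(backbone_id = "tiny_cnn_2head", input_size = input_size,
         trainable_policy = policy, params = params,
         buffers = list(bn1_mean = numeric(.C1), bn1_var = rep(1, .C1),
                        bn2_mean = numeric(.C2), bn2_var = rep(1, .C2)),
         opt_state = NULL, init_seed = as.integer(seed)),
    class = "tile_classifier"
  )
}

#' @export
print.tile_classifier <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<tile_classifier '%s'> input %d px, policy '%s', %d parameters\n",
              x$backbone_id, x$input_size, x$trainable_policy, n_par))
  invisible(x)
}

#' Trainable-parameter descriptor for a classifier
#'
#' Under the `"partial"` policy only the affine parameters of the
#' normalization layers (`bn*_gamma`, `bn*_beta`) and the final
#' classification layer (`head_w`, `head_b`) are marked trainable; every
#' other parameter is frozen. Under `"all"`, every parameter is trainable.
#'
#' @param classifier a [tile_classifier()].
#' @return Named logical vector over parameter groups; `TRUE` = trainable.
#' @export
partial_finetune_setup <- function(classifier) {
  stopifnot(inherits(classifier, "tile_classifier"))
  nm <- names(classifier$params)
  norm_affine <- grepl("^bn\\d+_(gamma|beta)$", nm)
  if (!any(norm_affine))
    stop("backbone has no identifiable normalization-layer affine parameters",
         call. = FALSE)
  if (classifier$trainable_policy == "all") {
    stats::setNames(rep(TRUE, length(nm)), nm)
  } else {
    stats::setNames(norm_affine | grepl("^head_", nm), nm)
  }
}

#' Assemble a batch of tiles with weak labels
#'
#' @param tiles list of `s x s x 3` tile rasters (values 0-255), or `NULL`
#'   when `pooled` is supplied.
#' @param labels `n x 2` matrix; columns `indolent`, `aggressive`; entries
#'   `1` (positive), `0` (negative) or `NA` (masked: contributes no loss and
#'   no gradient for that head).
#' @param slide_ids character vector of source slides (length n).
#' @param pooled optional pre-pooled `n x 16 x 16 x 3` array (internal fast
#'   path used by the training engine; values already scaled to `[0, 1]`).
#' @return A list of class `tile_batch`.
#' @export
tile_batch <- function(tiles = NULL, labels, slide_ids = NULL, pooled = NULL) {
  labels <- as.matrix(labels)
  if (ncol(labels) != 2L) stop("labels must have two columns (indolent, aggressive)", call. = FALSE)
  n <- if (!is.null(tiles)) length(tiles) else dim(pooled)[1]
  if (nrow(labels) != n) stop("labels and tiles have different lengths", call. = FALSE)
  if (!is.null(slide_ids) && length(slide_ids) != n)
    stop("slide_ids and tiles have different lengths", call. = FALSE)
  if (all(is.na(labels))) stop("degenerate batch: every (tile, head) pair is masked", call. = FALSE)
  if (!all(labels[!is.na(labels)] %in% c(0, 1)))
    stop("labels must be 0, 1 or NA", call. = FALSE)
  colnames(labels) <- c("indolent", "aggressive")
  structure(list(tiles = tiles, labels = labels, slide_ids = slide_ids,
                 pooled = pooled),
            class = "tile_batch")
}

# ---- pooling ---------------------------------------------------------------

.pool_matrix <- function(s, p = .POOL_P) {
  f <- s %/% p
  m <- matrix(0, p, s)
  for (i in seq_len(p)) m[i, ((i - 1) * f + 1):(i * f)] <- 1 / f
  m
}

# tiles: list of s x s x 3 rasters in [0,255] -> array (n, p, p, 3) in [0,1]
.pool_tiles <- function(tiles, input_size) {
  n <- length(tiles)
  M <- .pool_matrix(input_size)
  out <- array(0, c(n, .POOL_P, .POOL_P, 3))
  for (t in seq_len(n)) {
    tl <- tiles[[t]]
    if (!all(dim(tl)[1:2] == input_size))
      stop(sprintf("tile %d is %dx%d but classifier expects %dx%d",
                   t, dim(tl)[1], dim(tl)[2], input_size, input_size), call. = FALSE)
    for (c in 1:3) out[t, , , c] <- (M %*% (tl[, , c] / 255)) %*% t(M)
  }
  out
}

# ---- forward / backward ----------------------------------------------------

# im2col for 3x3 valid convolution. A: (n, H, W, C) -> ((n*OH*OW) x (9*C));
# rows ordered tile-fastest then output row then output column; columns
# ordered offset-row-fastest, then offset-column, then channel.
.im2col3 <- function(A) {
  d <- dim(A); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  OH <- H - 2L; OW <- W - 2L
  out <- matrix(0, n * OH * OW, 9L * C)
  k <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    out[, k] <- as.vector(A[, (1 + di):(OH + di), (1 + dj):(OW + dj), c])
  }
  out
}

.col2im3 <- function(dcols, n, H, W, C) {
  OH <- H - 2L; OW <- W - 2L
  dA <- array(0, c(n, H, W, C))
  k <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    dA[, (1 + di):(OH + di), (1 + dj):(OW + dj), c] <-
      dA[, (1 + di):(OH + di), (1 + dj):(OW + dj), c] + array(dcols[, k], c(n, OH, OW))
  }
  dA
}

.avgpool2 <- function(A) {  # (n, H, W, C) -> (n, H/2, W/2, C)
  i1 <- seq(1L, dim(A)[2], by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, dim(A)[3], by = 2L); j2 <- j1 + 1L
  (A[, i1, j1, , drop = FALSE] + A[, i2, j1, , drop = FALSE] +
   A[, i1, j2, , drop = FALSE] + A[, i2, j2, , drop = FALSE]) / 4
}

.bn_forward <- function(Z, gamma, beta, run_mean, run_var, training) {
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
  } else {
    mu <- run_mean; va <- run_var
  }
  invstd <- 1 / sqrt(va + .BN_EPS)
  Zhat <- sweep(sweep(Z, 2, mu, "-"), 2, invstd, "*")
  A <- sweep(sweep(Zhat, 2, gamma, "*"), 2, beta, "+")
  list(A = A, Zhat = Zhat, invstd = invstd, mu = mu, va = va)
}

.bn_backward <- function(dA, cache, gamma) {
  m <- nrow(dA)
  dgamma <- colSums(dA * cache$Zhat)
  dbeta <- colSums(dA)
  dZhat <- sweep(dA, 2, gamma, "*")
  t1 <- sweep(dZhat, 2, colMeans(dZhat), "-")
  t2 <- sweep(cache$Zhat, 2, colMeans(dZhat * cache$Zhat), "*")
  dZ <- sweep(t1 - t2, 2, cache$invstd, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# Forward pass on pooled input Xp (n, 16, 16, 3). Returns probabilities and,
# when training = TRUE, the caches needed for the backward pass.
.forward <- function(classifier, Xp, training = FALSE) {
  p <- classifier$params; b <- classifier$buffers
  n <- dim(Xp)[1]
  cols1 <- .im2col3(Xp)                              # (n*196) x 27
  Z1 <- sweep(cols1 %*% p$conv1_w, 2, p$conv1_b, "+")
  bn1 <- .bn_forward(Z1, p$bn1_gamma, p$bn1_beta, b$bn1_mean, b$bn1_var, training)
  R1 <- pmax(bn1$A, 0)
  A1 <- array(R1, c(n, 14L, 14L, .C1))
  P1 <- .avgpool2(A1)                                # (n, 7, 7, 8)
  cols2 <- .im2col3(P1)                              # (n*25) x 72
  Z2 <- sweep(cols2 %*% p$conv2_w, 2, p$conv2_b, "+")
  bn2 <- .bn_forward(Z2, p$bn2_gamma, p$bn2_beta, b$bn2_mean, b$bn2_var, training)
  R2 <- pmax(bn2$A, 0)
  A2 <- array(R2, c(n, 25L, .C2))
  Fm <- matrix(0, n, .C2)                            # global average pool
  for (f in seq_len(.C2)) Fm[, f] <- rowMeans(A2[, , f, drop = FALSE], dims = 1)
  logits <- sweep(Fm %*% p$head_w, 2, p$head_b, "+")
  prob <- 1 / (1 + exp(-logits))
  colnames(prob) <- c("indolent", "aggressive")
  out <- list(prob = prob)
  if (training) {
    out$cache <- list(cols1 = cols1, bn1 = bn1, R1 = R1, P1 = P1,
                      cols2 = cols2, bn2 = bn2, R2 = R2, Fm = Fm, n = n)
    out$bn_batch <- list(bn1_mean = bn1$mu, bn1_var = bn1$va,
                         bn2_mean = bn2$mu, bn2_var = bn2$va)
  }
  out
}

.backward <- function(classifier, cache, dlogits) {
  p <- classifier$params
  n <- cache$n
  g <- list()
  g$head_w <- t(cache$Fm) %*% dlogits
  g$head_b <- colSums(dlogits)
  dFm <- dlogits %*% t(p$head_w)                     # n x 16
  dR2 <- (dFm / 25)[rep(seq_len(n), times = 25L), , drop = FALSE]  # (n*25) x 16
  dA2 <- dR2 * (cache$R2 > 0)
  bb2 <- .bn_backward(dA2, cache$bn2, p$bn2_gamma)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  g$conv2_w <- t(cache$cols2) %*% bb2$dZ
  g$conv2_b <- colSums(bb2$dZ)
  dcols2 <- bb2$dZ %*% t(p$conv2_w)                  # (n*25) x 72
  dP1 <- .col2im3(dcols2, n, 7L, 7L, .C1)            # (n, 7, 7, 8)
  # unpool 2x2: each input position receives 1/4 of its cell's gradient
  dA1 <- array(0, c(n, 14L, 14L, .C1))
  i1 <- seq(1L, 13L, 2L)
  for (ii in 0:1) for (jj in 0:1)
    dA1[, i1 + ii, i1 + jj, ] <- dP1 / 4
  dR1 <- matrix(dA1, n * 196L, .C1)
  dA1m <- dR1 * (cache$R1 > 0)
  bb1 <- .bn_backward(dA1m, cache$bn1, p$bn1_gamma)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  g$conv1_w <- t(cache$cols1) %*% bb1$dZ
  g$conv1_b <- colSums(bb1$dZ)
  g
}

.masked_bce <- function(prob, labels, clip = 1e-15) {
  m <- !is.na(labels)
  if (!any(m)) stop("degenerate batch: all (tile, head) pairs are masked", call. = FALSE)
  pc <- pmin(pmax(prob, clip), 1 - clip)
  y <- labels
  ll <- -(y * log(pc) + (1 - y) * log(1 - pc))
  loss <- sum(ll[m]) / sum(m)
  dlogits <- matrix(0, nrow(prob), 2L)
  dlogits[m] <- (prob[m] - y[m]) / sum(m)
  list(loss = loss, dlogits = dlogits)
}

#' One optimization step on a tile batch
#'
#' Computes the mean binary cross-entropy over unmasked (tile, head) pairs,
#' backpropagates, and applies one Adam update to the parameters marked
#' trainable by [partial_finetune_setup()]. Masked pairs contribute zero loss
#' and zero gradient; frozen parameters are bit-identical before and after
#' the step.
#'
#' @param classifier a [tile_classifier()].
#' @param batch a [tile_batch()].
#' @param optimizer_config an [adam_config()].
#' @return List with `classifier` (updated) and `loss` (scalar).
#' @export
train_step <- function(classifier, batch, optimizer_config = adam_config()) {
  stopifnot(inherits(classifier, "tile_classifier"), inherits(batch, "tile_batch"))
  Xp <- batch$pooled %||% .pool_tiles(batch$tiles, classifier$input_size)
  fwd <- .forward(classifier, Xp, training = TRUE)
  lb <- .masked_bce(fwd$prob, batch$labels)
  grads <- .backward(classifier, fwd$cache, lb$dlogits)
  trainable <- partial_finetune_setup(classifier)
  classifier <- .adam_update(classifier, grads, trainable, optimizer_config)
  # batch-norm running statistics (buffers, not parameters)
  mom <- .BN_MOMENTUM
  for (nm in names(fwd$bn_batch))
    classifier$buffers[[nm]] <- mom * classifier$buffers[[nm]] + (1 - mom) * fwd$bn_batch[[nm]]
  list(classifier = classifier, loss = lb$loss)
}

.adam_update <- function(classifier, grads, trainable, cfg) {
  st <- classifier$opt_state
  if (is.null(st)) {
    st <- list(t = 0L,
               m = lapply(classifier$params, function(p) p * 0),
               v = lapply(classifier$params, function(p) p * 0))
  }
  st$t <- st$t + 1L
  for (nm in names(classifier$params)) {
    if (!isTRUE(trainable[[nm]]) || is.null(grads[[nm]])) next
    gr <- grads[[nm]]
    st$m[[nm]] <- cfg$beta1 * st$m[[nm]] + (1 - cfg$beta1) * gr
    st$v[[nm]] <- cfg$beta2 * st$v[[nm]] + (1 - cfg$beta2) * gr^2
    mhat <- st$m[[nm]] / (1 - cfg$beta1^st$t)
    vhat <- st$v[[nm]] / (1 - cfg$beta2^st$t)
    classifier$params[[nm]] <- classifier$params[[nm]] -
      cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
  }
  classifier$opt_state <- st
  classifier
}

#' Score tiles with a classifier
#'
#' Inference-mode forward pass (normalization layers use their running
#' statistics, so batched and unbatched calls agree exactly). Order is
#' preserved and identical tiles receive identical scores.
#'
#' @param classifier a [tile_classifier()].
#' @param tiles list of tile rasters matching the classifier's input size.
#' @return `n x 2` matrix with columns `p_indolent`, `p_aggressive`.
#' @export
predict_tiles <- function(classifier, tiles) {
  stopifnot(inherits(classifier, "tile_classifier"))
  if (length(tiles) == 0L)
    return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("p_indolent", "p_aggressive"))))
  Xp <- .pool_tiles(tiles, classifier$input_size)
  .predict_pooled(classifier, Xp)
}

.predict_pooled <- function(classifier, Xp, chunk = 1024L) {
  n <- dim(Xp)[1]
  out <- matrix(0, n, 2, dimnames = list(NULL, c("p_indolent", "p_aggressive")))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- .forward(classifier, Xp[s:e, , , , drop = FALSE], training = FALSE)$prob
  }
  out
}

# run expr under a temporary RNG seed, restoring global RNG state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
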