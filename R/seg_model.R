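#' Training protocol configuration for the TLS segmenter
#'
#' Defaults follow the reference protocol: AdamW (decoupled weight
#' decay), learning rate 1e-4, weight decay 1e-4, batch size 64 tiles,
#' at most 100 epochs, early stopping when the validation loss reaches
#' no new minimum for 10 consecutive epochs. The loss is a compound
#' overlap + cross-entropy (soft Dice + BCE) by default. For the small
#' pixelwise decoder head shipped here a larger learning rate trains in
#' far fewer steps; pass `learning_rate = 0.05` for desk-scale runs.
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight decay.
#' @param batch_size tiles per optimization step.
#' @param max_epochs maximum number of epochs.
#' @param early_stop_patience epochs without a new validation-loss
#'   minimum before stopping (must not exceed `max_epochs`).
#' @param loss `"bce_dice"`, `"bce"` or `"dice"`.
#' @param seed seed for shuffling (initialization is seeded by
#'   [build_model()]).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         batch_size = 64L, max_epochs = 100L,
                         early_stop_patience = 10L,
                         loss = c("bce_dice", "bce", "dice"), seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, early_stop_patience >= 1,
            early_stop_patience <= max_epochs)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

# Encoder presets: Gaussian scales (px), spatial stride of the decoded
# grid, and hidden width of the decoder head.
.seg_presets <- list(
  small  = list(sigmas = c(2, 6, 16), stride = 4L, hidden = 8L),
  medium = list(sigmas = c(2, 6, 16, 32), stride = 4L, hidden = 16L)
)

#' Build a TLS segmenter
#'
#' The segmenter is a lightweight pixelwise model: a fixed multiscale
#' encoder computes, at each pixel, stain darkness, a nucleus-density
#' channel (darkness above 0.5, i.e. hematoxylin-dark nuclei) and a
#' blue-excess channel, each smoothed at several Gaussian scales; a
#' trainable two-layer perceptron decoder head maps the feature vector
#' to a TLS probability, evaluated on a strided grid and bilinearly
#' upsampled to the tile resolution. Dense lymphocyte aggregates are
#' exactly what the nucleus-density channel at coarse scales responds
#' to, which is the visual definition of a TLS on H&E.
#'
#' @param preset `"small"` or `"medium"` encoder preset.
#' @param seed seed for parameter initialization; the untrained model is
#'   deterministic given the seed.
#' @return an object of class `tls_segmenter`; apply with
#'   [predict.tls_segmenter()], train with [train_segmenter()].
#' @export
build_model <- function(preset = "small", seed = 1L) {
  if (!preset %in% names(.seg_presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(.seg_presets), collapse = ", "))
  p <- .seg_presets[[preset]]
  f <- 2L + 2L * length(p$sigmas)   # raw darkness + blue excess + 2 per scale
  .with_seed(seed, {
    structure(list(preset = preset, sigmas = p$sigmas, stride = p$stride,
                   hidden = p$hidden, n_features = f,
                   W1 = matrix(rnorm(f * p$hidden, 0, 1 / sqrt(f)), f, p$hidden),
                   b1 = rep(0, p$hidden),
                   W2 = matrix(rnorm(p$hidden, 0, 1 / sqrt(p$hidden)), p$hidden, 1),
                   b2 = 0,
                   feat_center = rep(0, f), feat_scale = rep(1, f),
                   trained = FALSE, seed = as.integer(seed)),
              class = "tls_segmenter")
  })
}

# Multiscale features of one tile on the strided grid.
# Returns list(X = n x f matrix, nr, nc).
.seg_features <- function(px, model) {
  lum <- .luminance(px)
  d <- 1 - lum / 255
  nuc <- (d > 0.5) * 1
  be <- (px[, , 3] - px[, , 1]) / 255
  s <- model$stride
  ri <- seq(1, nrow(d), by = s); ci <- seq(1, ncol(d), by = s)
  sub <- function(m) as.numeric(m[ri, ci])
  cols <- list(sub(d), sub(.gblur(be, 6)))
  for (sg in model$sigmas) {
    cols[[length(cols) + 1L]] <- sub(.gblur(d, sg))
    cols[[length(cols) + 1L]] <- sub(.gblur(nuc, sg))
  }
  list(X = do.call(cbind, cols), nr = length(ri), nc = length(ci))
}

.seg_forward <- function(model, X) {
  Z1 <- sweep(X %*% model$W1, 2, model$b1, `+`)
  A1 <- tanh(Z1)
  logit <- as.numeric(A1 %*% model$W2) + model$b2
  list(p = 1 / (1 + exp(-logit)), A1 = A1, logit = logit)
}

#' Predict a TLS probability map for one tile
#'
#' @param object a `tls_segmenter`.
#' @param tile a [tile_image()] or H x W x 3 array, 0-255 scale.
#' @param ... unused.
#' @return numeric H x W matrix of probabilities in `[0, 1]`.
#' @export
predict.tls_segmenter <- function(object, tile, ...) {
  px <- .tile_pixels(tile)
  ft <- .seg_features(px, object)
  Xs <- sweep(sweep(ft$X, 2, object$feat_center), 2, object$feat_scale, `/`)
  p <- .seg_forward(object, Xs)$p
  m <- matrix(p, ft$nr, ft$nc)
  .clamp(.upsample_bilinear(m, nrow(px), ncol(px), object$stride), 0, 1)
}

#' @export
print.tls_segmenter <- function(x, ...) {
  cat(sprintf("<tls_segmenter> preset '%s' (%d features, hidden %d, stride %d), %s\n",
              x$preset, x$n_features, x$hidden, x$stride,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# loss and dlogit for predictions p vs labels y
.seg_loss <- function(p, y, kind) {
  eps <- 1e-7
  pc <- .clamp(p, eps, 1 - eps)
  n <- length(y)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  s <- 1
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  dsc <- (2 * spy + s) / (sp + sy + s)
  loss <- switch(kind, bce = bce, dice = 1 - dsc, bce_dice = bce + 1 - dsc)
  g_bce <- (pc - y) / n
  dD_dp <- (2 * y * (sp + sy + s) - (2 * spy + s)) / (sp + sy + s)^2
  g_dice <- -dD_dp * p * (1 - p)
  g <- switch(kind, bce = g_bce, dice = g_dice, bce_dice = g_bce + g_dice)
  list(loss = loss, dlogit = g)
}

#' Train the TLS segmenter
#'
#' Minibatch AdamW on the decoder head with the compound loss from the
#' [train_config()]. Each epoch shuffles the training tiles and steps
#' once per `batch_size` tiles; the validation loss is evaluated after
#' every epoch, and training stops early when it reaches no new minimum
#' for `early_stop_patience` consecutive epochs. The returned model
#' carries the weights of the best-validation epoch. Feature
#' standardization statistics are computed from the training set and
#' frozen into the model.
#'
#' @param model an untrained (or previously trained) [build_model()].
#' @param train_tiles,val_tiles lists of tiles (arrays or
#'   [tile_image()]).
#' @param train_masks,val_masks lists of logical TLS masks aligned with
#'   the tiles.
#' @param cfg a [train_config()].
#' @return list with `model` (trained `tls_segmenter`) and `history`
#'   (data.frame `epoch, train_loss, val_loss`).
#' @export
train_segmenter <- function(model, train_tiles, train_masks,
                            val_tiles, val_masks, cfg = train_config()) {
  stopifnot(inherits(model, "tls_segmenter"), inherits(cfg, "train_config"))
  if (length(train_tiles) == 0L) stop("empty training set")
  stopifnot(length(train_tiles) == length(train_masks),
            length(val_tiles) == length(val_masks))

  prep <- function(tiles, masks) {
    lapply(seq_along(tiles), function(i) {
      px <- .tile_pixels(tiles[[i]])
      ft <- .seg_features(px, model)
      m <- masks[[i]]
      s <- model$stride
      y <- as.numeric(m[seq(1, nrow(m), by = s), seq(1, ncol(m), by = s)])
      list(X = ft$X, y = y)
    })
  }
  tr <- prep(train_tiles, train_masks)
  va <- prep(val_tiles, val_masks)

  Xall <- do.call(rbind, lapply(tr, `[[`, "X"))
  model$feat_center <- colMeans(Xall)
  sds <- apply(Xall, 2, sd)
  model$feat_scale <- ifelse(sds < 1e-8, 1, sds)
  std <- function(X) sweep(sweep(X, 2, model$feat_center), 2, model$feat_scale, `/`)
  tr <- lapply(tr, function(e) { e$X <- std(e$X); e })
  va <- lapply(va, function(e) { e$X <- std(e$X); e })
  rm(Xall)

  params <- c("W1", "b1", "W2", "b2")
  mom <- lapply(params, function(p) model[[p]] * 0); names(mom) <- params
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  eval_loss <- function(set) {
    tot <- 0; npx <- 0
    for (e in set) {
      fw <- .seg_forward(model, e$X)
      tot <- tot + .seg_loss(fw$p, e$y, cfg$loss)$loss * length(e$y)
      npx <- npx + length(e$y)
    }
    tot / npx
  }

  best <- list(val = Inf, weights = model[params], epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  since_best <- 0L

  .with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(seq_along(tr))
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        X <- do.call(rbind, lapply(tr[idx], `[[`, "X"))
        y <- unlist(lapply(tr[idx], `[[`, "y"))
        fw <- .seg_forward(model, X)
        ls <- .seg_loss(fw$p, y, cfg$loss)
        ep_loss <- ep_loss + ls$loss * length(y); ep_n <- ep_n + length(y)
        dlog <- ls$dlogit
        gW2 <- crossprod(fw$A1, dlog)
        gb2 <- sum(dlog)
        dA1 <- outer(dlog, as.numeric(model$W2)) * (1 - fw$A1^2)
        gW1 <- crossprod(X, dA1)
        gb1 <- colSums(dA1)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        step <- step + 1L
        for (p in params) {
          mom[[p]] <- beta1 * mom[[p]] + (1 - beta1) * grads[[p]]
          vel[[p]] <- beta2 * vel[[p]] + (1 - beta2) * grads[[p]]^2
          mhat <- mom[[p]] / (1 - beta1^step)
          vhat <- vel[[p]] / (1 - beta2^step)
          upd <- cfg$learning_rate * mhat / (sqrt(vhat) + eps)
          if (p %in% c("W1", "W2"))
            upd <- upd + cfg$learning_rate * cfg$weight_decay * model[[p]]
          model[[p]] <- model[[p]] - upd
        }
      }
      val_loss <- eval_loss(va)
      history[epoch, ] <- list(epoch, ep_loss / ep_n, val_loss)
      if (val_loss < best$val) {
        best <- list(val = val_loss, weights = model[params], epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= cfg$early_stop_patience) break
      }
    }
  })

  model[params] <- best$weights
  model$trained <- TRUE
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_loss = best$val)
}

#' Binarize a probability map
#'
#' Pixels with probability strictly above the threshold (default 0.5)
#' are classified as TLS.
#'
#' @param p numeric probability matrix in `[0, 1]`.
#' @param threshold strict lower bound (default 0.5).
#' @return logical mask.
#' @examples
#' binarize(matrix(c(0.5, 0.51), 1))  # FALSE, TRUE
#' @export
binarize <- function(p, threshold = 0.5) {
  p > threshold
}

#' Oracle segmenter backed by a ground-truth mask
#'
#' Returns a drop-in segmenter (a function of a tile) that outputs
#' probability 1 on the ground-truth TLS mask and 0 elsewhere, cropped
#' to the tile's window. It lets the ratio orchestration be tested
#' independently of any trained model.
#'
#' @param truth_mask logical slide-level TLS mask.
#' @return a function `tile -> probability matrix`.
#' @export
oracle_segmenter <- function(truth_mask) {
  force(truth_mask)
  function(tile) {
    stopifnot(inherits(tile, "tile_image"))
    h <- dim(tile$pixels)[1]; w <- dim(tile$pixels)[2]
    sub <- truth_mask[(tile$origin_y + 1):(tile$origin_y + h),
                      (tile$origin_x + 1):(tile$origin_x + w), drop = FALSE]
    sub * 1
  }
}

# Normalize any supported segmenter representation to a function.
.as_segmenter <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, "tls_segmenter")) return(function(tile) predict(x, tile))
  stop("segmenter must be a function(tile) or a tls_segmenter")
}
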