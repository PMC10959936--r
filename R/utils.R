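# Internal helpers: seeded evaluation, luminance, blurs, raster utilities.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rec. 601 luminance on the 0-255 scale from an HxWx3 array.
.luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Gaussian blur of a plain matrix via EBImage, replicate boundary.
.gblur <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma,
                                    boundary = "replicate"))
}

# Grayscale max filter (disc of radius r) via EBImage dilation.
.maxfilter <- function(m, r) {
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(m), brush))
}

# Bilinear upsampling of a coarse map sampled at rows/cols 1, 1+stride, ...
# of a fine H x W grid.
.upsample_bilinear <- function(m, H, W, stride) {
  nr <- nrow(m); nc <- ncol(m)
  ci <- (seq_len(H) - 1) / stride + 1
  cj <- (seq_len(W) - 1) / stride + 1
  i0 <- pmin(floor(ci), nr); i1 <- pmin(i0 + 1, nr)
  j0 <- pmin(floor(cj), nc); j1 <- pmin(j0 + 1, nc)
  wi <- pmin(pmax(ci - i0, 0), 1)
  wj <- pmin(pmax(cj - j0, 0), 1)
  A <- m[i0, j0, drop = FALSE]; B <- m[i1, j0, drop = FALSE]
  C <- m[i0, j1, drop = FALSE]; D <- m[i1, j1, drop = FALSE]
  Wi <- matrix(wi, H, W); Wj <- matrix(wj, H, W, byrow = TRUE)
  (A * (1 - Wi) + B * Wi) * (1 - Wj) + (C * (1 - Wi) + D * Wi) * Wj
}

# Pixel-coordinate grids (0-based): X[i,j] = j-1, Y[i,j] = i-1.
.coord_grids <- function(h, w) {
  list(X = matrix(seq_len(w) - 1, h, w, byrow = TRUE),
       Y = matrix(seq_len(h) - 1, h, w))
}

# Logical mask of an ellipse (optionally with low-frequency radial wobble).
# cx, cy, a, b in pixels (0-based centre), theta in radians.
.ellipse_mask <- function(h, w, cx, cy, a, b, theta = 0, wobble = NULL) {
  g <- .coord_grids(h, w)
  dx <- g$X - cx; dy <- g$Y - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  rho <- sqrt(u^2 + v^2)
  if (is.null(wobble)) return(rho <= 1)
  phi <- atan2(v, u)
  lim <- 1 + wobble$a1 * sin(3 * phi + wobble$p1) +
    wobble$a2 * sin(5 * phi + wobble$p2)
  rho <= lim
}

# Draw filled discs of radius r and base colour col (length 3, 0-255) at
# 0-based centres (xs, ys) onto img (HxWx3), with per-pixel Gaussian noise.
# Returns the modified image.
.draw_discs <- function(img, xs, ys, r, col, noise_sd = 2) {
  h <- dim(img)[1]; w <- dim(img)[2]
  span <- -r:r
  offs <- expand.grid(dy = span, dx = span)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  for (k in seq_along(xs)) {
    rows <- ys[k] + 1L + offs$dy
    cols <- xs[k] + 1L + offs$dx
    ok <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
    rows <- rows[ok]; cols <- cols[ok]
    n <- length(rows)
    if (n == 0L) next
    for (c3 in 1:3) {
      idx <- cbind(rows, cols, rep(c3, n))
      img[idx] <- col[c3] + rnorm(n, 0, noise_sd)
    }
  }
  img
}

# Sample up to n points uniformly in an ellipse with a minimum pairwise
# separation (dart throwing). Returns a 2-column matrix of 0-based x, y or
# NULL if the budget is exhausted before n points are placed.
.dart_ellipse <- function(n, cx, cy, a, b, theta, min_sep, margin = 0,
                          max_tries = 200L) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  amax <- a - margin; bmax <- b - margin
  if (amax <= 0 || bmax <= 0) return(NULL)
  while (placed < n && tries < max_tries * n) {
    tries <- tries + 1L
    rr <- sqrt(runif(1)); ang <- runif(1, 0, 2 * pi)
    u <- rr * cos(ang) * amax; v <- rr * sin(ang) * bmax
    x <- cx + u * cos(theta) - v * sin(theta)
    y <- cy + u * sin(theta) + v * cos(theta)
    if (placed > 0L) {
      d2 <- (pts[seq_len(placed), 1] - x)^2 + (pts[seq_len(placed), 2] - y)^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- c(x, y)
  }
  if (placed < n) return(NULL)
  pts
}
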