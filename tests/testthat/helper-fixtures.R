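# Shared fixtures (generated in code, cached per session) and independent
# reference computations used as oracles.

.fixtures <- new.env(parent = emptyenv())

# A default synthetic slide, cached by seed.
fixture_slide <- function(seed, ...) {
  key <- paste0("slide-", seed, "-", paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_slide(synth_slide_spec(seed = seed, ...))
  .fixtures[[key]]
}

# A 512x512 slide with one TLS region sized for the smaller canvas.
fixture_slide_small <- function(seed) {
  fixture_slide(seed, width_px = 512, height_px = 512, n_tls_regions = 1,
                tls_fraction_target = 0.08, cells_per_tls_range = c(60L, 90L))
}

# Independent recomputation of the slide TLS ratio from the generator's
# ground-truth masks and cell table, applying the same retention rules as
# the pipeline: 10% tissue retention per tile, >80 lymphocytes inside the
# tile's TLS area. Pure arithmetic on the emitted ground truth; shares no
# code with compute_slide_ratio.
reference_slide_ratio <- function(sl, tile_size = 512L,
                                  tissue_frac = 0.10, min_lymph = 80L) {
  H <- nrow(sl$tissue_mask_true); W <- ncol(sl$tissue_mask_true)
  lym <- sl$cells[sl$cells$is_lymphocyte, , drop = FALSE]
  tls_sum <- 0; tissue_sum <- 0
  for (y in seq(0L, H - tile_size, by = tile_size)) {
    for (x in seq(0L, W - tile_size, by = tile_size)) {
      tis <- sl$tissue_mask_true[(y + 1):(y + tile_size),
                                 (x + 1):(x + tile_size)]
      tp <- sum(tis)
      if (!(tp > floor(tissue_frac * tile_size^2))) next
      tls <- sl$tls_mask_true[(y + 1):(y + tile_size),
                              (x + 1):(x + tile_size)] & tis
      inwin <- lym$x >= x & lym$x < x + tile_size &
        lym$y >= y & lym$y < y + tile_size
      cc <- lym[inwin, , drop = FALSE]
      cnt <- if (nrow(cc) > 0)
        sum(tls[cbind(floor(cc$y) - y + 1, floor(cc$x) - x + 1)]) else 0
      tissue_sum <- tissue_sum + tp
      if (cnt > min_lymph) tls_sum <- tls_sum + sum(tls)
    }
  }
  if (tissue_sum == 0) return(NA_real_)
  tls_sum / tissue_sum
}

# Brute-force AUC: fraction of correctly ordered positive-negative pairs,
# ties counting one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Tiles and masks from a slide on a given grid, as parallel lists.
slide_tiles <- function(sl, overlap = 0, tile_size = 512L) {
  g <- tile_grid(ncol(sl$tissue_mask_true), nrow(sl$tissue_mask_true),
                 tile_size, overlap)
  tiles <- list(); masks <- list()
  for (i in seq_len(nrow(g))) {
    x <- g$origin_x[i]; y <- g$origin_y[i]
    tiles[[i]] <- extract_tile(sl, c(x, y), tile_size = tile_size)
    masks[[i]] <- sl$tls_mask_true[(y + 1):(y + tile_size),
                                   (x + 1):(x + tile_size)]
  }
  list(tiles = tiles, masks = masks, grid = g)
}

# Random binary mask of given size with inclusion probability p.
random_mask <- function(h, w, p) matrix(runif(h * w) < p, h, w)
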