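#' Otsu tissue mask with pen-mark removal
#'
#' Branch 1 of the pipeline. The tile is converted to luminance
#' (Rec. 601 weights), the Otsu criterion picks the threshold separating
#' the bright non-tissue background from the darker stained tissue, and
#' pen-mark pixels flagged by [pen_filter()] are removed from the tissue
#' mask before it is returned.
#'
#' Degenerate tiles are treated as blank background: when the luminance
#' range falls below `config$min_contrast` (which covers exactly
#' constant tiles and pure background noise) the mask is empty.
#'
#' @param tile a [tile_image()] or H x W x 3 array, 0-255 scale.
#' @param config a [tls_config()].
#' @param threshold optional fixed luminance threshold (0-255). When
#'   quantifying a whole slide, the threshold is computed once from the
#'   slide-level histogram and passed here, so tiles fully interior to
#'   tissue (no background mode in their own histogram) are still masked
#'   correctly.
#' @return logical H x W matrix; `TRUE` = tissue.
#' @export
otsu_tissue_mask <- function(tile, config = tls_config(), threshold = NULL) {
  px <- .tile_pixels(tile)
  lum <- .luminance(px)
  if (is.null(threshold)) {
    if (diff(range(lum)) < config$min_contrast)
      return(matrix(FALSE, nrow(lum), ncol(lum)))
    threshold <- .otsu_threshold(lum)
  }
  tissue <- lum < threshold
  tissue & !pen_filter(px, config)
}

# Otsu threshold on a luminance matrix (0-255), returned on the same scale.
.otsu_threshold <- function(lum) {
  thr01 <- EBImage::otsu(EBImage::Image(.clamp(lum, 0, 255) / 255),
                         range = c(0, 1), levels = 256)
  thr01 * 255
}

#' Flag pen-mark pixels by colour rules
#'
#' Pure per-pixel channel-threshold predicates for saturated blue, green
#' and red marker strokes; the union of the three rules is returned. The
#' exact constants live in [tls_config()]`$pen_rules`. Each rule requires
#' a dominant channel, so dark hematoxylin, eosin pink, background and
#' black are never flagged.
#'
#' @param tile a [tile_image()] or H x W x 3 array, 0-255 scale.
#' @param config a [tls_config()].
#' @return logical H x W matrix; `TRUE` = pen pixel.
#' @examples
#' px <- array(c(30, 30, 200), c(1, 1, 3))  # saturated blue
#' pen_filter(px)[1, 1]
#' @export
pen_filter <- function(tile, config = tls_config()) {
  px <- .tile_pixels(tile)
  h <- dim(px)[1]; w <- dim(px)[2]
  R <- matrix(px[, , 1], h, w); G <- matrix(px[, , 2], h, w)
  B <- matrix(px[, , 3], h, w)
  r <- config$pen_rules
  blue <- B > r$blue[["b_min"]] & R < r$blue[["r_max"]] &
    G < r$blue[["g_max"]] & (B - R) > r$blue[["dom_min"]]
  green <- G > r$green[["g_min"]] & R < r$green[["r_max"]] &
    B < r$green[["b_max"]] & (G - R) > r$green[["dom_min"]]
  red <- R > r$red[["r_min"]] & G < r$red[["g_max"]] &
    B < r$red[["b_max"]] & (R - G) > r$red[["dom_min"]]
  blue | green | red
}

#' Tissue-retention rule for a tile
#'
#' A tile is retained when its tissue area strictly exceeds 10\% of the
#' tile area, i.e. `tissue_pixels > floor(fraction * tile_area)`. For a
#' 512 x 512 tile the largest rejected count is 26,214 pixels.
#'
#' @param tissue_pixels tissue pixel count (non-negative).
#' @param tile_area total tile pixel count (positive).
#' @param config a [tls_config()]; supplies the retention fraction.
#' @return `TRUE` iff the tile is retained.
#' @examples
#' tissue_retention(26214, 512^2)  # FALSE: boundary not exceeded
#' tissue_retention(26215, 512^2)  # TRUE
#' @export
tissue_retention <- function(tissue_pixels, tile_area, config = tls_config()) {
  stopifnot(tissue_pixels >= 0, tile_area > 0)
  tissue_pixels > floor(config$tissue_min_fraction * tile_area)
}
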