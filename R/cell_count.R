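#' Default classical nucleus detector
#'
#' Branch 3's pluggable detector interface is `tile -> cell table`; this
#' default is a classical, dependency-light detector sized for
#' lymphocyte nuclei. The tile is processed in non-overlapping 256 x 256
#' windows: within each window the luminance darkness is Gaussian
#' smoothed, pixels above a darkness threshold are nucleus candidates,
#' and local maxima of the smoothed darkness (grayscale max filter)
#' become detections. Window detections are aggregated with their
#' offsets, and duplicates within a minimum-distance radius (nuclei
#' straddling window borders) are suppressed, keeping the darker peak.
#' The lymphocyte flag is a darkness rule: small dense lymphocyte nuclei
#' retain a high smoothed peak darkness, while larger, paler nuclei
#' plateau lower (constants in [tls_config()]`$detector`).
#'
#' @param tile a [tile_image()] or H x W x 3 array, 0-255 scale.
#' @param config a [tls_config()].
#' @return data.frame `cell_id, x, y, cd3, cd20, is_lymphocyte` with
#'   0-based tile-frame centroids; `cd3`/`cd20` are `NA` (marker status
#'   is not observable on H&E).
#' @export
detect_cells_default <- function(tile, config = tls_config()) {
  px <- .tile_pixels(tile)
  H <- dim(px)[1]; W <- dim(px)[2]
  det <- config$detector
  win <- config$detector_window
  found <- list()
  for (oy in seq(0L, H - 1L, by = win)) {
    for (ox in seq(0L, W - 1L, by = win)) {
      hh <- min(win, H - oy); ww <- min(win, W - ox)
      sub <- px[(oy + 1):(oy + hh), (ox + 1):(ox + ww), , drop = FALSE]
      d <- .gblur(1 - .luminance(sub) / 255, det$sigma)
      cand <- d > det$darkness_min
      if (!any(cand)) next
      mx <- .maxfilter(d, det$peak_radius)
      peaks <- which(cand & d >= mx - 1e-12, arr.ind = TRUE)
      if (nrow(peaks) == 0L) next
      found[[length(found) + 1L]] <-
        data.frame(x = ox + peaks[, 2] - 1L, y = oy + peaks[, 1] - 1L,
                   darkness = d[peaks])
    }
  }
  if (length(found) == 0L)
    return(data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      cd3 = logical(0), cd20 = logical(0),
                      is_lymphocyte = logical(0)))
  cells <- do.call(rbind, found)
  cells <- cells[order(-cells$darkness), , drop = FALSE]
  keep <- rep(TRUE, nrow(cells))
  for (i in seq_len(nrow(cells))) {      # greedy non-maximum suppression
    if (!keep[i]) next
    if (i < nrow(cells)) {
      j <- (i + 1):nrow(cells)
      d2 <- (cells$x[j] - cells$x[i])^2 + (cells$y[j] - cells$y[i])^2
      keep[j][d2 < det$merge_radius^2] <- FALSE
    }
  }
  cells <- cells[keep, , drop = FALSE]
  cells <- cells[order(cells$y, cells$x), , drop = FALSE]
  data.frame(cell_id = seq_len(nrow(cells)), x = cells$x, y = cells$y,
             cd3 = NA, cd20 = NA,
             is_lymphocyte = cells$darkness > det$lymphocyte_darkness)
}

#' Oracle detector backed by a ground-truth cell table
#'
#' Returns a drop-in detector that reports the generator's true cells
#' falling inside the tile's window, with centroids shifted to the tile
#' frame.
#'
#' @param cells slide-level cell table (`x`, `y` 0-based slide
#'   coordinates, `cd3`, `cd20`, `is_lymphocyte`).
#' @return a function `tile -> cell table`.
#' @export
oracle_detector <- function(cells) {
  force(cells)
  function(tile) {
    stopifnot(inherits(tile, "tile_image"))
    h <- dim(tile$pixels)[1]; w <- dim(tile$pixels)[2]
    inwin <- cells$x >= tile$origin_x & cells$x < tile$origin_x + w &
      cells$y >= tile$origin_y & cells$y < tile$origin_y + h
    sub <- cells[inwin, , drop = FALSE]
    sub$x <- sub$x - tile$origin_x
    sub$y <- sub$y - tile$origin_y
    rownames(sub) <- NULL
    sub
  }
}

.as_detector <- function(x) {
  if (is.function(x)) return(x)
  stop("detector must be a function(tile) returning a cell table")
}

#' Count lymphocytes inside a TLS mask
#'
#' Counts cells flagged `is_lymphocyte` whose centroid pixel (0-based
#' coordinates floored to the grid) lies inside the mask. Additive over
#' disjoint mask components.
#'
#' @param cells tile-frame cell table with `x`, `y`, `is_lymphocyte`.
#' @param tls_mask logical mask on the same grid.
#' @return integer count.
#' @export
lymphocytes_in_tls <- function(cells, tls_mask) {
  if (nrow(cells) == 0L) return(0L)
  lym <- cells[which(cells$is_lymphocyte), , drop = FALSE]
  if (nrow(lym) == 0L) return(0L)
  rows <- floor(lym$y) + 1L
  cols <- floor(lym$x) + 1L
  ok <- rows >= 1L & rows <= nrow(tls_mask) & cols >= 1L & cols <= ncol(tls_mask)
  sum(tls_mask[cbind(rows[ok], cols[ok])])
}

#' Small-TLS exclusion filter
#'
#' A tile's segmented TLS area enters the ratio only when the lymphocyte
#' count inside it strictly exceeds 80 (the filter is designed to
#' exclude small TLS fragments, applied per tile against the tile's
#' entire binarized TLS area).
#'
#' @param count lymphocyte count inside the tile's TLS area.
#' @param config a [tls_config()].
#' @return `TRUE` iff `count > 80` (strict).
#' @examples
#' tls_tile_filter(80)  # FALSE
#' tls_tile_filter(81)  # TRUE
#' @export
tls_tile_filter <- function(count, config = tls_config()) {
  stopifnot(count >= 0)
  count > config$lymphocyte_min_count
}
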