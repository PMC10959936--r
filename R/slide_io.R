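#' Slide records, tile grids and tile extraction
#'
#' A `slide_record` is a lightweight in-memory handle on a slide raster
#' plus its identifiers and physical resolution in micrometres per pixel
#' (um/px). The reference scanning convention is 20x magnification at
#' 0.5 um/px; 40x material (0.25 um/px) is handled at extraction time by
#' cropping a double-size window and downscaling.
#'
#' @param image numeric H x W x 3 RGB array on the 0-255 scale.
#' @param slide_id,subject_id identifier strings.
#' @param mpp micrometres per pixel; must be positive.
#' @return an object of class `slide_record` with fields `image`,
#'   `width_px`, `height_px`, `mpp`, `slide_id`, `subject_id`.
#' @seealso [tile_grid()], [extract_tile()], [read_slide()], [write_slide()]
#' @export
slide_record <- function(image, slide_id = "slide", subject_id = slide_id,
                         mpp = 0.5) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3, mpp > 0)
  structure(list(image = image,
                 width_px = dim(image)[2],
                 height_px = dim(image)[1],
                 mpp = mpp,
                 slide_id = slide_id,
                 subject_id = subject_id),
            class = "slide_record")
}

#' @export
print.slide_record <- function(x, ...) {
  cat(sprintf("<slide_record> %s (subject %s): %d x %d px @ %.3g um/px\n",
              x$slide_id, x$subject_id, x$width_px, x$height_px, x$mpp))
  invisible(x)
}

# Coerce a synth_slide or slide_record to a slide_record.
.as_slide_record <- function(x) {
  if (inherits(x, "slide_record")) return(x)
  if (inherits(x, "synth_slide"))
    return(slide_record(x$image, slide_id = x$slide_id,
                        subject_id = x$subject_id, mpp = x$mpp))
  stop("expected a slide_record or synth_slide")
}

#' A single RGB tile with its slide-level origin
#'
#' Tiles carry their 0-based, half-open source window
#' `[origin_x, origin_x + W) x [origin_y, origin_y + H)` so that oracle
#' segmenters and detectors can look up ground truth for the same window.
#'
#' @param pixels numeric H x W x 3 array, 0-255 scale.
#' @param origin_x,origin_y 0-based pixel offsets of the window in the slide.
#' @param mpp micrometres per pixel of the tile raster.
#' @return an object of class `tile_image`.
#' @export
tile_image <- function(pixels, origin_x = 0L, origin_y = 0L, mpp = 0.5) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  structure(list(pixels = pixels,
                 origin_x = as.integer(origin_x),
                 origin_y = as.integer(origin_y),
                 mpp = mpp),
            class = "tile_image")
}

.tile_pixels <- function(tile) {
  if (inherits(tile, "tile_image")) tile$pixels else tile
}

#' Enumerate sliding-window tile origins
#'
#' Windows of side `tile_size` are enumerated row-major (left to right,
#' then top to bottom) with stride `tile_size * (1 - overlap_fraction)`.
#' The training convention uses 50\% overlap; quantification uses none.
#' Windows that would extend past the slide edge are dropped, never
#' padded, so partial tiles cannot distort area ratios.
#'
#' @param width_px,height_px slide dimensions in pixels (positive).
#' @param tile_size window side in pixels.
#' @param overlap_fraction 0 (no overlap) or 0.5 (half-window overlap).
#' @return data.frame with 0-based columns `origin_x`, `origin_y`, one row
#'   per window; zero rows if the slide is smaller than one tile.
#' @examples
#' tile_grid(1024, 512, 512, 0.5)  # origins x in {0, 256, 512}, y = 0
#' @export
tile_grid <- function(width_px, height_px, tile_size, overlap_fraction = 0) {
  if (width_px <= 0 || height_px <= 0) stop("slide dimensions must be positive")
  if (tile_size <= 0) stop("tile_size must be positive")
  if (!overlap_fraction %in% c(0, 0.5))
    stop("overlap_fraction must be 0 or 0.5")
  stride <- as.integer(tile_size * (1 - overlap_fraction))
  xs <- seq(0L, by = stride, length.out = max(0L, (width_px - tile_size) %/% stride + 1L))
  ys <- seq(0L, by = stride, length.out = max(0L, (height_px - tile_size) %/% stride + 1L))
  xs <- xs[xs + tile_size <= width_px]
  ys <- ys[ys + tile_size <= height_px]
  if (length(xs) == 0L || length(ys) == 0L)
    return(data.frame(origin_x = integer(0), origin_y = integer(0)))
  data.frame(origin_x = rep(xs, times = length(ys)),
             origin_y = rep(ys, each = length(xs)))
}

# Area-averaging downscale by an integer factor (mean over f x f blocks),
# applied per channel. No rounding: fractional means are preserved.
.downscale_area <- function(img, f) {
  h <- dim(img)[1]; w <- dim(img)[2]
  stopifnot(h %% f == 0, w %% f == 0)
  out <- array(0, c(h %/% f, w %/% f, 3))
  for (c3 in 1:3) {
    m <- img[, , c3]
    dim(m) <- c(f, h %/% f, w)
    m <- colMeans(m)                # (h/f) x w
    m <- t(m); dim(m) <- c(f, w %/% f, h %/% f)
    out[, , c3] <- t(colMeans(m))
  }
  out
}

#' Extract one tile from a slide
#'
#' In `native20x` mode a `tile_size` window is copied as-is. In `from40x`
#' mode (0.25 um/px material) a `2 * tile_size` window is cropped and
#' downscaled by a factor of 2 with area averaging, yielding a
#' `tile_size` tile at twice the source mpp. Fractional averaged values
#' are kept unrounded.
#'
#' @param slide a [slide_record()] (or `synth_slide`).
#' @param origin length-2 vector `c(x, y)`, 0-based window offset.
#' @param magnification_mode `"native20x"` or `"from40x"`.
#' @param tile_size output tile side (default 512).
#' @return a [tile_image()].
#' @export
extract_tile <- function(slide, origin, magnification_mode = "native20x",
                         tile_size = 512L) {
  slide <- .as_slide_record(slide)
  mode <- match.arg(magnification_mode, c("native20x", "from40x"))
  crop <- if (mode == "from40x") 2L * tile_size else tile_size
  x <- as.integer(origin[1]); y <- as.integer(origin[2])
  if (x < 0 || y < 0 || x + crop > slide$width_px || y + crop > slide$height_px)
    stop("tile window out of slide bounds")
  px <- slide$image[(y + 1):(y + crop), (x + 1):(x + crop), , drop = FALSE]
  out_mpp <- slide$mpp
  if (mode == "from40x") {
    px <- .downscale_area(px, 2L)
    out_mpp <- slide$mpp * 2
  }
  tile_image(px, origin_x = x, origin_y = y, mpp = out_mpp)
}

#' Write a slide (and any ground truth) to a directory of plain files
#'
#' The image is written as PNG (lossless) or single-level TIFF, with a
#' JSON sidecar carrying `slide_id`, `subject_id`, `mpp`, `width_px`,
#' `height_px`. For synthetic slides, ground-truth masks are written as
#' 0/255 PNGs and the cell table as CSV with 0-based pixel coordinates.
#'
#' @param slide a `slide_record` or `synth_slide`.
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"tiff"` for the image raster.
#' @return invisibly, the directory path.
#' @export
write_slide <- function(slide, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- .as_slide_record(slide)
  img01 <- .clamp(rec$image, 0, 255) / 255
  if (format == "png") {
    png::writePNG(img01, file.path(dir, "image.png"))
  } else {
    tiff::writeTIFF(img01, file.path(dir, "image.tiff"), compression = "none")
  }
  meta <- list(slide_id = rec$slide_id, subject_id = rec$subject_id,
               mpp = rec$mpp, width_px = rec$width_px, height_px = rec$height_px)
  jsonlite::write_json(meta, file.path(dir, "slide.json"), auto_unbox = TRUE)
  if (inherits(slide, "synth_slide")) {
    png::writePNG(slide$tls_mask_true * 1, file.path(dir, "tls_mask_true.png"))
    png::writePNG(slide$tissue_mask_true * 1, file.path(dir, "tissue_mask_true.png"))
    cells <- slide$cells
    write.csv(cells[, c("cell_id", "x", "y", "cd3", "cd20", "is_lymphocyte")],
              file.path(dir, "cells.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a slide written by [write_slide()]
#'
#' @param dir directory containing `image.png` (or `image.tiff`) and
#'   `slide.json`. Ground-truth files, when present, are attached as
#'   `tls_mask_true`, `tissue_mask_true` and `cells` attributes-free list
#'   entries.
#' @return a `slide_record`; if ground truth files are present, a
#'   `synth_slide`-compatible list.
#' @export
read_slide <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "slide.json"), simplifyVector = TRUE)
  p_png <- file.path(dir, "image.png")
  img01 <- if (file.exists(p_png)) png::readPNG(p_png)
           else tiff::readTIFF(file.path(dir, "image.tiff"))
  img <- round(img01 * 255)
  rec <- slide_record(img, slide_id = meta$slide_id,
                      subject_id = meta$subject_id, mpp = meta$mpp)
  p_tls <- file.path(dir, "tls_mask_true.png")
  if (file.exists(p_tls)) {
    out <- list(image = img,
                tls_mask_true = png::readPNG(p_tls) > 0.5,
                tissue_mask_true = png::readPNG(file.path(dir, "tissue_mask_true.png")) > 0.5,
                cells = read.csv(file.path(dir, "cells.csv")),
                mpp = meta$mpp, slide_id = meta$slide_id,
                subject_id = meta$subject_id)
    out$true_ratio <- sum(out$tls_mask_true & out$tissue_mask_true) /
      sum(out$tissue_mask_true)
    class(out) <- "synth_slide"
    return(out)
  }
  rec
}
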