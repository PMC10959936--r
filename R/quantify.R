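#' Compute the TLS ratio of one slide
#'
#' Orchestrates the three branches over the slide's non-overlapping
#' 512 x 512 tile grid. Per tile:
#' \enumerate{
#'   \item tissue branch: Otsu tissue mask (threshold computed once from
#'     the whole-slide luminance histogram) minus pen pixels; the tile is
#'     skipped entirely unless [tissue_retention()] passes;
#'   \item segmentation branch: the segmenter's probability map is
#'     binarized (strictly above `config$prob_threshold`) and intersected
#'     with the tissue mask, guaranteeing TLS area is tissue and the
#'     ratio stays in `[0, 1]`;
#'   \item counting branch: if the lymphocyte count inside the tile's TLS
#'     area does not exceed `config$lymphocyte_min_count`, the tile's TLS
#'     area is zeroed -- its tissue still accrues to the denominator,
#'     because the filter excludes small TLSs, not tissue.
#' }
#' The slide ratio is the accumulated TLS pixel sum over the accumulated
#' tissue pixel sum. A slide with no retained tissue gets an undefined
#' ratio (`NA` with `defined = FALSE`), never a division error.
#'
#' @param slide a [slide_record()] or `synth_slide`.
#' @param segmenter a `tls_segmenter`, [oracle_segmenter()] or any
#'   function `tile -> probability matrix`.
#' @param detector [detect_cells_default()] (the default when `NULL`),
#'   [oracle_detector()] or any function `tile -> cell table`.
#' @param config a [tls_config()].
#' @return an object of class `ratio_result`: `slide_id`, `subject_id`,
#'   `tls_pixels`, `tissue_pixels`, `ratio`, `defined`, `n_tiles_total`,
#'   `n_tiles_retained`, `n_tiles_tls_filtered` (retained tiles whose
#'   non-zero TLS area was zeroed by the lymphocyte filter), and the
#'   per-tile log `tiles`.
#' @export
compute_slide_ratio <- function(slide, segmenter, detector = NULL,
                                config = tls_config()) {
  rec <- .as_slide_record(slide)
  seg <- .as_segmenter(segmenter)
  det <- if (is.null(detector)) {
    function(tile) detect_cells_default(tile, config)
  } else .as_detector(detector)

  lum <- .luminance(rec$image)
  slide_thr <- if (diff(range(lum)) < config$min_contrast) -Inf
               else .otsu_threshold(lum)

  grid <- tile_grid(rec$width_px, rec$height_px, config$tile_size, 0)
  tls_sum <- 0; tissue_sum <- 0
  n_ret <- 0L; n_filtered <- 0L
  log <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tile <- extract_tile(rec, c(grid$origin_x[i], grid$origin_y[i]),
                         tile_size = config$tile_size)
    tissue <- otsu_tissue_mask(tile, config, threshold = slide_thr)
    tp <- sum(tissue)
    retained <- tissue_retention(tp, length(tissue), config)
    tlp <- 0L; count <- NA_integer_; passed <- NA
    if (retained) {
      n_ret <- n_ret + 1L
      prob <- seg(tile)
      tls <- binarize(prob, config$prob_threshold) & tissue
      count <- lymphocytes_in_tls(det(tile), tls)
      passed <- tls_tile_filter(count, config)
      if (passed) {
        tlp <- sum(tls)
      } else if (sum(tls) > 0L) {
        n_filtered <- n_filtered + 1L
      }
      tls_sum <- tls_sum + tlp
      tissue_sum <- tissue_sum + tp
    }
    log[[i]] <- data.frame(origin_x = grid$origin_x[i],
                           origin_y = grid$origin_y[i],
                           tissue_pixels = tp, retained = retained,
                           lymphocytes_in_tls = count,
                           tls_pixels = tlp)
  }
  defined <- tissue_sum > 0
  structure(list(slide_id = rec$slide_id, subject_id = rec$subject_id,
                 tls_pixels = tls_sum, tissue_pixels = tissue_sum,
                 ratio = if (defined) tls_sum / tissue_sum else NA_real_,
                 defined = defined,
                 n_tiles_total = nrow(grid), n_tiles_retained = n_ret,
                 n_tiles_tls_filtered = n_filtered,
                 tiles = do.call(rbind, log)),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf(paste0("<ratio_result> %s: TLS ratio %s ",
                     "(%d TLS px / %d tissue px; %d/%d tiles retained)\n"),
              x$slide_id,
              if (x$defined) sprintf("%.4f", x$ratio) else "undefined",
              x$tls_pixels, x$tissue_pixels,
              x$n_tiles_retained, x$n_tiles_total))
  invisible(x)
}

#' Per-subject TLS ratio
#'
#' For subjects with more than one slide the TLS ratio is the unweighted
#' arithmetic mean over slides with a defined ratio; undefined slide
#' ratios (no retained tissue) are excluded with a warning rather than
#' zeroing the subject's biomarker.
#'
#' @param results list of `ratio_result` objects for one subject.
#' @return an object of class `subject_ratio`: `subject_id`, `ratio`
#'   (`NA` if every slide was undefined), `n_slides` (number of defined
#'   slides used).
#' @export
subject_ratio <- function(results) {
  if (inherits(results, "ratio_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  ratios <- vapply(results, `[[`, 0, "ratio")
  defined <- vapply(results, `[[`, TRUE, "defined")
  if (any(!defined))
    warning(sum(!defined), " slide(s) with undefined ratio excluded from ",
            "the subject mean")
  subject_id <- results[[1]]$subject_id
  structure(list(subject_id = subject_id,
                 ratio = if (any(defined)) mean(ratios[defined]) else NA_real_,
                 n_slides = sum(defined)),
            class = "subject_ratio")
}

#' @export
print.subject_ratio <- function(x, ...) {
  cat(sprintf("<subject_ratio> %s: %s over %d slide(s)\n", x$subject_id,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio),
              x$n_slides))
  invisible(x)
}
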