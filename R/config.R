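#' Pipeline configuration with every threshold pinned
#'
#' All constants used by the quantification pipeline live here so that a
#' run is fully described by one object: the tile geometry, the tissue
#' retention fraction, the probability binarization threshold, the
#' lymphocyte-count filter, the pen-mark colour rules and the nucleus
#' detector parameters. Defaults follow the reference protocol: 512 px
#' tiles at 0.5 um/px, retention when tissue exceeds 10\% of the tile
#' (26,214 px for a 512x512 tile), TLS pixels where probability is
#' strictly above 0.5, and tiles kept for the ratio only when more than
#' 80 lymphocytes fall inside the segmented TLS area.
#'
#' @param tile_size tile side in pixels.
#' @param tissue_min_fraction minimum tissue fraction for tile retention;
#'   a tile is retained when its tissue pixel count strictly exceeds
#'   `floor(tissue_min_fraction * tile_area)`.
#' @param prob_threshold binarization threshold on the TLS probability
#'   map (strict `>`).
#' @param lymphocyte_min_count lymphocyte-count filter: a tile's TLS area
#'   enters the ratio only when the lymphocyte count inside its segmented
#'   TLSs strictly exceeds this value.
#' @param detector_window side of the non-overlapping windows used by the
#'   nucleus detector.
#' @param min_contrast minimum luminance range (0-255 scale) below which a
#'   tile is treated as blank background and gets an empty tissue mask.
#' @param pen_rules named list of per-colour channel-threshold rules, each
#'   a numeric vector of named constants (see Details).
#' @param detector detector constants: Gaussian smoothing sigma,
#'   nucleus-darkness threshold, peak separation radius, duplicate-merge
#'   radius and the smoothed-darkness cut separating lymphocyte from
#'   larger, paler nuclei.
#'
#' @details Pen rules are pure per-pixel predicates on 0-255 RGB values.
#' A pixel is a blue pen stroke when `B > b_min`, `R < r_max`,
#' `G < g_max` and `B - R > dom_min`; green and red rules are analogous
#' with the dominant channel swapped. The defaults flag saturated marker
#' colours while leaving eosin pink, hematoxylin purple and black
#' unflagged (black has no dominant channel).
#'
#' @return an object of class `tls_config` (a named list).
#' @examples
#' cfg <- tls_config()
#' cfg$tile_size
#' @export
tls_config <- function(tile_size = 512L,
                       tissue_min_fraction = 0.10,
                       prob_threshold = 0.5,
                       lymphocyte_min_count = 80L,
                       detector_window = 256L,
                       min_contrast = 20,
                       pen_rules = list(
                         blue  = c(dom_min = 60, b_min = 170, r_max = 110, g_max = 130),
                         green = c(dom_min = 40, g_min = 120, r_max = 110, b_max = 160),
                         red   = c(dom_min = 60, r_min = 150, g_max = 100, b_max = 120)
                       ),
                       detector = list(
                         sigma = 2,
                         darkness_min = 0.43,
                         peak_radius = 3L,
                         merge_radius = 4,
                         lymphocyte_darkness = 0.56
                       )) {
  stopifnot(tile_size > 0, tissue_min_fraction >= 0, tissue_min_fraction <= 1,
            prob_threshold >= 0, prob_threshold <= 1, lymphocyte_min_count >= 0)
  structure(list(tile_size = as.integer(tile_size),
                 tissue_min_fraction = tissue_min_fraction,
                 prob_threshold = prob_threshold,
                 lymphocyte_min_count = as.integer(lymphocyte_min_count),
                 detector_window = as.integer(detector_window),
                 min_contrast = min_contrast,
                 pen_rules = pen_rules,
                 detector = detector),
            class = "tls_config")
}
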