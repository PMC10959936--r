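#' Specification of one synthetic H&E-like slide
#'
#' The generator emulates the visual ingredients the pipeline must cope
#' with: tissue on a bright background, dense basophilic TLS-like
#' aggregates of lymphocyte nuclei, scattered stromal lymphocytes, a few
#' larger and paler non-lymphocyte nuclei, per-slide stain-intensity
#' variation (mimicking differing hematoxylin/eosin protocols) and,
#' optionally, saturated pen-mark strokes. Every rendered nucleus is
#' reported in a cell table with CD3/CD20 flags, and exact tissue and TLS
#' masks are emitted, so ground truth is known to the pixel.
#'
#' @param width_px,height_px canvas size in pixels.
#' @param mpp micrometres per pixel (default 0.5, the 20x convention).
#' @param tissue_fraction_target fraction of the canvas covered by
#'   tissue, in `[0, ~0.69]` (the tissue region is a wobbled ellipse and
#'   cannot fill the whole canvas).
#' @param tls_fraction_target fraction of the tissue area covered by TLS
#'   regions, in `[0, 1]`.
#' @param n_tls_regions number of TLS regions; 0 forces an empty TLS mask
#'   regardless of `tls_fraction_target`.
#' @param cells_per_tls_range integer interval; each region receives a
#'   uniformly drawn number of CD3+/CD20+ lymphocytes in this range.
#' @param scattered_lymphocyte_density stromal lymphocytes per mm^2 of
#'   non-TLS tissue.
#' @param nonlymphocyte_fraction extra non-lymphocyte nuclei, as a
#'   fraction of the scattered lymphocyte count.
#' @param stain_jitter non-negative scalar; per-slide multiplicative
#'   perturbation of optical density per channel.
#' @param pen_marks logical; draw 1-2 saturated pen strokes across the
#'   tissue edge.
#' @param seed integer seed; identical specs give byte-identical slides.
#' @return an object of class `synth_slide_spec`.
#' @export
synth_slide_spec <- function(width_px = 1024L, height_px = 1024L, mpp = 0.5,
                             tissue_fraction_target = 0.6,
                             tls_fraction_target = 0.10,
                             n_tls_regions = 3L,
                             cells_per_tls_range = c(80L, 160L),
                             scattered_lymphocyte_density = 400,
                             nonlymphocyte_fraction = 0.25,
                             stain_jitter = 0.05,
                             pen_marks = FALSE,
                             seed = 1L) {
  stopifnot(width_px > 0, height_px > 0, mpp > 0,
            tissue_fraction_target >= 0, tissue_fraction_target <= 1,
            tls_fraction_target >= 0, tls_fraction_target <= 1,
            n_tls_regions >= 0, length(cells_per_tls_range) == 2,
            cells_per_tls_range[1] <= cells_per_tls_range[2],
            scattered_lymphocyte_density >= 0, stain_jitter >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), mpp = mpp,
                 tissue_fraction_target = tissue_fraction_target,
                 tls_fraction_target = tls_fraction_target,
                 n_tls_regions = as.integer(n_tls_regions),
                 cells_per_tls_range = as.integer(cells_per_tls_range),
                 scattered_lymphocyte_density = scattered_lymphocyte_density,
                 nonlymphocyte_fraction = nonlymphocyte_fraction,
                 stain_jitter = stain_jitter,
                 pen_marks = isTRUE(pen_marks),
                 seed = as.integer(seed)),
            class = "synth_slide_spec")
}

# Rendering palette (0-255 RGB) and nucleus geometry, shared by the
# renderer and documented for the detector's darkness rules.
.synth_palette <- function() {
  list(background = c(246, 244, 244), background_sd = 1.2,
       tissue = c(206, 144, 168), tissue_sd = 5,
       lymph = c(96, 72, 138), lymph_r = 4L,
       nonlymph = c(146, 110, 166), nonlymph_r = 7L,
       nucleus_sd = 2,
       lymph_sep = 7, scatter_sep = 9,
       pen = list(blue = c(30, 30, 200), green = c(30, 160, 60),
                  red = c(220, 40, 40)))
}

#' Generate one synthetic slide with exact ground truth
#'
#' Tissue is rendered as a wobbled ellipse sized to
#' `tissue_fraction_target`; TLS regions as non-overlapping ellipses
#' whose areas sum to `tls_fraction_target` of the tissue, each packed
#' with its drawn number of lymphocyte nuclei. Stain jitter is applied as
#' per-slide multiplicative shifts in an optical-density-like colour
#' space. Targets that cannot be realised on the canvas (tissue fraction
#' beyond the elliptical maximum, TLS regions that do not fit or cannot
#' hold their cells) raise an error rather than being silently clipped.
#'
#' @param spec a [synth_slide_spec()].
#' @param slide_id,subject_id identifiers attached to the output.
#' @return an object of class `synth_slide`: `image` (H x W x 3, 0-255),
#'   `tissue_mask_true`, `tls_mask_true` (logical, TLS a subset of
#'   tissue), `tls_labels` (integer region labels), `cells` (data.frame
#'   `cell_id, x, y, cd3, cd20, is_lymphocyte`, 0-based pixel
#'   coordinates, origin top-left), `tls_regions` summary, `true_ratio`,
#'   `mpp`, `spec`.
#' @examples
#' sl <- generate_slide(synth_slide_spec(width_px = 512, height_px = 512,
#'                                       n_tls_regions = 1,
#'                                       cells_per_tls_range = c(60, 80),
#'                                       tls_fraction_target = 0.08, seed = 7))
#' sl$true_ratio
#' @export
generate_slide <- function(spec, slide_id = sprintf("synth-%d", spec$seed),
                           subject_id = slide_id) {
  stopifnot(inherits(spec, "synth_slide_spec"))
  .with_seed(spec$seed, .generate_slide_impl(spec, slide_id, subject_id))
}

.generate_slide_impl <- function(spec, slide_id, subject_id) {
  pal <- .synth_palette()
  W <- spec$width_px; H <- spec$height_px
  A_tissue <- spec$tissue_fraction_target * W * H

  # tissue ellipse, aspect matched to the canvas
  a_t <- sqrt(A_tissue * W / (pi * H))
  b_t <- sqrt(A_tissue * H / (pi * W))
  if (spec$tissue_fraction_target > 0 && (a_t > 0.47 * W || b_t > 0.47 * H))
    stop("impossible geometry: tissue_fraction_target too large for an ",
         "elliptical tissue region on this canvas")
  cx <- W / 2 + runif(1, -0.02, 0.02) * W
  cy <- H / 2 + runif(1, -0.02, 0.02) * H
  wob <- list(a1 = 0.04, p1 = runif(1, 0, 2 * pi),
              a2 = 0.03, p2 = runif(1, 0, 2 * pi))
  tissue <- if (spec$tissue_fraction_target > 0)
    .ellipse_mask(H, W, cx, cy, a_t, b_t, 0, wob) else matrix(FALSE, H, W)

  # TLS regions: non-overlapping ellipses inside the tissue ellipse
  n_tls <- if (spec$tls_fraction_target <= 0) 0L else spec$n_tls_regions
  tls_labels <- matrix(0L, H, W)
  regions <- list()
  if (n_tls > 0L) {
    A_tls_each <- spec$tls_fraction_target * A_tissue / n_tls
    centers <- matrix(NA_real_, n_tls, 2)
    geom <- vector("list", n_tls)
    for (i in seq_len(n_tls)) {
      A_i <- A_tls_each * runif(1, 0.85, 1.15)
      q <- runif(1, 0.7, 1)
      r_i <- sqrt(A_i / pi)
      a_i <- r_i / sqrt(q); b_i <- r_i * sqrt(q)
      th_i <- runif(1, 0, pi)
      rho_max <- 0.92 - (max(a_i, b_i) + 8) / min(a_t, b_t)
      if (rho_max <= 0.1)
        stop("impossible geometry: TLS regions too large for the tissue region")
      placed <- FALSE
      for (try in 1:200) {
        rr <- sqrt(runif(1)) * rho_max; ang <- runif(1, 0, 2 * pi)
        cxi <- cx + rr * cos(ang) * a_t
        cyi <- cy + rr * sin(ang) * b_t
        if (i > 1) {
          prev <- seq_len(i - 1L)
          mind <- sqrt((centers[prev, 1] - cxi)^2 + (centers[prev, 2] - cyi)^2)
          lim <- max(a_i, b_i) + vapply(geom[prev], function(g) max(g$a, g$b), 0) + 6
          if (any(mind < lim)) next
        }
        centers[i, ] <- c(cxi, cyi)
        geom[[i]] <- list(a = a_i, b = b_i, theta = th_i)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("impossible geometry: could not place ", n_tls,
             " non-overlapping TLS regions")
    }
    for (i in seq_len(n_tls)) {
      g <- geom[[i]]
      m <- .ellipse_mask(H, W, centers[i, 1], centers[i, 2], g$a, g$b, g$theta)
      m <- m & tissue
      tls_labels[m] <- i
      regions[[i]] <- list(cx = centers[i, 1], cy = centers[i, 2],
                           a = g$a, b = g$b, theta = g$theta,
                           area_px = sum(m))
    }
  }
  tls <- tls_labels > 0L

  # cells: packed lymphocytes per TLS region, then scattered nuclei
  cells <- list()
  for (i in seq_along(regions)) {
    g <- regions[[i]]
    n_cells <- if (spec$cells_per_tls_range[1] == spec$cells_per_tls_range[2])
      spec$cells_per_tls_range[1]
    else sample(spec$cells_per_tls_range[1]:spec$cells_per_tls_range[2], 1)
    pts <- .dart_ellipse(n_cells, g$cx, g$cy, g$a, g$b, g$theta,
                         min_sep = pal$lymph_sep, margin = pal$lymph_r + 2)
    if (is.null(pts))
      stop("impossible geometry: TLS region ", i, " cannot hold ", n_cells,
           " lymphocytes at the configured packing")
    cd3 <- runif(n_cells) < 0.6
    cells[[length(cells) + 1L]] <-
      data.frame(x = pts[, 1], y = pts[, 2], cd3 = cd3, cd20 = !cd3,
                 is_lymphocyte = TRUE, radius = pal$lymph_r, region = i)
    regions[[i]]$n_cells <- n_cells
  }

  # scattered nuclei in tissue outside TLS; discs must stay inside tissue
  scatter_px <- sum(tissue & !tls)
  n_scatter <- round(spec$scattered_lymphocyte_density *
                       scatter_px * (spec$mpp^2) / 1e6)
  n_nonlymph <- round(spec$nonlymphocyte_fraction * n_scatter)
  place_scatter <- function(n, r, min_sep, existing) {
    if (n <= 0) return(NULL)
    erode_r <- as.integer(r) + 2L
    brush <- EBImage::makeBrush(2L * erode_r + 1L, shape = "disc")
    allowed <- EBImage::imageData(EBImage::erode(EBImage::Image(tissue * 1), brush)) > 0.5
    allowed <- allowed & !tls
    idx <- which(allowed)
    if (length(idx) == 0L) return(NULL)
    pts <- matrix(NA_real_, n, 2); placed <- 0L; tries <- 0L
    while (placed < n && tries < 60L * n) {
      tries <- tries + 1L
      k <- idx[sample.int(length(idx), 1L)]
      yy <- (k - 1L) %% H; xx <- (k - 1L) %/% H
      near <- FALSE
      if (placed > 0L) {
        d2 <- (pts[seq_len(placed), 1] - xx)^2 + (pts[seq_len(placed), 2] - yy)^2
        near <- min(d2) < min_sep^2
      }
      if (!near && !is.null(existing) && nrow(existing) > 0) {
        d2 <- (existing$x - xx)^2 + (existing$y - yy)^2
        near <- min(d2) < min_sep^2
      }
      if (near) next
      placed <- placed + 1L
      pts[placed, ] <- c(xx, yy)
    }
    pts[seq_len(placed), , drop = FALSE]
  }
  existing <- if (length(cells)) do.call(rbind, cells)[, c("x", "y")] else NULL
  sc <- place_scatter(n_scatter, pal$lymph_r, pal$scatter_sep, existing)
  if (!is.null(sc) && nrow(sc) > 0) {
    cd3 <- runif(nrow(sc)) < 0.7
    cells[[length(cells) + 1L]] <-
      data.frame(x = sc[, 1], y = sc[, 2], cd3 = cd3, cd20 = !cd3,
                 is_lymphocyte = TRUE, radius = pal$lymph_r, region = 0L)
  }
  existing <- if (length(cells)) do.call(rbind, cells)[, c("x", "y")] else NULL
  nl <- place_scatter(n_nonlymph, pal$nonlymph_r, pal$scatter_sep + 2, existing)
  if (!is.null(nl) && nrow(nl) > 0) {
    cells[[length(cells) + 1L]] <-
      data.frame(x = nl[, 1], y = nl[, 2], cd3 = FALSE, cd20 = FALSE,
                 is_lymphocyte = FALSE, radius = pal$nonlymph_r, region = 0L)
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(x = numeric(0), y = numeric(0), cd3 = logical(0),
               cd20 = logical(0), is_lymphocyte = logical(0),
               radius = integer(0), region = integer(0))
  cells$x <- round(cells$x); cells$y <- round(cells$y)
  cells <- cells[order(cells$region, cells$y, cells$x), , drop = FALSE]
  cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
  rownames(cells) <- NULL

  # render: background, tissue texture, nuclei, stain jitter, pen marks
  img <- array(0, c(H, W, 3))
  n_px <- H * W
  for (c3 in 1:3)
    img[, , c3] <- pal$background[c3] + rnorm(n_px, 0, pal$background_sd)
  t_idx <- which(tissue)
  for (c3 in 1:3) {
    ch <- img[, , c3]
    ch[t_idx] <- pal$tissue[c3] + rnorm(length(t_idx), 0, pal$tissue_sd)
    img[, , c3] <- ch
  }
  nlym <- cells[!cells$is_lymphocyte, , drop = FALSE]
  img <- .draw_discs(img, nlym$x, nlym$y, pal$nonlymph_r, pal$nonlymph,
                     pal$nucleus_sd)
  lym <- cells[cells$is_lymphocyte, , drop = FALSE]
  img <- .draw_discs(img, lym$x, lym$y, pal$lymph_r, pal$lymph, pal$nucleus_sd)

  if (spec$stain_jitter > 0) {
    fac <- .clamp(1 + spec$stain_jitter * rnorm(3), 0.7, 1.3) *
      .clamp(1 + 0.5 * spec$stain_jitter * rnorm(1), 0.8, 1.2)
    for (c3 in 1:3) {
      od <- -log(.clamp(img[, , c3], 1, 255) / 255)
      img[, , c3] <- 255 * exp(-od * fac[c3])
    }
  }

  if (spec$pen_marks) {
    n_strokes <- sample(1:2, 1)
    for (s in seq_len(n_strokes)) {
      colname <- sample(names(pal$pen), 1)
      col <- pal$pen[[colname]]
      ang <- runif(1, 0, 2 * pi)
      # from outside the tissue ellipse towards (past) its boundary
      x0 <- cx + 1.25 * a_t * cos(ang); y0 <- cy + 1.25 * b_t * sin(ang)
      x1 <- cx + 0.55 * a_t * cos(ang + runif(1, -0.4, 0.4))
      y1 <- cy + 0.55 * b_t * sin(ang + runif(1, -0.4, 0.4))
      tseq <- seq(0, 1, length.out = ceiling(sqrt((x1 - x0)^2 + (y1 - y0)^2) / 2))
      bend <- runif(1, -40, 40)
      xs <- round(x0 + (x1 - x0) * tseq + bend * sin(pi * tseq))
      ys <- round(y0 + (y1 - y0) * tseq + bend * cos(pi * tseq) * 0.3)
      keep <- xs >= 0 & xs < W & ys >= 0 & ys < H
      img <- .draw_discs(img, xs[keep], ys[keep], 5L, col, 0)
    }
  }

  img <- round(.clamp(img, 0, 255))
  true_ratio <- if (sum(tissue) > 0) sum(tls & tissue) / sum(tissue) else NA_real_

  reg_df <- if (length(regions))
    data.frame(region_id = seq_along(regions),
               cx = vapply(regions, `[[`, 0, "cx"),
               cy = vapply(regions, `[[`, 0, "cy"),
               area_px = vapply(regions, `[[`, 0, "area_px"),
               n_cells = vapply(regions, `[[`, 0, "n_cells"))
  else data.frame(region_id = integer(0), cx = numeric(0), cy = numeric(0),
                  area_px = numeric(0), n_cells = numeric(0))

  structure(list(image = img, tissue_mask_true = tissue, tls_mask_true = tls,
                 tls_labels = tls_labels, cells = cells,
                 tls_regions = reg_df, true_ratio = true_ratio,
                 mpp = spec$mpp, spec = spec,
                 slide_id = slide_id, subject_id = subject_id),
            class = "synth_slide")
}

#' @export
print.synth_slide <- function(x, ...) {
  cat(sprintf(paste0("<synth_slide> %s: %d x %d px @ %.3g um/px, ",
                     "%d TLS regions, %d cells, true TLS ratio %.4f\n"),
              x$slide_id, ncol(x$tissue_mask_true), nrow(x$tissue_mask_true),
              x$mpp, nrow(x$tls_regions), nrow(x$cells), x$true_ratio))
  invisible(x)
}

#' @export
plot.synth_slide <- function(x, which = c("image", "tls", "tissue"), ...) {
  which <- match.arg(which)
  op <- graphics::par(mar = c(0, 0, 2, 0)); on.exit(graphics::par(op))
  if (which == "image") {
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), asp = ncol(x$image) / nrow(x$image))
    graphics::rasterImage(x$image / 255, 0, 0, 1, 1)
    graphics::title(x$slide_id)
  } else {
    m <- if (which == "tls") x$tls_mask_true else x$tissue_mask_true
    graphics::image(t(m[nrow(m):1, ]), col = c("white", "black"),
                    axes = FALSE, main = paste(x$slide_id, which))
  }
  invisible(x)
}

#' Specification of a synthetic cohort with outcome-linked TLS ratios
#'
#' Per-subject true TLS ratios are drawn from a Beta distribution; overall
#' survival follows an exponential model whose log-hazard is
#' `log(baseline_hazard) + log_hazard_beta * true_ratio`, censored by an
#' independent exponential; binary treatment response follows a logistic
#' model in the true ratio. Outcomes are linked to the *true* ratio so
#' that downstream statistical tests can separate estimation error from
#' statistical error.
#'
#' @param n_subjects number of subjects.
#' @param slides_per_subject slides rendered per subject (when rendering).
#' @param ratio_distribution list with Beta parameters `shape1`,
#'   `shape2` for the true-ratio distribution.
#' @param log_hazard_beta effect of the true ratio on the log hazard
#'   (negative = protective).
#' @param baseline_hazard baseline event rate per day (> 0).
#' @param censoring_rate independent exponential censoring rate per day
#'   (>= 0; 0 disables censoring).
#' @param response_log_odds_beta effect of the true ratio on the response
#'   log-odds (intercept fixed at `qlogis(0.3)`).
#' @param covariate_scheme list with `age_mean`, `age_sd`, `p_male` and
#'   `stage_probs` (named probabilities for TNM stages I-IV).
#' @param seed integer seed; cohorts are bit-reproducible.
#' @return an object of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_subjects = 100L, slides_per_subject = 1L,
                              ratio_distribution = list(shape1 = 2, shape2 = 18),
                              log_hazard_beta = -2,
                              baseline_hazard = 1 / 1000,
                              censoring_rate = 1 / 2000,
                              response_log_odds_beta = 6,
                              covariate_scheme = list(
                                age_mean = 62, age_sd = 10, p_male = 0.6,
                                stage_probs = c(I = 0.2, II = 0.3, III = 0.3, IV = 0.2)),
                              seed = 1L) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censoring_rate < 0) stop("censoring_rate must be non-negative")
  stopifnot(n_subjects >= 1, slides_per_subject >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 slides_per_subject = as.integer(slides_per_subject),
                 ratio_distribution = ratio_distribution,
                 log_hazard_beta = log_hazard_beta,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 response_log_odds_beta = response_log_odds_beta,
                 covariate_scheme = covariate_scheme,
                 seed = as.integer(seed)),
            class = "synth_cohort_spec")
}

#' Generate a synthetic cohort (slides plus clinical table)
#'
#' @param spec a [synth_cohort_spec()].
#' @param render_slides if `TRUE`, render `slides_per_subject` synthetic
#'   slides per subject whose TLS fraction matches the subject's drawn
#'   ratio; outcomes are then linked to the achieved (rendered) mean
#'   ratio. If `FALSE` (useful for large statistical simulations) only
#'   the clinical table is produced and outcomes use the drawn ratio.
#' @param slide_template a [synth_slide_spec()] whose geometry is reused
#'   for every rendered slide (its `tls_fraction_target`,
#'   `n_tls_regions` and `seed` are overridden per slide).
#' @return a list with `clinical` (data.frame `subject_id, time_days,
#'   event, age, sex, tnm_stage, response, true_ratio`), `slides` (list
#'   of per-subject lists of `synth_slide`, or `NULL`), and `spec`.
#' @export
generate_cohort <- function(spec, render_slides = FALSE,
                            slide_template = synth_slide_spec()) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_subjects
    rd <- spec$ratio_distribution
    ratio <- stats::rbeta(n, rd$shape1, rd$shape2)
    cs <- spec$covariate_scheme
    age <- round(.clamp(rnorm(n, cs$age_mean, cs$age_sd), 30, 92))
    sex <- ifelse(runif(n) < cs$p_male, "M", "F")
    stage <- sample(names(cs$stage_probs), n, replace = TRUE,
                    prob = cs$stage_probs)

    slides <- NULL
    if (render_slides) {
      slides <- vector("list", n)
      for (i in seq_len(n)) {
        subj <- sprintf("S%03d", i)
        slides[[i]] <- lapply(seq_len(spec$slides_per_subject), function(s) {
          sp <- slide_template
          sp$tls_fraction_target <- ratio[i]
          # regions must each be large enough to pack their cells (random
          # sequential disc packing saturates near 55%, and the placement
          # margin shrinks the usable area); a drawn ratio below one viable
          # region renders as TLS-free
          tis_area <- sp$tissue_fraction_target * sp$width_px * sp$height_px
          min_region <- 110 * max(sp$cells_per_tls_range)
          n_by_area <- floor(ratio[i] * tis_area / min_region)
          sp$n_tls_regions <- if (n_by_area < 1L) 0L else
            min(as.integer(ceiling(ratio[i] / 0.04)), as.integer(n_by_area))
          sp$seed <- as.integer((spec$seed * 1000L + i * 10L + s) %% .Machine$integer.max)
          generate_slide(sp, slide_id = sprintf("%s-sl%d", subj, s),
                         subject_id = subj)
        })
        ratio[i] <- mean(vapply(slides[[i]], `[[`, 0, "true_ratio"))
      }
    }

    hazard <- spec$baseline_hazard * exp(spec$log_hazard_beta * ratio)
    t_event <- rexp(n, hazard)
    t_cens <- if (spec$censoring_rate > 0) rexp(n, spec$censoring_rate)
              else rep(Inf, n)
    time_days <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    p_resp <- plogis(qlogis(0.3) + spec$response_log_odds_beta * ratio)
    response <- as.integer(runif(n) < p_resp)

    clinical <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                           time_days = time_days, event = event,
                           age = age, sex = sex, tnm_stage = stage,
                           response = response, true_ratio = ratio)
    list(clinical = clinical, slides = slides, spec = spec)
  })
}
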