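#' Dice coefficient between two binary masks
#'
#' `2|P n T| / (|P| + |T|)`. When both masks are empty the score is 1:
#' a correct all-negative prediction is not penalized (a non-empty
#' prediction against an empty truth scores 0 naturally).
#'
#' @param pred,truth logical masks of identical dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  .check_same_dim(pred, truth)
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred & truth) / denom
}

#' Intersection over union between two binary masks
#'
#' `|P n T| / |P u T|`; 1 when both masks are empty. Related to Dice by
#' `dice = 2 * iou / (1 + iou)`.
#'
#' @inheritParams dice
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(pred, truth) {
  .check_same_dim(pred, truth)
  un <- sum(pred | truth)
  if (un == 0) return(1)
  sum(pred & truth) / un
}

.check_same_dim <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) ||
      (is.null(dim(pred)) && length(pred) != length(truth)))
    stop("mask dimensions differ")
}

# AUC of scores vs binary labels by the rank (Mann-Whitney) statistic;
# ties count one half via average ranks.
.rank_auc <- function(scores, labels) {
  n1 <- as.numeric(sum(labels)); n0 <- length(labels) - n1
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class ground truth")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pixel-level AUC with a tile bootstrap confidence interval
#'
#' Each tile is treated as a pixel-level binary classification problem;
#' pixels are pooled across tiles and the AUC is computed by the rank
#' statistic (equal to the fraction of correctly ordered
#' positive-negative pixel pairs, ties counting one half). The 95\% CI
#' is the percentile interval over `n_boot` bootstrap replicates that
#' resample *tiles* with replacement -- pixels within a tile are
#' spatially dependent, so the tile is the exchangeable unit.
#'
#' @param probmaps list of probability maps (numeric matrices in `[0,1]`),
#'   or a single matrix.
#' @param truths list of logical masks aligned with `probmaps`.
#' @param n_boot number of bootstrap replicates (default 500).
#' @param seed seed for the bootstrap resampling.
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `ci` (length-2 vector), `n_boot`.
#' @export
pixel_auc <- function(probmaps, truths, n_boot = 500L, seed = 1L,
                      conf = 0.95) {
  if (is.matrix(probmaps)) probmaps <- list(probmaps)
  if (is.matrix(truths) || is.logical(truths)) truths <- list(truths)
  stopifnot(length(probmaps) == length(truths), length(probmaps) >= 1)
  scores <- lapply(probmaps, as.numeric)
  labels <- lapply(truths, function(t) as.integer(as.logical(t)))
  auc <- .rank_auc(unlist(scores), unlist(labels))
  n_tiles <- length(scores)
  boots <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_tiles, n_tiles, replace = TRUE)
      lab <- unlist(labels[idx])
      if (sum(lab) == 0L || sum(lab) == length(lab)) return(NA_real_)
      .rank_auc(unlist(scores[idx]), lab)
    }, 0)
  })
  boots <- boots[!is.na(boots)]
  if (length(boots) < 10L)
    stop("bootstrap degenerate: too many single-class replicates")
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  list(auc = auc, ci = ci, n_boot = n_boot)
}

#' Spearman correlation between predicted and true per-tile areas
#'
#' Average-rank ties; the p-value uses the large-sample t approximation
#' (never the exact small-sample distribution).
#'
#' @param pred_areas,true_areas paired numeric vectors, length >= 3.
#' @return list with `rho` and `p`.
#' @export
area_correlation <- function(pred_areas, true_areas) {
  stopifnot(length(pred_areas) == length(true_areas), length(pred_areas) >= 3)
  if (sd(pred_areas) == 0 || sd(true_areas) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(cor.test(pred_areas, true_areas,
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Pooled segmentation score over a set of tiles
#'
#' Pools all tiles of one scope (a slide, or a whole set) and reports
#' Dice, IoU and -- when probability maps are supplied -- pixel AUC with
#' its tile-bootstrap CI.
#'
#' @param pred_masks list of predicted binary masks.
#' @param truth_masks list of ground-truth masks.
#' @param probmaps optional list of probability maps for the AUC.
#' @param n_boot,seed bootstrap parameters for [pixel_auc()].
#' @return list with `dice`, `iou`, and optionally `auc`, `auc_ci`.
#' @export
seg_score <- function(pred_masks, truth_masks, probmaps = NULL,
                      n_boot = 500L, seed = 1L) {
  if (is.matrix(pred_masks) || is.logical(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(truth_masks) || is.logical(truth_masks)) truth_masks <- list(truth_masks)
  stopifnot(length(pred_masks) == length(truth_masks))
  p <- unlist(lapply(pred_masks, as.logical))
  t <- unlist(lapply(truth_masks, as.logical))
  inter <- sum(p & t)
  d <- if (sum(p) + sum(t) == 0) 1 else 2 * inter / (sum(p) + sum(t))
  u <- if (sum(p | t) == 0) 1 else inter / sum(p | t)
  out <- list(dice = d, iou = u)
  if (!is.null(probmaps)) {
    a <- pixel_auc(probmaps, truth_masks, n_boot = n_boot, seed = seed)
    out$auc <- a$auc
    out$auc_ci <- a$ci
  }
  out
}
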