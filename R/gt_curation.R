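#' Does a candidate region qualify as a TLS?
#'
#' A candidate region qualifies when it contains at least `min_cells`
#' (default 50) CD3+ or CD20+ lymphocytes. Containment is decided by the
#' pixel the cell centroid falls in (0-based coordinates floored to the
#' pixel grid).
#'
#' @param candidate logical H x W mask of one connected candidate region.
#' @param cells data.frame with columns `x`, `y` (0-based pixel
#'   coordinates) and logical `cd3`, `cd20`.
#' @param min_cells qualification threshold (inclusive).
#' @return `TRUE` iff the contained CD3+/CD20+ count is >= `min_cells`.
#' @export
qualify_region <- function(candidate, cells, min_cells = 50L) {
  .count_marker_cells(candidate, cells) >= min_cells
}

.count_marker_cells <- function(mask, cells) {
  if (nrow(cells) == 0L) return(0L)
  pos <- cells$cd3 | cells$cd20
  if (!any(pos)) return(0L)
  rows <- floor(cells$y[pos]) + 1L
  cols <- floor(cells$x[pos]) + 1L
  ok <- rows >= 1L & rows <= nrow(mask) & cols >= 1L & cols <= ncol(mask)
  sum(mask[cbind(rows[ok], cols[ok])])
}

#' Build the TLS ground-truth mask from candidate regions
#'
#' Returns the union of the candidate components that pass
#' [qualify_region()]. Candidates come from manual annotation or from the
#' synthetic generator (`tls_labels`), never from automatic clustering:
#' region proposal is an input to curation, not an algorithm.
#'
#' @param candidates either a list of logical masks (one per candidate,
#'   pairwise disjoint) or an integer label matrix with 0 = background.
#' @param cells cell table as in [qualify_region()].
#' @param min_cells qualification threshold.
#' @return logical mask, the union of qualifying components.
#' @export
build_tls_mask <- function(candidates, cells, min_cells = 50L) {
  if (is.matrix(candidates) && !is.logical(candidates)) {
    labs <- sort(unique(candidates[candidates > 0]))
    candidates <- lapply(labs, function(l) candidates == l)
  }
  if (length(candidates) == 0L)
    stop("no candidate regions supplied; pass at least an empty label matrix")
  dims <- dim(candidates[[1]])
  out <- matrix(FALSE, dims[1], dims[2])
  if (length(candidates) > 1L) {
    overlap <- Reduce(`+`, lapply(candidates, function(m) m * 1L))
    if (any(overlap > 1L)) stop("candidate regions overlap")
  }
  for (m in candidates) {
    stopifnot(identical(dim(m), dims))
    if (qualify_region(m, cells, min_cells)) out <- out | m
  }
  out
}

#' Curate training tiles by TLS-area fraction
#'
#' Retains tiles whose TLS-mask fraction strictly exceeds `min_fraction`
#' (default 0.40, the training-set curation rule). Optionally a fraction
#' of TLS-free tiles is appended as negatives; the default of 0 matches
#' the literal curation rule.
#'
#' @param tiles list of tiles (any type; carried through).
#' @param masks list of logical TLS masks aligned with `tiles`.
#' @param min_fraction strict lower bound on the TLS-area fraction.
#' @param negative_fraction fraction (of the number of retained positive
#'   tiles) of TLS-free tiles to append, sampled with `seed`.
#' @param seed seed for negative sampling.
#' @return integer vector of retained tile indices (positives first).
#' @export
curate_training_tiles <- function(tiles, masks, min_fraction = 0.40,
                                  negative_fraction = 0, seed = 1L) {
  stopifnot(length(tiles) == length(masks))
  frac <- vapply(masks, function(m) mean(m), 0)
  pos <- which(frac > min_fraction)
  if (negative_fraction > 0) {
    neg_pool <- which(frac == 0)
    n_neg <- min(length(neg_pool), round(negative_fraction * length(pos)))
    if (n_neg > 0) {
      neg <- .with_seed(seed, neg_pool[sample.int(length(neg_pool), n_neg)])
      return(c(pos, neg))
    }
  }
  pos
}

#' Random 7:1:2 train/validation/test split
#'
#' Tile ids are shuffled with the given seed and allocated
#' `floor(n * 7/10)` to train, `floor(n * 1/10)` to validation and the
#' remainder to test, so the three sets are disjoint and exhaustive for
#' any n.
#'
#' @param tile_ids vector of unique tile identifiers.
#' @param ratios length-3 positive weights (default `c(7, 1, 2)`).
#' @param seed integer seed.
#' @return an object of class `dataset_split`: list with `train`, `val`,
#'   `test` and `seed`.
#' @examples
#' split_dataset(1:10, seed = 1)  # sizes 7, 1, 2
#' @export
split_dataset <- function(tile_ids, ratios = c(7, 1, 2), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  if (anyDuplicated(tile_ids)) stop("tile_ids must be unique")
  n <- length(tile_ids)
  if (n == 0L)
    return(structure(list(train = tile_ids, val = tile_ids, test = tile_ids,
                          seed = seed), class = "dataset_split"))
  tot <- sum(ratios)
  shuffled <- .with_seed(seed, sample(tile_ids))
  n_train <- floor(n * ratios[1] / tot)
  n_val <- floor(n * ratios[2] / tot)
  structure(list(train = shuffled[seq_len(n_train)],
                 val = shuffled[n_train + seq_len(n_val)],
                 test = shuffled[setdiff(seq_len(n), seq_len(n_train + n_val))],
                 seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}
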