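make_cells <- function(n, x0, y0, cd3 = TRUE) {
  data.frame(x = x0 + seq_len(n) %% 10, y = y0 + seq_len(n) %/% 10,
             cd3 = rep(cd3, n), cd20 = rep(FALSE, n),
             is_lymphocyte = rep(TRUE, n))
}

test_that("regions qualify at exactly 50 marker-positive cells", {
  comp <- matrix(FALSE, 40, 40); comp[5:25, 5:25] <- TRUE
  expect_true(qualify_region(comp, make_cells(50, 8, 8)))
  expect_false(qualify_region(comp, make_cells(49, 8, 8)))
  expect_false(qualify_region(comp, make_cells(0, 8, 8)))
  # marker-negative cells never count
  neg <- make_cells(60, 8, 8); neg$cd3 <- FALSE
  expect_false(qualify_region(comp, neg))
})

test_that("the TLS mask is the union of qualifying components only", {
  a <- matrix(FALSE, 60, 60); a[5:25, 5:25] <- TRUE
  b <- matrix(FALSE, 60, 60); b[35:55, 35:55] <- TRUE
  cells <- rbind(make_cells(60, 8, 8), make_cells(10, 38, 38))
  m <- build_tls_mask(list(a, b), cells)
  expect_identical(m, a)
  expect_identical(build_tls_mask(list(b, a), cells), m)  # order invariance
  # both qualify: disjoint union
  cells2 <- rbind(make_cells(60, 8, 8), make_cells(55, 38, 38))
  m2 <- build_tls_mask(list(a, b), cells2)
  expect_equal(sum(m2), sum(a) + sum(b))
  # no qualifying candidate -> empty mask
  expect_false(any(build_tls_mask(list(a), make_cells(3, 8, 8))))
  # overlap is an error
  ab <- a; ab[20:40, 20:40] <- TRUE
  expect_error(build_tls_mask(list(a, ab), cells), "overlap")
})

test_that("ground truth rebuilt from the cell table matches the generator", {
  sl <- fixture_slide(63)
  m <- build_tls_mask(sl$tls_labels, sl$cells)
  expect_identical(m, sl$tls_mask_true)
})

test_that("tile curation keeps only tiles with TLS fraction above 40%", {
  mk <- function(frac) {
    m <- matrix(FALSE, 100, 100)
    if (frac > 0) m[seq_len(round(frac * 100)), ] <- TRUE
    m
  }
  masks <- list(mk(0.41), mk(0.40), mk(0), mk(0.9))
  kept <- curate_training_tiles(as.list(1:4), masks)
  expect_equal(kept, c(1L, 4L))
  # optional negatives are drawn from TLS-free tiles
  kept2 <- curate_training_tiles(as.list(1:4), masks, negative_fraction = 0.5,
                                 seed = 3)
  expect_setequal(setdiff(kept2, kept), 3L)
})

test_that("7:1:2 splits partition the tile ids at the documented sizes", {
  s10 <- split_dataset(1:10, seed = 1)
  expect_equal(lengths(s10[c("train", "val", "test")]),
               c(train = 7L, val = 1L, test = 2L))
  s20 <- split_dataset(1:20, seed = 1)
  expect_equal(lengths(s20[c("train", "val", "test")]),
               c(train = 14L, val = 2L, test = 4L))
  s0 <- split_dataset(integer(0), seed = 1)
  expect_equal(lengths(s0[c("train", "val", "test")]),
               c(train = 0L, val = 0L, test = 0L))
  # disjoint and complete for arbitrary n and seed; deterministic
  for (n in c(7, 13, 101)) {
    for (seed in c(2, 9)) {
      s <- split_dataset(seq_len(n), seed = seed)
      all_ids <- c(s$train, s$val, s$test)
      expect_equal(sort(all_ids), seq_len(n))
      expect_equal(length(all_ids), n)  # no duplicates across sets
      expect_identical(split_dataset(seq_len(n), seed = seed)$train, s$train)
    }
  }
  expect_error(split_dataset(c(1, 1, 2)), "unique")
})
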