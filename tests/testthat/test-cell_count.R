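test_that("well-separated nuclei are each detected near their true centroid", {
  sp <- synth_slide_spec(width_px = 512, height_px = 512, n_tls_regions = 0,
                         tls_fraction_target = 0,
                         scattered_lymphocyte_density = 500,
                         nonlymphocyte_fraction = 0, seed = 71)
  sl <- generate_slide(sp)
  det <- detect_cells_default(tile_image(sl$image, 0, 0))
  expect_equal(nrow(det), nrow(sl$cells))
  for (i in seq_len(nrow(sl$cells))) {
    d <- sqrt((det$x - sl$cells$x[i])^2 + (det$y - sl$cells$y[i])^2)
    expect_lte(min(d), 3)
  }
  expect_true(all(det$is_lymphocyte))
})

test_that("blank background tiles yield no detections", {
  set.seed(1)
  blank <- array(245 + rnorm(512 * 512 * 3, 0, 1.5), c(512, 512, 3))
  expect_equal(nrow(detect_cells_default(blank)), 0L)
})

test_that("per-window counts aggregate across the four 256px windows", {
  sl <- generate_slide(synth_slide_spec(
    width_px = 512, height_px = 512, n_tls_regions = 0,
    tls_fraction_target = 0, scattered_lymphocyte_density = 500,
    nonlymphocyte_fraction = 0, seed = 72))
  det <- detect_cells_default(tile_image(sl$image, 0, 0))
  # recount: detections per quadrant sum to the total
  quad <- table(factor(paste(det$x >= 256, det$y >= 256),
                       levels = c("FALSE FALSE", "TRUE FALSE",
                                  "FALSE TRUE", "TRUE TRUE")))
  expect_equal(sum(quad), nrow(det))
  expect_equal(nrow(det), nrow(sl$cells))
})

test_that("default detector counts are within 10% of truth on dense tiles", {
  for (seed in 73:74) {
    sl <- fixture_slide(seed)
    st <- slide_tiles(sl, overlap = 0)
    for (i in seq_along(st$tiles)) {
      truth <- sum(oracle_detector(sl$cells)(st$tiles[[i]])$is_lymphocyte)
      if (truth < 30) next
      got <- sum(detect_cells_default(st$tiles[[i]])$is_lymphocyte)
      expect_lte(abs(got - truth) / truth, 0.10)
    }
  }
})

test_that("lymphocytes are counted by centroid membership in the mask", {
  mask <- matrix(FALSE, 100, 100); mask[1:50, 1:50] <- TRUE
  cells <- data.frame(
    x = c(seq(5, 45, length.out = 10), seq(60, 90, length.out = 5),
          seq(10, 40, length.out = 3)),
    y = c(seq(5, 45, length.out = 10), seq(60, 90, length.out = 5),
          seq(10, 40, length.out = 3)),
    is_lymphocyte = c(rep(TRUE, 15), rep(FALSE, 3)))
  expect_equal(lymphocytes_in_tls(cells, mask), 10)   # 10 in, 5 out, 3 non-lymph in
  expect_equal(lymphocytes_in_tls(cells, matrix(FALSE, 100, 100)), 0)
  expect_equal(lymphocytes_in_tls(cells, matrix(TRUE, 100, 100)), 15)
  # additivity over disjoint components
  m1 <- mask; m2 <- matrix(FALSE, 100, 100); m2[51:100, 51:100] <- TRUE
  expect_equal(lymphocytes_in_tls(cells, m1 | m2),
               lymphocytes_in_tls(cells, m1) + lymphocytes_in_tls(cells, m2))
})

test_that("the lymphocyte-count filter is strict at 80", {
  expect_true(tls_tile_filter(81))
  expect_false(tls_tile_filter(80))
  expect_false(tls_tile_filter(0))
})
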