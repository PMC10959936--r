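test_that("single-tile ratio arithmetic follows the three-branch rule", {
  # one 512x512 tile: exactly 100,000 tissue px (dark block), a 25,000 px
  # TLS sub-block, and a mocked detector reporting 120 lymphocytes in it
  img <- array(245, c(512, 512, 3))
  img[1:200, 1:500, ] <- 120                     # 100,000 tissue px
  tls <- matrix(FALSE, 512, 512); tls[1:50, 1:500] <- TRUE  # 25,000 px
  seg <- function(tile) tls * 1
  in_tls <- data.frame(x = seq(10, 400, length.out = 120), y = rep(20, 120),
                       is_lymphocyte = TRUE)
  det <- function(tile) in_tls
  r <- compute_slide_ratio(slide_record(img), seg, det)
  expect_equal(r$tissue_pixels, 100000)
  expect_equal(r$tls_pixels, 25000)
  expect_equal(r$ratio, 0.25)
  expect_equal(r$n_tiles_retained, 1L)
  # at exactly 80 lymphocytes the tile's TLS area is zeroed, tissue kept
  det80 <- function(tile) in_tls[1:80, ]
  r80 <- compute_slide_ratio(slide_record(img), seg, det80)
  expect_equal(r80$ratio, 0)
  expect_equal(r80$tissue_pixels, 100000)
  expect_equal(r80$n_tiles_tls_filtered, 1L)
})

test_that("slides without TLS and blank slides are handled", {
  sl <- generate_slide(synth_slide_spec(width_px = 512, height_px = 512,
                                        n_tls_regions = 0, seed = 81))
  r <- compute_slide_ratio(sl, oracle_segmenter(sl$tls_mask_true),
                           oracle_detector(sl$cells))
  expect_equal(r$ratio, 0)
  blank <- array(245, c(512, 512, 3))
  rb <- compute_slide_ratio(slide_record(blank), function(tile) matrix(0, 512, 512))
  expect_false(rb$defined)
  expect_true(is.na(rb$ratio))
})

test_that("the oracle pipeline matches an independent ground-truth recomputation", {
  sl <- fixture_slide(63)
  r <- compute_slide_ratio(sl, oracle_segmenter(sl$tls_mask_true),
                           oracle_detector(sl$cells))
  ref <- reference_slide_ratio(sl)
  expect_lt(abs(r$ratio - ref) / ref, 1e-9)
})

test_that("enlarging the true TLS area never decreases the oracle ratio", {
  sl <- fixture_slide(63)
  base <- compute_slide_ratio(sl, oracle_segmenter(sl$tls_mask_true),
                              oracle_detector(sl$cells))
  grown <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(sl$tls_mask_true * 1), EBImage::makeBrush(9, "disc"))) > 0.5
  r2 <- compute_slide_ratio(sl, oracle_segmenter(grown),
                            oracle_detector(sl$cells))
  expect_gte(r2$ratio, base$ratio)
})

test_that("subject ratios average defined slide ratios only", {
  mk <- function(ratio, defined = TRUE)
    structure(list(slide_id = "s", subject_id = "P1", ratio = ratio,
                   defined = defined), class = "ratio_result")
  expect_equal(subject_ratio(list(mk(0.2), mk(0.4)))$ratio, 0.3)
  expect_equal(subject_ratio(mk(0.17))$ratio, 0.17)
  expect_warning(sr <- subject_ratio(list(mk(0.2), mk(NA_real_, FALSE))),
                 "undefined")
  expect_equal(sr$ratio, 0.2)
  expect_equal(sr$n_slides, 1L)
  expect_warning(s0 <- subject_ratio(list(mk(NA_real_, FALSE))))
  expect_true(is.na(s0$ratio))
})
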