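test_that("slide generation is byte-identical under a fixed seed", {
  sp <- synth_slide_spec(width_px = 512, height_px = 512, seed = 41,
                         n_tls_regions = 1, tls_fraction_target = 0.08,
                         cells_per_tls_range = c(60, 90), pen_marks = TRUE)
  a <- generate_slide(sp)
  b <- generate_slide(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$cells, b$cells)
  expect_identical(a$tls_mask_true, b$tls_mask_true)
})

test_that("no-TLS spec yields an empty TLS mask and zero true ratio", {
  sl <- generate_slide(synth_slide_spec(width_px = 512, height_px = 512,
                                        n_tls_regions = 0, seed = 42))
  expect_false(any(sl$tls_mask_true))
  expect_equal(sl$true_ratio, 0)
})

test_that("achieved TLS and tissue fractions track their targets", {
  sl <- fixture_slide(43, tls_fraction_target = 0.25, n_tls_regions = 4,
                      cells_per_tls_range = c(60L, 120L))
  # recount emitted mask pixels
  ratio <- sum(sl$tls_mask_true & sl$tissue_mask_true) / sum(sl$tissue_mask_true)
  expect_equal(ratio, sl$true_ratio)
  expect_gte(ratio, 0.20)
  expect_lte(ratio, 0.30)
  tf <- mean(sl$tissue_mask_true)
  expect_gte(tf, 0.6 * 0.8)
  expect_lte(tf, 0.6 * 1.2)
})

test_that("TLS masks are subsets of tissue and regions hold their cells", {
  for (seed in 44:46) {
    sl <- fixture_slide(seed)
    expect_false(any(sl$tls_mask_true & !sl$tissue_mask_true))
    expect_true(all(sl$true_ratio >= 0, sl$true_ratio <= 1))
    for (r in sl$tls_regions$region_id) {
      comp <- sl$tls_labels == r
      members <- sl$cells$region == r
      n_in <- sum(comp[cbind(floor(sl$cells$y[members]) + 1,
                             floor(sl$cells$x[members]) + 1)])
      expect_gte(n_in, sl$tls_regions$n_cells[sl$tls_regions$region_id == r])
      expect_gte(n_in, 50)   # downstream curation relies on this
    }
  }
})

test_that("impossible geometry raises an error instead of clipping", {
  expect_error(generate_slide(synth_slide_spec(tissue_fraction_target = 0.95,
                                               seed = 1)),
               "impossible geometry")
  # one small region forced to hold far more cells than it can pack
  expect_error(generate_slide(synth_slide_spec(
    width_px = 512, height_px = 512, tls_fraction_target = 0.01,
    n_tls_regions = 1, cells_per_tls_range = c(500L, 500L), seed = 1)),
    "impossible geometry")
})

test_that("cohort generation is reproducible and honours the censoring knob", {
  sp <- synth_cohort_spec(n_subjects = 60, censoring_rate = 0, seed = 5)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$clinical, b$clinical)
  expect_true(all(a$clinical$event == 1))   # no censoring
  expect_error(synth_cohort_spec(baseline_hazard = 0), "positive")
  expect_error(synth_cohort_spec(censoring_rate = -1), "non-negative")
})

test_that("a Cox fit on the true ratio recovers the simulated log-hazard", {
  sp <- synth_cohort_spec(n_subjects = 400, log_hazard_beta = -2, seed = 17)
  co <- generate_cohort(sp)
  fit <- cox_fit(co$clinical, "true_ratio")
  expect_lt(abs(fit$coefficients[["true_ratio"]] - (-2)),
            3 * fit$se[["true_ratio"]])
})

test_that("a null cohort shows no separation between ratio halves", {
  sp <- synth_cohort_spec(n_subjects = 300, log_hazard_beta = 0,
                          censoring_rate = 0, seed = 23)
  co <- generate_cohort(sp)$clinical
  hi <- co$true_ratio > median(co$true_ratio)
  r <- km_logrank(co$time_days[hi], co$event[hi],
                  co$time_days[!hi], co$event[!hi])
  expect_gt(r$p, 0.01)
})

test_that("rendered cohorts link outcomes to the achieved slide ratios", {
  sp <- synth_cohort_spec(n_subjects = 3, slides_per_subject = 2, seed = 31)
  tmpl <- synth_slide_spec(width_px = 640, height_px = 640,
                           cells_per_tls_range = c(55L, 80L))
  co <- generate_cohort(sp, render_slides = TRUE, slide_template = tmpl)
  expect_length(co$slides, 3)
  for (i in 1:3) {
    achieved <- mean(vapply(co$slides[[i]], `[[`, 0, "true_ratio"))
    expect_equal(co$clinical$true_ratio[i], achieved)
  }
})
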