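sim_surv <- function(n, beta, x = NULL, seed = 1, cens_rate = 0) {
  set.seed(seed)
  if (is.null(x)) x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.01 * exp(beta * x))
  t_c <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  data.frame(time_days = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
             x = x)
}

test_that("optimal cutpoint equals an exhaustive standardized log-rank scan", {
  for (seed in c(9, 30, 57)) {
    set.seed(seed)
    n <- 30
    v <- runif(n)
    d <- sim_surv(n, 1.2, x = as.integer(v > 0.5), seed = seed + 1,
                  cens_rate = 0.002)
    oc <- optimal_cutpoint(v, d$time_days, d$event)
    cuts <- sort(unique(v)); cuts <- cuts[-length(cuts)]
    keep <- vapply(cuts, function(cc) {
      nl <- sum(v <= cc); nl >= 0.1 * n && (n - nl) >= 0.1 * n
    }, TRUE)
    cuts <- cuts[keep]
    stats <- vapply(cuts, function(cc) {
      sqrt(survival::survdiff(survival::Surv(time_days, event) ~ I(v <= cc),
                              data = d)$chisq)
    }, 0)
    best <- cuts[which(stats >= max(stats) - 1e-9)[1]]
    expect_equal(oc$cutpoint, best)
    expect_equal(oc$statistic, max(stats), tolerance = 1e-8)
  }
})

test_that("the cutpoint lands in the gap between separated risk clusters", {
  set.seed(200)
  n <- 200
  v <- c(runif(n / 2, 0, 0.3), runif(n / 2, 0.7, 1))   # two value clusters
  grp <- as.integer(v > 0.5)
  d <- sim_surv(n, log(3), x = grp, seed = 201, cens_rate = 0.002)
  oc <- optimal_cutpoint(v, d$time_days, d$event)
  expect_gt(oc$cutpoint, 0.29)
  expect_lt(oc$cutpoint, 0.71)
  expect_error(optimal_cutpoint(v, d$time_days, rep(0, n)), "no events")
  expect_error(optimal_cutpoint(rep(1, 20), d$time_days[1:20], d$event[1:20]),
               "constant")
  expect_equal(levels(apply_cutpoint(v, oc$cutpoint)), c("low", "high"))
})

test_that("log-rank matches a hand-computed O-E table on six subjects", {
  # A: events at 1, 2, 3; B: events at 4, 5, 6 -- work the table directly
  tm <- c(1, 2, 3, 4, 5, 6); ev <- rep(1, 6)
  grp <- rep(c("A", "B"), each = 3)
  O <- 0; E <- 0; V <- 0
  for (t in tm) {
    at <- tm >= t
    n_i <- sum(at); n1 <- sum(at & grp == "A")
    d1 <- as.integer(t <= 3)
    O <- O + d1; E <- E + n1 / n_i
    if (n_i > 1) V <- V + (n1 / n_i) * (1 - n1 / n_i)
  }
  expected_chisq <- (O - E)^2 / V
  r <- km_logrank(tm[grp == "A"], ev[grp == "A"], tm[grp == "B"], ev[grp == "B"])
  expect_equal(r$statistic, expected_chisq, tolerance = 1e-12)
  # a group compared with itself: statistic 0, p = 1
  self <- km_logrank(tm, ev, tm, ev)
  expect_equal(self$statistic, 0, tolerance = 1e-12)
  expect_equal(self$p, 1)
  expect_error(km_logrank(numeric(0), numeric(0), tm, ev), "empty")
})

test_that("Cox coefficients match a direct partial-likelihood maximization", {
  d <- sim_surv(20, 0.8, seed = 77)           # no ties (continuous times)
  expect_equal(anyDuplicated(d$time_days), 0L)
  fit <- cox_fit(d, "x")
  # independent oracle: maximize the no-ties partial likelihood numerically
  pl <- function(beta) {
    s <- 0
    for (i in which(d$event == 1)) {
      rs <- d$time_days >= d$time_days[i]
      s <- s + beta * d$x[i] - log(sum(exp(beta * d$x[rs])))
    }
    s
  }
  opt <- optimize(pl, c(-5, 5), maximum = TRUE)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-4)
  # the returned optimum beats any grid perturbation
  expect_gte(pl(fit$coefficients) + 1e-10, pl(fit$coefficients + 0.1))
  expect_gte(pl(fit$coefficients) + 1e-10, pl(fit$coefficients - 0.1))
})

test_that("Cox fits recover simulated hazard ratios and flag degeneracies", {
  d <- sim_surv(400, log(0.5), seed = 88, cens_rate = 0.003)
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$coefficients[["x"]] - log(0.5)), 3 * fit$se[["x"]])
  expect_true(all(fit$wald_ci[, "lower"] < fit$hazard_ratios))
  expect_true(all(fit$wald_ci[, "upper"] > fit$hazard_ratios))
  # identical groups relabeled: coefficient ~ 0, HR ~ 1
  d2 <- rbind(d, d); d2$x <- rep(c(0, 1), each = nrow(d))
  d2$time_days <- c(d$time_days, d$time_days)
  fit2 <- cox_fit(d2, "x")
  expect_lt(abs(fit2$coefficients[["x"]]), 1e-6)
  expect_error(cox_fit(transform(d, x = 1), "x"), "constant")
  expect_error(cox_fit(transform(d, event = 0), "x"), "no events")
})

test_that("concordance enumerates usable pairs with half-credit ties", {
  expect_equal(c_index(1:4, rep(1, 4), c(4, 3, 2, 1)), 1)
  expect_equal(c_index(1:4, rep(1, 4), c(1, 2, 3, 4)), 0)
  expect_equal(c_index(c(1, 2, 3, 4), rep(1, 4), c(4, 3, 1, 2)), 5 / 6)
  expect_error(c_index(c(1, 1), c(0, 0), c(1, 2)), "no usable pairs")
  # agrees with the survival package on censored data without tied times
  d <- sim_surv(80, 1, seed = 91, cens_rate = 0.004)
  fit <- cox_fit(d, "x")
  risk <- predict(fit$fit, type = "lp")
  expect_equal(c_index(d$time_days, d$event, risk), fit$c_index,
               tolerance = 1e-12)
  # a pure-noise model sits near 0.5
  set.seed(92)
  expect_lt(abs(c_index(d$time_days, d$event, rnorm(80)) - 0.5), 0.1)
})

test_that("nested likelihood-ratio tests behave at both extremes", {
  d <- sim_surv(200, log(0.4), seed = 95, cens_rate = 0.003)
  set.seed(96); d$noise <- rnorm(200)
  full <- cox_fit(d, c("x", "noise"))
  red <- cox_fit(d, "x")
  lrt <- lrt_nested(full, red)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$p, 0)
  # full = reduced: statistic 0, p = 1
  same <- lrt_nested(red, red)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(lrt_nested(red, full), "not nested")
  # adding the truly prognostic covariate is detected
  d$null_risk <- d$noise
  base <- cox_fit(d, "noise")
  with_x <- cox_fit(d, c("noise", "x"))
  expect_lt(lrt_nested(with_x, base)$p, 0.05)
})

test_that("the responder comparison uses the documented exact/approximate modes", {
  r <- response_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p, 0.1)     # 2 * 1/20: only one of C(6,3) assignments as extreme
  same <- response_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  # exact and approximate p agree closely at combined n = 20 without ties
  set.seed(97)
  x <- rnorm(10); y <- rnorm(10) + 0.5
  r_ex <- response_test(x, y)
  expect_true(r_ex$exact)
  r_ap <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(r_ex$p - r_ap), 0.02)
})
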