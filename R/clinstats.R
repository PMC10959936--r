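#' Maximally selected log-rank cutpoint
#'
#' Scans every distinct biomarker value that leaves at least a `minprop`
#' proportion of subjects on each side, splits subjects into low
#' (`value <= cut`) and high groups, and returns the cutpoint maximizing
#' the absolute standardized log-rank statistic `|O - E| / sqrt(V)`
#' (the convention of maximally selected rank statistics for survival
#' cutpoints). Ties are broken towards the smaller cutpoint.
#'
#' @param values numeric biomarker values (non-constant).
#' @param times,events survival times (> 0) and event indicators (0/1);
#'   at least one event required.
#' @param minprop minimum group proportion per side, in `(0, 0.5)`.
#' @return list with `cutpoint`, `statistic` (the maximal standardized
#'   log-rank statistic) and `candidates` (data.frame of every scanned
#'   cutpoint with its statistic).
#' @export
optimal_cutpoint <- function(values, times, events, minprop = 0.1) {
  n <- length(values)
  stopifnot(length(times) == n, length(events) == n, n >= 10,
            minprop > 0, minprop < 0.5)
  if (sum(events) == 0) stop("log-rank undefined: no events")
  if (length(unique(values)) < 2) stop("biomarker values are constant")
  cuts <- sort(unique(values))
  cuts <- cuts[-length(cuts)]             # highest value leaves an empty side
  n_low <- vapply(cuts, function(cc) sum(values <= cc), 0L)
  ok <- n_low >= minprop * n & (n - n_low) >= minprop * n
  cuts <- cuts[ok]
  if (length(cuts) == 0L)
    stop("no candidate cutpoint satisfies the minprop constraint")
  stat <- vapply(cuts, function(cc) {
    abs(.logrank_z(times, events, values <= cc))
  }, 0)
  best <- which(stat >= max(stat) - 1e-9)[1]   # ties -> smaller cutpoint
  list(cutpoint = cuts[best], statistic = stat[best],
       candidates = data.frame(cutpoint = cuts, statistic = stat))
}

# Standardized log-rank statistic (O - E)/sqrt(V) for group1 = TRUE,
# hypergeometric variance (the Mantel-Haenszel form used by survdiff).
.logrank_z <- function(times, events, group1) {
  et <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in et) {
    at <- times >= t
    n_i <- sum(at); d_i <- sum(events == 1 & times == t)
    n1 <- sum(at & group1); d1 <- sum(events == 1 & times == t & group1)
    O <- O + d1
    E <- E + d_i * n1 / n_i
    if (n_i > 1)
      V <- V + d_i * (n1 / n_i) * (1 - n1 / n_i) * (n_i - d_i) / (n_i - 1)
  }
  if (V <= 0) return(0)
  (O - E) / sqrt(V)
}

#' Apply a fixed cutpoint to biomarker values
#'
#' Supports the external-cutoff mode: a cutpoint learned on one cohort
#' can be applied to another.
#'
#' @param values numeric biomarker values.
#' @param cutpoint the cut; values `<= cutpoint` are `"low"`.
#' @return factor with levels `low`, `high`.
#' @export
apply_cutpoint <- function(values, cutpoint) {
  factor(ifelse(values <= cutpoint, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank comparison of two groups
#'
#' Standard two-group log-rank chi-square with 1 df via
#' [survival::survdiff()]; Kaplan-Meier step functions via
#' [survival::survfit()] are returned for plotting.
#'
#' @param time_a,event_a times and event flags of group A (non-empty).
#' @param time_b,event_b times and event flags of group B.
#' @return list with `statistic` (chi-square), `p`, and `km` (data.frame
#'   `group, time, surv, n_risk, n_event`).
#' @export
km_logrank <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) stop("empty group")
  df <- data.frame(time = c(time_a, time_b),
                   event = c(event_a, event_b),
                   group = rep(c("A", "B"), c(length(time_a), length(time_b))))
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(fit$strata), fit$strata)
  km <- data.frame(group = sub("group=", "", strata), time = fit$time,
                   surv = fit$surv, n_risk = fit$n.risk, n_event = fit$n.event)
  list(statistic = sd0$chisq, p = pchisq(sd0$chisq, df = 1, lower.tail = FALSE),
       km = km)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron tie handling via
#' [survival::coxph()]; hazard ratios with Wald 95\% CIs
#' (`exp(coef +/- 1.96 se)`), the partial log-likelihood and Harrell's
#' concordance are exposed. Monotone likelihood (perfect separation) is
#' flagged as an error rather than returned as a divergent coefficient.
#'
#' @param records data.frame with the time/event columns and covariates.
#' @param covariates character vector of covariate column names
#'   (factors/characters are expanded to treatment contrasts by the
#'   model formula).
#' @param time_col,event_col column names (defaults `time_days`,
#'   `event`).
#' @return an object of class `cox_fit`: `coefficients`,
#'   `hazard_ratios`, `wald_ci` (matrix with `lower`/`upper`),
#'   `log_likelihood`, `null_log_likelihood`, `c_index`, `n`, `n_event`,
#'   `covariates`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(records, covariates, time_col = "time_days",
                    event_col = "event") {
  stopifnot(is.data.frame(records), length(covariates) >= 1,
            all(c(time_col, event_col, covariates) %in% names(records)))
  if (sum(records[[event_col]]) == 0) stop("no events in records")
  for (cv in covariates)
    if (length(unique(records[[cv]])) < 2)
      stop("covariate '", cv, "' is constant")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(cf)) || any(abs(cf) > 15) || any(!is.finite(se)))
    stop("Cox fit did not converge (possible monotone likelihood / ",
         "perfect separation)")
  ci <- cbind(lower = exp(cf - 1.96 * se), upper = exp(cf + 1.96 * se))
  structure(list(coefficients = cf, se = se, hazard_ratios = exp(cf),
                 wald_ci = ci,
                 log_likelihood = fit$loglik[2],
                 null_log_likelihood = fit$loglik[1],
                 c_index = unname(fit$concordance["concordance"]),
                 n = fit$n, n_event = fit$nevent,
                 covariates = covariates, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d (%d events), C-index %.3f, loglik %.2f\n",
              x$n, x$n_event, x$c_index, x$log_likelihood))
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    lower95 = x$wald_ci[, "lower"],
                    upper95 = x$wald_ci[, "upper"])
  print(round(tab, 4))
  invisible(x)
}

#' Harrell's concordance index by pair enumeration
#'
#' Over all usable pairs (the subject with the shorter time has an
#' observed event, and times differ), the C-index is the fraction of
#' pairs where the higher risk score goes to the earlier failure; ties
#' in risk count one half.
#'
#' @param time,event survival times and event flags.
#' @param risk numeric risk scores (higher = expected earlier failure);
#'   alternatively pass a `cox_fit` as `risk` together with `records` to
#'   use its linear predictor.
#' @return C-index in `[0, 1]`.
#' @export
c_index <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- time[i]; tj <- time[j]
      if (ti == tj) next
      first <- if (ti < tj) i else j
      second <- if (ti < tj) j else i
      if (event[first] != 1) next
      usable <- usable + 1
      if (risk[first] > risk[second]) conc <- conc + 1
      else if (risk[first] == risk[second]) conc <- conc + 0.5
    }
  }
  if (usable == 0) stop("no usable pairs for the concordance index")
  conc / usable
}

#' Likelihood-ratio test between nested Cox models
#'
#' `statistic = 2 * (loglik_full - loglik_reduced)`, chi-square with
#' degrees of freedom equal to the difference in estimated coefficients.
#' The reduced model's covariates must be a subset of the full model's.
#'
#' @param fit_full,fit_reduced [cox_fit()] objects on the same records.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_nested <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "cox_fit"), inherits(fit_reduced, "cox_fit"))
  if (!all(fit_reduced$covariates %in% fit_full$covariates))
    stop("models are not nested: reduced covariates must be a subset")
  if (fit_full$n != fit_reduced$n)
    stop("models fit on different records")
  stat <- max(0, 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood))
  df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  if (df <= 0) return(list(statistic = stat, df = 0L, p = 1))
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Two-sided Wilcoxon rank-sum comparison of responder TLS ratios
#'
#' Exact distribution when the combined sample size is at most 20 and
#' there are no ties; normal approximation with tie correction (and
#' continuity correction) otherwise.
#'
#' @param ratios_responders,ratios_nonresponders numeric vectors
#'   (non-empty).
#' @return list with `W` (rank-sum statistic of the first group) and
#'   `p`.
#' @export
response_test <- function(ratios_responders, ratios_nonresponders) {
  x <- ratios_responders; y <- ratios_nonresponders
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, exact = exact)
}
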