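test_that("the product-limit estimate matches closed forms", {
  ## all censored: the curve never drops
  all_cens <- km_estimate(c(3, 8, 12), c(0, 0, 0))
  expect_true(all(all_cens$s_hat == 1))
  ## three events, no censoring
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$s_hat, c(2 / 3, 1 / 3, 0))
  expect_error(km_estimate(numeric(0), numeric(0)), class = "ec_validation_error")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "ec_validation_error")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(31)
  for (i in 1:5) {
    times <- round(rexp(40, 0.05), 1)
    km <- km_estimate(times, rep(1, 40))
    ecdf_surv <- vapply(km$time, function(t) mean(times > t), numeric(1))
    expect_equal(km$s_hat, ecdf_surv)
  }
})

test_that("curve summaries report horizon rates and medians per convention", {
  no_event <- km_estimate(c(50, 80, 130), c(0, 0, 0))
  cs <- curve_summary(no_event, 120)
  expect_equal(cs$rate_pct, 100)
  expect_true(cs$not_reached)

  ## a curve crossing 0.5 exactly at t = 35
  crossing <- km_estimate(c(35, 35, 40, 60), c(1, 1, 0, 0))
  cs2 <- curve_summary(crossing, 120)
  expect_equal(cs2$median_months, 35)

  ## drops after the horizon do not affect the horizon rate
  late <- km_estimate(c(10, 130, 140), c(0, 1, 1))
  expect_equal(curve_summary(late, 120)$rate_at_horizon, 1)
})

test_that("monotone censoring: turning an event into censoring never lowers the curve", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 12
    times <- round(rexp(n, 0.04), 1) + 0.1
    events <- rbinom(n, 1, 0.7)
    if (!any(events == 1)) events[1] <- 1
    km0 <- km_estimate(times, events)
    i <- sample(which(events == 1), 1)
    events2 <- events
    events2[i] <- 0
    km1 <- km_estimate(times, events2)
    grid <- sort(unique(times))
    s_at <- function(km, t) {
      idx <- which(km$time <= t)
      if (length(idx)) km$s_hat[max(idx)] else 1
    }
    for (t in grid) expect_gte(s_at(km1, t) + 1e-12, s_at(km0, t))
  }
})

test_that("log-rank is zero for identical groups and invariant to relabeling", {
  times <- c(5, 8, 12, 20, 33, 47)
  events <- c(1, 0, 1, 1, 0, 1)
  lr <- logrank_test(rep(times, 2), rep(events, 2),
                     rep(c("a", "b"), each = 6))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  set.seed(5)
  t2 <- rexp(60, 0.03)
  e2 <- rbinom(60, 1, 0.8)
  g2 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  a <- logrank_test(t2, e2, g2)
  relabel <- c(x = "III", y = "I", z = "II")[g2]
  b <- logrank_test(t2, e2, relabel)
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$df, 2)

  expect_error(logrank_test(times, events, rep("a", 6)),
               class = "ec_validation_error")
})

test_that("two-group log-rank equals the squared standardized statistic", {
  ## independent oracle: O-E and hypergeometric variance enumerated by hand
  set.seed(8)
  times <- c(2, 3, 3, 5, 7, 9, 11, 14, 20, 22)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0)
  grp <- rep(c(0, 1), 5)
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle_chi2 <- o_minus_e^2 / v
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$chi2, oracle_chi2, tolerance = 1e-8)
})

test_that("complete early/late separation gives a decisive log-rank result", {
  times <- c(seq(2, 20, length.out = 15), seq(80, 120, length.out = 15))
  events <- c(rep(1, 15), rep(1, 15))
  lr <- logrank_test(times, events, rep(c("early", "late"), each = 15))
  expect_lt(lr$p_value, 0.001)
})

test_that("Cox regression rejects degenerate inputs and flags convergence", {
  set.seed(2)
  times <- rexp(30, 0.05)
  events <- rbinom(30, 1, 0.8)
  expect_error(cox_ph(cbind(x = rep(0, 30)), times, events),
               class = "ec_degenerate_error")
  expect_error(cox_ph(cbind(x = rnorm(1)), times[1], 1L),
               class = "ec_degenerate_error")
  fit <- cox_ph(cbind(age = rnorm(30)), times, events)
  expect_true(is.logical(fit$converged))
  expect_equal(fit$table$hr, exp(fit$table$log_hr))
  expect_true(all(fit$table$ci95_low <= fit$table$ci95_high))
})

test_that("a monotone-separating covariate is flagged as non-convergent", {
  ## perfect separation: hazard direction fully determined by the covariate
  times <- c(1, 2, 3, 4, 50, 60, 70, 80)
  events <- rep(1, 8)
  x <- c(rep(1, 4), rep(0, 4))
  fit <- cox_ph(cbind(sep = x), times, events)
  expect_false(fit$converged)
})

test_that("the Cox sign agrees with which KM curve sits lower", {
  set.seed(12)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  times <- rexp(n, 0.02 * exp(0.9 * x))
  events <- rep(1, n)
  fit <- cox_ph(cbind(x = x), times, events)
  km1 <- curve_summary(km_estimate(times[x == 1], events[x == 1]), 60)
  km0 <- curve_summary(km_estimate(times[x == 0], events[x == 0]), 60)
  expect_equal(fit$table$log_hr > 0, km1$rate_at_horizon < km0$rate_at_horizon)
})

test_that("Cox CIs cover a null hazard ratio at the nominal rate", {
  set.seed(99)
  n <- 120
  covered <- logical(500)
  for (i in 1:500) {
    x <- rbinom(n, 1, 0.5)
    times <- rexp(n, 0.03)          # hazard independent of x
    events <- rbinom(n, 1, 0.85)
    fit <- cox_ph(cbind(x = x), times, events)
    covered[i] <- fit$table$ci95_low <= 1 && 1 <= fit$table$ci95_high
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("Efron and Breslow tie handling are both available and differ on ties", {
  times <- c(rep(4, 5), rep(9, 5), 12, 15)
  events <- c(1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0)
  x <- rep(c(0, 1), 6)
  efron <- cox_ph(cbind(x = x), times, events, ties = "efron")
  breslow <- cox_ph(cbind(x = x), times, events, ties = "breslow")
  expect_false(isTRUE(all.equal(efron$table$log_hr, breslow$table$log_hr)))
})

test_that("report covariate codings dichotomize age/stage/LVSI with CNL reference", {
  clin <- rbind(
    make_clinical("A", age = 60, stage = "III", lvsi = "yes"),
    make_clinical("B", age = 54, stage = "I", lvsi = "no"),
    make_clinical("C", age = 55, stage = "unknown", lvsi = "unknown"))
  x <- encode_cox_covariates(clin, c("CNH", "CNL", "POLE"))
  expect_equal(unname(x["A", ]), c(1, 1, 1, 0, 0, 1))
  expect_equal(unname(x["B", ]), c(0, 0, 0, 0, 0, 0))
  expect_true(is.na(x["C", "stage_III_IV"]))
  expect_true(is.na(x["C", "lvsi_yes"]))
  expect_equal(x["C", "subtype_POLE"], 1, ignore_attr = TRUE)
  expect_equal(colnames(x), c("age_ge_55", "stage_III_IV", "lvsi_yes",
                              "subtype_POLE", "subtype_MSIH", "subtype_CNH"))
})
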