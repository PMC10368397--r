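fit54 <- onearm_fit(rep(12 / log(2), 54))  # 54 events, fitted median 12

test_that("one-sided test reproduces the worked p-values with exact hazards", {
  ni <- exp_hazard_test(fit54, surv_summary(median = 10))
  expect_equal(round(ni$p.value, 4), 0.0902)
  expect_lt(ni$p.value, 0.1)

  sup <- exp_hazard_test(fit54, surv_summary(median = 12))
  expect_identical(sup$p.value, 0.5)
  expect_gt(sup$p.value, 0.1)

  # same z through an independent trapezoid-integrated normal CDF
  z <- sqrt(54) * (log(log(2) / 10) - log(log(2) / 12))
  expect_equal(ni$p.value, 1 - oracle_pnorm(z), tolerance = 1e-6)

  # effect sizes recorded on both scales
  expect_equal(ni$effect_median, 2)
  expect_equal(ni$effect_hazard, log(2) / 12 - log(2) / 10)
})

test_that("p-value is exactly 0.5 at the null for any number of events", {
  for (d in c(1, 7, 40, 54, 500)) {
    fit <- onearm_fit(rep(1, d))
    expect_identical(exp_hazard_test(fit, fit$hazard)$p.value, 0.5)
  }
})

test_that("p-value falls with more events and rises with the fitted hazard", {
  p_by_d <- vapply(c(10, 20, 54, 100), function(d)
    exp_hazard_test(onearm_fit(rep(12 / log(2), d)),
                    surv_summary(median = 10))$p.value, numeric(1))
  expect_true(all(diff(p_by_d) < 0))

  p_by_m <- vapply(c(14, 12, 11, 10.5), function(m)
    exp_hazard_test(onearm_fit(rep(m / log(2), 54)),
                    surv_summary(median = 10))$p.value, numeric(1))
  expect_true(all(diff(p_by_m) > 0))  # hazard rising toward the null
})

test_that("NI p-value never exceeds the superiority p-value when NIM >= 1", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    lam <- runif(1, 0.02, 0.4)
    tm <- rexp(n, lam)
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) == 0) ev[1] <- 1L
    fit <- onearm_fit(tm, ev)
    ctrl <- surv_summary(median = runif(1, 2, 30))
    nim <- runif(1, 1, 1.6)
    p_ni <- exp_hazard_test(fit, shifted_null(ctrl, nim))$p.value
    p_sup <- exp_hazard_test(fit, ctrl)$p.value
    expect_lte(p_ni, p_sup)
  }
})

test_that("the worked final analysis concludes non-inferior only", {
  dec <- dual_test(fit54, surv_summary(median = 12), nim = 1.2, alpha = 0.1)
  expect_s3_class(dec, "dual_decision")
  expect_equal(dec$conclusion, "non_inferior_only")
  expect_lt(dec$ni$p.value, 0.1)
  expect_gte(dec$superiority$p.value, 0.1)
  expect_output(print(dec), "non_inferior_only")
})

test_that("dual decision ranks superior > non-inferior only > inconclusive", {
  ctrl <- surv_summary(median = 12)
  # fitted median far above the control: both nulls rejected
  strong <- dual_test(onearm_fit(rep(24 / log(2), 100)), ctrl, 1.2, 0.1)
  expect_equal(strong$conclusion, "superior")
  expect_lt(strong$superiority$p.value, 0.1)

  # fitted hazard exactly at the NI boundary: p = 0.5, nothing rejected,
  # and the superiority test is gatekept (never run)
  boundary <- dual_test(onearm_fit(rep(10 / log(2), 54)), ctrl, 1.2, 0.1)
  expect_equal(boundary$conclusion, "inconclusive")
  expect_identical(boundary$ni$p.value, 0.5)
  expect_null(boundary$superiority)
})

test_that("the hierarchy is structural: superiority implies non-inferiority", {
  set.seed(21)
  for (i in 1:30) {
    d <- sample(5:80, 1)
    fit <- onearm_fit(rep(runif(1, 4, 40) / log(2), d))
    dec <- dual_test(fit, surv_summary(median = runif(1, 6, 20)),
                     nim = runif(1, 1, 1.5), alpha = 0.1)
    if (dec$conclusion == "superior") {
      expect_lt(dec$ni$p.value, 0.1)
      expect_lt(dec$superiority$p.value, 0.1)
    }
    if (dec$conclusion == "inconclusive") expect_null(dec$superiority)
  }
})

test_that("effect sizes subtract the nulls and the NI effect dominates", {
  ctrl <- surv_summary(median = 12)
  es <- effect_sizes(fit54, ctrl, 1.2)
  expect_equal(unname(es$superiority["median"]), 0)
  expect_equal(unname(es$non_inferiority["median"]), 2)

  es18 <- effect_sizes(onearm_fit(rep(18 / log(2), 30)), ctrl, 1.2)
  expect_equal(unname(es18$superiority["median"]), 6)
  expect_equal(unname(es18$non_inferiority["median"]), 8)

  # for any fit at or above the control median with NIM > 1, the NI effect
  # exceeds the superiority effect in absolute value on both scales
  set.seed(5)
  for (i in 1:25) {
    m0 <- runif(1, 5, 20)
    mhat <- m0 * runif(1, 1, 2.5)
    nim <- runif(1, 1.01, 1.5)
    es_i <- effect_sizes(onearm_fit(rep(mhat / log(2), 20)),
                         surv_summary(median = m0), nim)
    expect_gt(abs(es_i$non_inferiority["median"]),
              abs(es_i$superiority["median"]))
    expect_gt(abs(es_i$non_inferiority["hazard"]),
              abs(es_i$superiority["hazard"]))
  }
})

test_that("threshold decision encodes the CI lower-bound rule", {
  expect_equal(threshold_decision(3.6, 3.3, 4)$conclusion,
               "non_inferior_only")
  expect_equal(threshold_decision(4.5, 3.3, 4)$conclusion, "superior")
  expect_equal(threshold_decision(3.0, 3.3, 4)$conclusion, "inconclusive")
  expect_equal(threshold_decision(NA, 3.3, 4)$conclusion, "inconclusive")
  expect_match(threshold_decision(NA, 3.3, 4)$diagnostic, "undefined")
  expect_error(threshold_decision(3.6, 4, 3.3), "must not exceed")
})

test_that("KM survival curve matches brute-force product-limit exhaustively", {
  # every event/censoring pattern on small samples with distinct times
  for (n in 1:6) {
    times <- seq_len(n)
    for (mask in 0:(2^n - 1)) {
      ev <- as.integer(intToBits(mask)[1:n])
      sf <- survival::survfit(survival::Surv(times, ev) ~ 1)
      km <- oracle_km(times, ev)
      expect_equal(summary(sf, times = km$time)$surv, km$surv,
                   tolerance = 1e-12)
    }
  }
  # tied times, events and censorings mixed at the same time point
  times <- c(1, 1, 2, 2, 2, 3, 5, 5)
  for (mask in 0:(2^8 - 1)) {
    ev <- as.integer(intToBits(mask)[1:8])
    sf <- survival::survfit(survival::Surv(times, ev) ~ 1)
    km <- oracle_km(times, ev)
    expect_equal(summary(sf, times = km$time)$surv, km$surv,
                 tolerance = 1e-12)
  }
})

test_that("KM median on uncensored data is the sample median order statistic", {
  x <- c(9, 3, 14, 6, 2, 11, 5)  # n = 7: survival crosses 0.5 at the 4th
  dec <- km_decision(data.frame(time = x, event = 1),
                     ni_threshold = 1, sup_threshold = 2)
  expect_equal(dec$median, sort(x)[4])
  expect_equal(dec$median, oracle_km_median(x, rep(1, 7)))
})

test_that("KM decision applies the thresholds to the median CI lower bound", {
  set.seed(31)
  d <- data.frame(time = rexp(120, log(2) / 4.6), event = 1)
  dec <- km_decision(d, ni_threshold = 3.3, sup_threshold = 4,
                     conf.level = 0.90)
  lower <- dec$ci[["lower"]]
  expect_false(is.na(lower))
  expect_equal(dec$conclusion,
               threshold_decision(lower, 3.3, 4)$conclusion)
  # the reported interval is the survfit log-log interval for the median
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                          conf.type = "log-log", conf.int = 0.90)
  q <- quantile(sf, probs = 0.5)
  expect_equal(lower, unname(q$lower))
  expect_equal(dec$median, unname(q$quantile))

  # heavy censoring: median never reached -> inconclusive with diagnostic
  few <- data.frame(time = c(10, 12, 14, 15), event = c(0, 0, 0, 1))
  dec2 <- km_decision(few, ni_threshold = 3.3, sup_threshold = 4)
  expect_equal(dec2$conclusion, "inconclusive")
  expect_match(dec2$diagnostic, "undefined")
})

test_that("trial data CSV reader validates structure and flags bad rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,time,event", "1,5.2,1", "2,7.1,0", "3,2.0,1"),
             path)
  df <- read_trial_data(path)
  expect_equal(nrow(df), 3)
  expect_type(df$time, "double")
  expect_type(df$event, "integer")

  writeLines(c("patient_id,time,event", "1,5.2,1", "2,-1,0", "3,2.0,2"),
             path)
  expect_error(read_trial_data(path), "lines 2, 3")

  writeLines(c("patient_id,time", "1,5.2"), path)
  expect_error(read_trial_data(path), "event")
  expect_error(read_trial_data(tempfile()), "not found")
})
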