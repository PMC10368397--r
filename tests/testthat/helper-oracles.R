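# Independent oracles used to cross-check the package's computations.
# These deliberately avoid the code paths (and, where feasible, the base
# functions) they are used to verify.

# Standard normal CDF by trapezoid integration of the density.
oracle_pnorm <- function(z) {
  if (z < -12) return(0)
  x <- seq(-12, z, length.out = 200001L)
  f <- exp(-x^2 / 2) / sqrt(2 * pi)
  h <- x[2] - x[1]
  h * (sum(f) - (f[1] + f[length(f)]) / 2)
}

# Inverse standard normal CDF by bisection on the oracle CDF.
oracle_qnorm <- function(p) {
  lo <- -10; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (oracle_pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force Kaplan-Meier product-limit estimator. Events precede
# censorings at tied times. Returns the survival step function evaluated
# just after each unique observed time.
oracle_km <- function(time, event) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    if (d > 0) s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Brute-force KM median: smallest observed time where survival drops to
# <= 0.5, NA if never reached.
oracle_km_median <- function(time, event) {
  km <- oracle_km(time, event)
  idx <- which(km$surv <= 0.5 + 1e-12)
  if (length(idx)) km$time[min(idx)] else NA_real_
}

# A reproducible censored dataset with a known fitted hazard: d events, each
# contributing mean exposure, plus censored records absorbing the remainder.
make_trial <- function(d, exposure_total, n_censored = 0) {
  if (n_censored == 0)
    return(data.frame(time = rep(exposure_total / d, d), event = 1L))
  event_time <- exposure_total / (2 * d)
  cens_time <- (exposure_total - d * event_time) / n_censored
  data.frame(time = c(rep(event_time, d), rep(cens_time, n_censored)),
             event = c(rep(1L, d), rep(0L, n_censored)))
}

# Baseline configuration of the worked metastatic design, for simulations.
metastatic_config <- function(true_median, replicates, seed,
                              dropout_rate = 0) {
  lam <- log(2) / true_median
  mu <- if (dropout_rate > 0)
    calibrate_dropout(dropout_rate, lam, accrual = 12, followup = 24) else 0
  sim_config(true_hazard = lam, n_patients = 66, accrual = 12, followup = 24,
             dropout_hazard = mu, replicates = replicates, seed = seed,
             control = surv_summary(median = 12), nim = 1.2, alpha = 0.1)
}
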