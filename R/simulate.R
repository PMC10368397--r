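# Patient-level trial simulator (uniform accrual, exponential event times,
# dropout, administrative censoring) and Monte Carlo operating
# characteristics of the dual decision rule.

#' Configuration for trial simulation
#'
#' Bundles the generative model (true hazard, accrual, follow-up, dropout),
#' the trial size, the Monte Carlo settings, and the decision inputs the
#' simulated trials are analysed with. Entry times are uniform over the
#' accrual period; latent event and dropout times are exponential;
#' administrative censoring falls at `accrual + followup` months from study
#' start, i.e. every patient gets at least `followup` months of potential
#' observation.
#'
#' @param true_hazard True event hazard per month.
#' @param n_patients Patients per simulated trial.
#' @param accrual,followup Accrual period and minimum follow-up (months).
#' @param dropout_hazard Dropout (random censoring) hazard per month; 0 for
#'   none. See [calibrate_dropout()] to match a target dropout fraction.
#' @param dropout_model `"exponential"` (default) or `"uniform"`; the
#'   uniform model draws the dropout time uniformly over each patient's
#'   administrative window, scaled to the same overall dropout fraction is
#'   *not* attempted — the rate parameter is reinterpreted as the dropout
#'   probability per patient.
#' @param replicates Number of simulated trials.
#' @param seed Base seed; each replicate derives its own reproducible,
#'   order-independent stream from `(seed, replicate)`.
#' @param control Control [surv_summary()] (or median) for the decision rule.
#' @param nim Non-inferiority margin (object or ratio >= 1).
#' @param alpha One-sided level for the dual test.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(true_hazard, n_patients, accrual, followup,
                       dropout_hazard = 0,
                       dropout_model = c("exponential", "uniform"),
                       replicates = 10000, seed = 1,
                       control, nim = 1, alpha = 0.1) {
  dropout_model <- match.arg(dropout_model)
  stopifnot(is.numeric(true_hazard), length(true_hazard) == 1L,
            true_hazard > 0,
            is.numeric(n_patients), n_patients >= 1,
            is.numeric(accrual), accrual >= 0,
            is.numeric(followup), followup > 0,
            is.numeric(dropout_hazard), dropout_hazard >= 0,
            is.numeric(replicates), replicates >= 1)
  structure(
    list(true_hazard = true_hazard, n_patients = as.integer(n_patients),
         accrual = accrual, followup = followup,
         dropout_hazard = dropout_hazard, dropout_model = dropout_model,
         replicates = as.integer(replicates), seed = as.integer(seed),
         control = as_surv_summary(control), nim = nim_value(nim),
         alpha = alpha),
    class = "sim_config")
}

# Reproducible, order-independent per-replicate seed: distinct for all
# replicate indices below 2^31 - 1 (prime modulus, nonzero multiplier).
replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) + 747796405 * as.numeric(replicate)) %%
               2147483647)
}

#' Simulate one single-arm trial
#'
#' Draws one patient-level dataset under the configured generative model.
#' Each patient's observed time is the minimum of the latent event time,
#' the latent dropout time, and the administrative censoring time
#' `accrual + followup - entry`; the event flag records whether the event
#' came first. The draw is deterministic given `(seed, replicate)` and does
#' not depend on how many other replicates were generated.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index (1-based).
#' @return A data frame with columns `patient_id`, `entry_time`, `time`,
#'   `event`.
#' @export
simulate_trial <- function(config, replicate = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(replicate_seed(config$seed, replicate))
  n <- config$n_patients
  entry <- stats::runif(n, 0, config$accrual)
  t_event <- stats::rexp(n, config$true_hazard)
  admin <- config$accrual + config$followup - entry
  t_drop <- if (config$dropout_hazard <= 0) rep(Inf, n)
    else if (config$dropout_model == "exponential")
      stats::rexp(n, config$dropout_hazard)
    else  # uniform: with prob = dropout_hazard, drop at a U(0, admin) time
      ifelse(stats::runif(n) < config$dropout_hazard,
             stats::runif(n, 0, admin), Inf)
  time <- pmin(t_event, t_drop, admin)
  data.frame(patient_id = seq_len(n),
             entry_time = entry,
             time = time,
             event = as.integer(t_event <= pmin(t_drop, admin)))
}

#' Calibrate the dropout hazard to a target dropout fraction
#'
#' Solves for the exponential dropout hazard under which the expected
#' fraction of patients whose observation ends by dropout (before either the
#' event or administrative censoring) equals the target. The planning-stage
#' inflation divides the patient count by `1 - target`; this gives the
#' generative counterpart of that rate.
#'
#' @param target Target dropout fraction in (0, 1).
#' @param true_hazard Event hazard the dropouts compete against.
#' @param accrual,followup Accrual and minimum follow-up (months).
#' @return Dropout hazard per month.
#' @export
calibrate_dropout <- function(target, true_hazard, accrual, followup) {
  stopifnot(is.numeric(target), length(target) == 1L, target > 0, target < 1)
  frac <- function(mu) {
    lam <- true_hazard
    per_entry <- function(e) {
      tau <- accrual + followup - e
      (mu / (lam + mu)) * (1 - exp(-(lam + mu) * tau))
    }
    if (accrual == 0) per_entry(0)
    else stats::integrate(per_entry, 0, accrual)$value / accrual
  }
  upper <- 1
  while (frac(upper) < target) upper <- upper * 2
  stats::uniroot(function(m) frac(m) - target, c(1e-10, upper),
                 tol = 1e-10)$root
}

#' Monte Carlo operating characteristics of the dual decision rule
#'
#' Simulates trials under a [sim_config()], analyses each with
#' [dual_test()], and tallies the rejection rates of the non-inferiority and
#' superiority nulls together with the conclusion frequencies, mean events
#' per trial, and Monte Carlo standard errors \eqn{\sqrt{p(1-p)/R}}. Trials
#' with no events cannot reject (and are counted separately).
#'
#' @param config A [sim_config()].
#' @return An object of class `"onearm_oc"`; also a one-row data frame via
#'   [as.data.frame()].
#' @export
operating_characteristics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  R <- config$replicates
  rej_ni <- rej_sup <- logical(R)
  conclusions <- character(R)
  d_events <- integer(R)
  zero_events <- 0L
  for (r in seq_len(R)) {
    trial <- simulate_trial(config, r)
    d_events[r] <- sum(trial$event)
    if (d_events[r] == 0L) {
      zero_events <- zero_events + 1L
      conclusions[r] <- "inconclusive"
      next
    }
    fit <- onearm_fit(trial$time, trial$event)
    dec <- dual_test(fit, config$control, config$nim, config$alpha)
    rej_ni[r] <- dec$conclusion != "inconclusive"
    rej_sup[r] <- dec$conclusion == "superior"
    conclusions[r] <- dec$conclusion
  }
  p_ni <- mean(rej_ni)
  p_sup <- mean(rej_sup)
  freq <- c(superior = mean(conclusions == "superior"),
            non_inferior_only = mean(conclusions == "non_inferior_only"),
            inconclusive = mean(conclusions == "inconclusive"))
  structure(
    list(config = config,
         reject_ni_rate = p_ni, reject_sup_rate = p_sup,
         se_ni = sqrt(p_ni * (1 - p_ni) / R),
         se_sup = sqrt(p_sup * (1 - p_sup) / R),
         conclusion_freq = freq,
         mean_events = mean(d_events),
         zero_event_trials = zero_events,
         replicates = R),
    class = "onearm_oc")
}

#' @export
print.onearm_oc <- function(x, digits = 4, ...) {
  cat(sprintf("Operating characteristics (%d replicates, true median %s m)\n",
              x$replicates,
              format(signif(log(2) / x$config$true_hazard, digits))))
  cat(sprintf("  reject NI null:          %.4f (MC SE %.4f)\n",
              x$reject_ni_rate, x$se_ni))
  cat(sprintf("  reject superiority null: %.4f (MC SE %.4f)\n",
              x$reject_sup_rate, x$se_sup))
  cat(sprintf("  conclusions: superior %.3f / non-inferior only %.3f / inconclusive %.3f\n",
              x$conclusion_freq["superior"],
              x$conclusion_freq["non_inferior_only"],
              x$conclusion_freq["inconclusive"]))
  cat(sprintf("  mean events per trial: %.1f; zero-event trials: %d\n",
              x$mean_events, x$zero_event_trials))
  invisible(x)
}

#' @export
as.data.frame.onearm_oc <- function(x, ...) {
  data.frame(true_hazard = x$config$true_hazard,
             true_median = log(2) / x$config$true_hazard,
             n_patients = x$config$n_patients,
             replicates = x$replicates,
             reject_ni_rate = x$reject_ni_rate,
             reject_sup_rate = x$reject_sup_rate,
             se_ni = x$se_ni, se_sup = x$se_sup,
             superior = unname(x$conclusion_freq["superior"]),
             non_inferior_only = unname(x$conclusion_freq["non_inferior_only"]),
             inconclusive = unname(x$conclusion_freq["inconclusive"]),
             mean_events = x$mean_events,
             zero_event_trials = x$zero_event_trials)
}

#' Rejection rates over a grid of true hazards
#'
#' Runs [operating_characteristics()] for each true hazard in a grid,
#' holding the rest of the configuration fixed. Rejection rates are
#' non-increasing (within Monte Carlo noise) as the true hazard grows.
#'
#' @param config A [sim_config()] providing everything but the true hazard.
#' @param true_hazards Numeric vector of true hazards.
#' @return A data frame, one row per grid point.
#' @export
power_curve <- function(config, true_hazards = config$true_hazard) {
  stopifnot(inherits(config, "sim_config"), length(true_hazards) >= 1)
  rows <- lapply(true_hazards, function(h) {
    cfg <- config
    cfg$true_hazard <- h
    as.data.frame(operating_characteristics(cfg))
  })
  do.call(rbind, rows)
}
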