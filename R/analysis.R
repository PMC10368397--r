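# Final-analysis machinery: one-sided tests of the fitted hazard against the
# superiority and non-inferiority nulls, effect sizes on both scales, the
# hierarchical dual decision, and the nonparametric Kaplan-Meier path.

#' One-sided test of the fitted hazard against a null hazard
#'
#' Asymptotic normal test of the exponential log-hazard MLE: with \eqn{d}
#' events,
#' \deqn{z = \sqrt{d}\,\{\ln \lambda_0 - \ln \hat\lambda\}, \qquad
#'       p = 1 - \Phi(z),}
#' so small p-values indicate the observed hazard lies below the null (the
#' treatment does better than the null allows). When the fitted hazard equals
#' the null exactly the p-value is exactly 0.5. Effect sizes against the
#' null are reported on both the median and hazard scales
#' (\eqn{\hat m - m_0} and \eqn{\hat\lambda - \lambda_0}).
#'
#' @param fit An [onearm_fit()] result.
#' @param null A [surv_summary()], or a single positive null hazard rate.
#' @param label Optional label for printing (e.g. "non-inferiority").
#' @return An object of class `"exp_hazard_test"` with elements
#'   `null_hazard`, `null_median`, `events`, `z`, `p.value`,
#'   `effect_median`, `effect_hazard`, `label`.
#' @examples
#' # 54 events at a fitted median of 12 months vs a 10-month null:
#' fit <- onearm_fit(rep(12 / log(2), 54))
#' exp_hazard_test(fit, surv_summary(median = 10))   # p = 0.0902
#' @export
exp_hazard_test <- function(fit, null, label = NULL) {
  if (!inherits(fit, "onearm_fit"))
    stop("'fit' must be an onearm_fit object", call. = FALSE)
  null_hazard <- if (inherits(null, "surv_summary")) null$hazard else null
  if (!is.numeric(null_hazard) || length(null_hazard) != 1L ||
      is.na(null_hazard) || null_hazard <= 0)
    stop("'null' must be a surv_summary or a single positive hazard",
         call. = FALSE)
  z <- sqrt(fit$events) * (log(null_hazard) - log(fit$hazard))
  structure(
    list(null_hazard = null_hazard,
         null_median = log(2) / null_hazard,
         events = fit$events,
         z = z,
         p.value = stats::pnorm(z, lower.tail = FALSE),
         effect_median = fit$median - log(2) / null_hazard,
         effect_hazard = fit$hazard - null_hazard,
         hazard = fit$hazard, median = fit$median,
         label = label),
    class = "exp_hazard_test")
}

#' @export
print.exp_hazard_test <- function(x, digits = 4, ...) {
  lab <- if (!is.null(x$label)) paste0(" (", x$label, ")") else ""
  cat(sprintf("One-sided exponential hazard test%s\n", lab))
  cat(sprintf("  null: hazard %.3g/month (median %s m); observed %.3g (median %s m)\n",
              x$null_hazard, format(signif(x$null_median, digits)),
              x$hazard, format(signif(x$median, digits))))
  cat(sprintf("  events = %d, z = %s, p = %s\n",
              x$events, format(signif(x$z, digits)),
              format(signif(x$p.value, digits))))
  cat(sprintf("  effect size: %+.3g months (median scale), %+.3g/month (hazard scale)\n",
              x$effect_median, x$effect_hazard))
  invisible(x)
}

#' Effect sizes against the superiority and non-inferiority nulls
#'
#' Signed differences between the fitted summary and each null, on the median
#' and hazard scales. Because the NI null sits below the control median (and
#' above the control hazard) whenever the margin exceeds 1, the NI effect size
#' dominates the superiority effect size in absolute value for any fit at or
#' above the control median.
#'
#' @param fit An [onearm_fit()] result.
#' @param control Control [surv_summary()] (or its median in months).
#' @param nim Non-inferiority margin ([fixed_margin_nim()] result or
#'   ratio >= 1).
#' @return A list with components `superiority` and `non_inferiority`, each
#'   a named vector `c(median =, hazard =)`.
#' @export
effect_sizes <- function(fit, control, nim) {
  if (!inherits(fit, "onearm_fit"))
    stop("'fit' must be an onearm_fit object", call. = FALSE)
  control <- as_surv_summary(control)
  ni <- shifted_null(control, nim)
  list(
    superiority = c(median = fit$median - control$median,
                    hazard = fit$hazard - control$hazard),
    non_inferiority = c(median = fit$median - ni$median,
                        hazard = fit$hazard - ni$hazard))
}

rank_conclusion <- function(ni_pass, sup_pass) {
  if (ni_pass && sup_pass) "superior"
  else if (ni_pass) "non_inferior_only"
  else "inconclusive"
}

#' Hierarchical non-inferiority-then-superiority decision
#'
#' Gatekept dual test at an unadjusted level: the non-inferiority null
#' (control hazard times the margin) is tested first; only when it is
#' rejected is the superiority null (the control hazard itself) tested, at
#' the same \eqn{\alpha}. Because the NI null is the easier of the two, its
#' p-value never exceeds the superiority p-value, which is what makes the
#' hierarchy a valid multiplicity control. The conclusion ranks the evidence:
#' `superior` > `non_inferior_only` > `inconclusive`.
#'
#' @inheritParams effect_sizes
#' @param alpha One-sided test level, in (0, 1).
#' @return An object of class `"dual_decision"`: elements `ni` (an
#'   [exp_hazard_test()]), `superiority` (present only when NI is rejected),
#'   `conclusion`, `alpha`, `nim`, `effects`.
#' @examples
#' fit <- onearm_fit(rep(12 / log(2), 54))   # 54 events, median 12
#' dual_test(fit, control = surv_summary(median = 12), nim = 1.2, alpha = 0.1)
#' @export
dual_test <- function(fit, control, nim, alpha = 0.1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  control <- as_surv_summary(control)
  nim <- nim_value(nim)
  ni_test <- exp_hazard_test(fit, shifted_null(control, nim),
                             label = "non-inferiority")
  ni_pass <- ni_test$p.value < alpha
  sup_test <- NULL
  sup_pass <- FALSE
  if (ni_pass) {
    sup_test <- exp_hazard_test(fit, control, label = "superiority")
    sup_pass <- sup_test$p.value < alpha
  }
  structure(
    list(ni = ni_test, superiority = sup_test,
         conclusion = rank_conclusion(ni_pass, sup_pass),
         alpha = alpha, nim = nim, control = control,
         effects = effect_sizes(fit, control, nim)),
    class = "dual_decision")
}

#' @export
print.dual_decision <- function(x, digits = 4, ...) {
  cat(sprintf("Hierarchical NI/superiority decision (alpha = %g, NIM = %g)\n\n",
              x$alpha, x$nim))
  cat(sprintf("  non-inferiority: p = %s (null median %s m)\n",
              format(signif(x$ni$p.value, digits)),
              format(signif(x$ni$null_median, digits))))
  if (!is.null(x$superiority))
    cat(sprintf("  superiority:     p = %s (null median %s m)\n",
                format(signif(x$superiority$p.value, digits)),
                format(signif(x$superiority$null_median, digits))))
  else
    cat("  superiority:     not tested (gatekept by non-inferiority)\n")
  cat(sprintf("\n  conclusion: %s\n", x$conclusion))
  invisible(x)
}

#' Decision from a median confidence-interval lower bound
#'
#' The threshold form of the dual decision used with nonparametric
#' estimates: non-inferiority is achieved when the lower confidence bound of
#' the median exceeds the NI threshold (the control median divided by the
#' margin), and superiority when it also exceeds the superiority threshold
#' (the control median itself). An undefined lower bound (median not reached
#' or interval unbounded below) is inconclusive.
#'
#' @param ci_lower Lower confidence bound of the estimated median (months),
#'   or `NA` when undefined.
#' @param ni_threshold,sup_threshold Decision thresholds in months, with
#'   `ni_threshold <= sup_threshold`.
#' @return A list with `conclusion` and the pass flags.
#' @examples
#' threshold_decision(3.6, ni_threshold = 3.3, sup_threshold = 4)
#' @export
threshold_decision <- function(ci_lower, ni_threshold, sup_threshold) {
  if (ni_threshold > sup_threshold)
    stop("'ni_threshold' must not exceed 'sup_threshold'", call. = FALSE)
  if (is.null(ci_lower) || length(ci_lower) != 1L || is.na(ci_lower)) {
    return(list(conclusion = "inconclusive", ni = FALSE, superiority = FALSE,
                diagnostic = "median CI lower bound undefined"))
  }
  ni_pass <- ci_lower > ni_threshold
  sup_pass <- ni_pass && ci_lower > sup_threshold
  list(conclusion = rank_conclusion(ni_pass, sup_pass),
       ni = ni_pass, superiority = sup_pass, diagnostic = NULL)
}

#' Nonparametric dual decision from the Kaplan-Meier median CI
#'
#' Estimates the Kaplan-Meier median and its two-sided confidence interval
#' (Greenwood variance on the complementary log-log scale, inverted to a
#' median interval in the Brookmeyer-Crowley manner) and applies
#' [threshold_decision()]: NI is declared when the interval's lower bound
#' clears the NI threshold, superiority when it also clears the superiority
#' threshold. Ties are handled with the standard convention that events
#' precede censorings at the same time.
#'
#' @param data A data frame with columns `time` and `event` (0/1), or an
#'   [onearm_fit()] whose stored data are then used.
#' @param ni_threshold,sup_threshold Thresholds on the median scale
#'   (months); typically `control_median / nim` and `control_median`.
#' @param conf.level Two-sided confidence level for the median interval;
#'   defaults to 0.90, so each bound acts as a one-sided 5% test.
#' @return An object of class `"km_decision"` with the KM median, its CI,
#'   the thresholds, the conclusion, and a diagnostic when the bound is
#'   undefined.
#' @examples
#' set.seed(1)
#' d <- data.frame(time = rexp(60, log(2) / 4.5), event = 1)
#' km_decision(d, ni_threshold = 3.3, sup_threshold = 4)
#' @export
km_decision <- function(data, ni_threshold, sup_threshold, conf.level = 0.90) {
  if (inherits(data, "onearm_fit"))
    data <- data.frame(time = data$time, event = data$status)
  if (!is.data.frame(data) || !all(c("time", "event") %in% names(data)))
    stop("'data' must have columns 'time' and 'event'", call. = FALSE)
  if (!is.numeric(conf.level) || length(conf.level) != 1L ||
      is.na(conf.level) || conf.level <= 0 || conf.level >= 1)
    stop("'conf.level' must be in (0, 1)", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                          conf.type = "log-log", conf.int = conf.level)
  q <- stats::quantile(sf, probs = 0.5)
  med <- unname(q$quantile)
  lower <- unname(q$lower)
  upper <- unname(q$upper)
  dec <- threshold_decision(lower, ni_threshold, sup_threshold)
  structure(
    list(median = med, ci = c(lower = lower, upper = upper),
         conf.level = conf.level,
         ni_threshold = ni_threshold, sup_threshold = sup_threshold,
         conclusion = dec$conclusion, ni = dec$ni,
         superiority = dec$superiority, diagnostic = dec$diagnostic,
         n = nrow(data), events = sum(data$event)),
    class = "km_decision")
}

#' @export
print.km_decision <- function(x, digits = 4, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else format(signif(v, digits))
  cat("Kaplan-Meier dual decision\n")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$events))
  cat(sprintf("  median %s months, %g%% CI %s-%s\n",
              fmt(x$median), 100 * x$conf.level,
              fmt(x$ci["lower"]), fmt(x$ci["upper"])))
  cat(sprintf("  thresholds: NI > %g, superiority > %g months\n",
              x$ni_threshold, x$sup_threshold))
  if (!is.null(x$diagnostic)) cat(sprintf("  note: %s\n", x$diagnostic))
  cat(sprintf("  conclusion: %s\n", x$conclusion))
  invisible(x)
}

#' Read patient-level trial data from a CSV file
#'
#' Expects a comma-separated file with a header and columns `patient_id`,
#' `time`, `event` (0/1), plus an optional `entry_time`. Rows failing
#' validation are reported by line number.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the validated columns.
#' @export
read_trial_data <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time))) |
                 as.numeric(df$time) <= 0 |
                 !(df$event %in% c(0, 1)))
  if (!is.null(df$entry_time))
    bad <- union(bad, which(!is.finite(suppressWarnings(
      as.numeric(df$entry_time))) | as.numeric(df$entry_time) < 0))
  if (length(bad))
    stop("invalid rows (data lines ", paste(sort(bad), collapse = ", "),
         "): 'time' must be positive, 'event' 0/1, 'entry_time' >= 0",
         call. = FALSE)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (!is.null(df$entry_time)) df$entry_time <- as.numeric(df$entry_time)
  df
}
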