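# Sample-size chain for the one-sample exponential design: required events,
# event probability under uniform accrual with fixed minimum follow-up,
# required patients, dropout inflation, and the analytic power inverse.

z_alpha <- function(alpha, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  stats::qnorm(1 - if (sided == "two") alpha / 2 else alpha)
}

#' Required number of events for the one-sample log-hazard test
#'
#' Under the exponential model the ML estimate of the log hazard from
#' \eqn{d} events has variance \eqn{1/d}, so the number of events needed to
#' detect a hazard ratio HR against the null with one-sided level
#' \eqn{\alpha} and power \eqn{1-\beta} is
#' \deqn{d = \frac{(z_{1-\alpha} + z_{1-\beta})^2}{(\ln \mathrm{HR})^2},}
#' rounded up. The formula is symmetric in HR and 1/HR. A two-sided level
#' uses \eqn{z_{1-\alpha/2}}.
#'
#' @param hr Hazard ratio to detect (alternative over null hazard,
#'   equivalently null over alternative median); positive and different
#'   from 1.
#' @param alpha Type I error level.
#' @param sided `"one"` (default) or `"two"`.
#' @param power Target power, in (0, 1).
#' @return A list with `events_exact` (real) and `events` (ceiling).
#' @examples
#' required_events(12 / 18, alpha = 0.1, power = 0.9)   # 39.96 -> 40
#' @export
required_events <- function(hr, alpha = 0.1, sided = c("one", "two"),
                            power = 0.9) {
  sided <- match.arg(sided)
  if (!is.numeric(hr) || length(hr) != 1L || is.na(hr) || hr <= 0)
    stop("'hr' must be a single positive ratio", call. = FALSE)
  if (hr == 1)
    stop("degenerate design: 'hr' = 1 gives no effect to detect", call. = FALSE)
  if (!is.numeric(power) || length(power) != 1L || is.na(power) ||
      power <= 0 || power >= 1)
    stop("'power' must be in (0, 1)", call. = FALSE)
  events_exact <- (z_alpha(alpha, sided) + stats::qnorm(power))^2 / log(hr)^2
  list(events_exact = events_exact, events = ceiling(events_exact))
}

#' Probability that an accrued patient yields an event
#'
#' With entries uniform over an accrual period of length \eqn{a}, a minimum
#' follow-up \eqn{f} after the last entry (administrative censoring at
#' \eqn{a+f} from study start), and exponential event times with hazard
#' \eqn{\lambda}, the chance a patient's event is observed before censoring is
#' \deqn{P = 1 - e^{-\lambda f}\,\frac{1 - e^{-\lambda a}}{\lambda a},}
#' which tends to \eqn{1 - e^{-\lambda f}} as the accrual period shrinks to
#' zero (all patients then get exactly \eqn{f} months of follow-up).
#'
#' @param hazard Event hazard per month, positive.
#' @param accrual Accrual period in months, non-negative.
#' @param followup Minimum follow-up in months, positive.
#' @return Probability in (0, 1).
#' @examples
#' event_probability(log(2) / 18, accrual = 12, followup = 24)  # 0.682
#' @export
event_probability <- function(hazard, accrual, followup) {
  if (!is.numeric(hazard) || length(hazard) != 1L || is.na(hazard) || hazard <= 0)
    stop("'hazard' must be a single positive rate", call. = FALSE)
  if (!is.numeric(followup) || length(followup) != 1L || is.na(followup) ||
      followup <= 0)
    stop("'followup' must be a single positive time", call. = FALSE)
  if (!is.numeric(accrual) || length(accrual) != 1L || is.na(accrual) ||
      accrual < 0)
    stop("'accrual' must be a single non-negative time", call. = FALSE)
  la <- hazard * accrual
  # -expm1(-la)/la is exact in the la -> 0 limit up to rounding; guard la = 0
  accrual_factor <- if (la == 0) 1 else -expm1(-la) / la
  1 - exp(-hazard * followup) * accrual_factor
}

#' Required number of patients given an event probability and dropout
#'
#' Divides the required events by the per-patient event probability, then
#' inflates for the fraction of patients expected to drop out (who are
#' conservatively assumed to contribute nothing), and rounds up:
#' \eqn{n = \lceil d / P / (1 - r) \rceil}.
#'
#' @param events Required events (at least 1).
#' @param event_probability Per-patient event probability in (0, 1].
#' @param dropout_rate Expected dropout fraction, at least 0 and below 1.
#' @return A list with `patients_exact` (events / probability),
#'   `patients_inflated` (after dropout correction) and `patients` (ceiling).
#' @examples
#' required_patients(40, 0.682, dropout_rate = 0.1)  # 58.6 -> 65.1 -> 66
#' @export
required_patients <- function(events, event_probability, dropout_rate = 0) {
  if (!is.numeric(events) || length(events) != 1L || is.na(events) || events < 1)
    stop("'events' must be at least 1", call. = FALSE)
  if (!is.numeric(event_probability) || length(event_probability) != 1L ||
      is.na(event_probability) ||
      event_probability <= 0 || event_probability > 1)
    stop("'event_probability' must be in (0, 1]", call. = FALSE)
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1L ||
      is.na(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("'dropout_rate' must be in [0, 1)", call. = FALSE)
  patients_exact <- events / event_probability
  patients_inflated <- patients_exact / (1 - dropout_rate)
  list(patients_exact = patients_exact,
       patients_inflated = patients_inflated,
       patients = ceiling(patients_inflated))
}

#' Analytic power of the one-sample log-hazard test
#'
#' Inverts the events formula: with \eqn{d} events the power against a hazard
#' ratio HR at level \eqn{\alpha} is
#' \eqn{\Phi(\sqrt{d}\,|\ln \mathrm{HR}| - z_{1-\alpha})}
#' (or \eqn{z_{1-\alpha/2}} two-sided). Evaluated at the exact (unrounded)
#' event count from [required_events()] this returns the planning power.
#'
#' @inheritParams required_events
#' @param events Number of events (may be fractional).
#' @return Power, a probability.
#' @examples
#' analytic_power(39.96, 12 / 18, alpha = 0.1)   # ~0.90
#' @export
analytic_power <- function(events, hr, alpha = 0.1, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!is.numeric(events) || length(events) != 1L || is.na(events) || events < 1)
    stop("'events' must be at least 1", call. = FALSE)
  if (!is.numeric(hr) || length(hr) != 1L || is.na(hr) || hr <= 0)
    stop("'hr' must be a single positive ratio", call. = FALSE)
  if (hr == 1)
    stop("degenerate design: 'hr' = 1 gives no effect to detect", call. = FALSE)
  stats::pnorm(sqrt(events) * abs(log(hr)) - z_alpha(alpha, sided))
}

#' Plan a single-arm exponential trial with NI and superiority objectives
#'
#' Chains the full sample-size calculation: hazard ratio from the control and
#' alternative summaries, required events, per-patient event probability under
#' uniform accrual with administrative censoring (evaluated at the alternative
#' hazard by default, since that is the world the study is powered for), and
#' required patients after dropout inflation. When a non-inferiority margin is
#' supplied, the shifted NI null is recorded alongside the superiority null so
#' the report states both hypotheses on the median and hazard scales.
#'
#' @param control [surv_summary()] for the historical control (or its median).
#' @param alternative [surv_summary()] for the targeted alternative (or its
#'   median). Its hazard must differ from the control hazard.
#' @param alpha,sided,power Test level, sidedness and target power.
#' @param accrual,followup Accrual period and minimum follow-up, months.
#' @param dropout_rate Expected dropout fraction, at least 0 and below 1.
#' @param nim Optional non-inferiority margin ([fixed_margin_nim()] result or
#'   ratio >= 1).
#' @param event_hazard Which hazard the event probability is computed at:
#'   the `"alternative"` (default), the `"control"`, or a `"weighted"`
#'   mixture `weight * alternative + (1 - weight) * control`.
#' @param weight Mixing weight for `event_hazard = "weighted"`.
#' @return An object of class `"onearm_design"`; its print method lays out
#'   the chain the way a protocol would.
#' @examples
#' onearm_design(control = surv_summary(median = 12),
#'               alternative = surv_summary(median = 18),
#'               alpha = 0.1, power = 0.9,
#'               accrual = 12, followup = 24, dropout_rate = 0.1, nim = 1.2)
#' @export
onearm_design <- function(control, alternative, alpha = 0.1,
                          sided = c("one", "two"), power = 0.9,
                          accrual, followup, dropout_rate = 0, nim = NULL,
                          event_hazard = c("alternative", "control", "weighted"),
                          weight = 0.5) {
  sided <- match.arg(sided)
  event_hazard <- match.arg(event_hazard)
  control <- as_surv_summary(control, "control")
  alternative <- as_surv_summary(alternative, "alternative")
  if (control$hazard <= 0)
    stop("control hazard must be positive for sizing", call. = FALSE)
  hr <- alternative$hazard / control$hazard
  ev <- required_events(hr, alpha = alpha, sided = sided, power = power)
  ph <- switch(event_hazard,
               alternative = alternative$hazard,
               control = control$hazard,
               weighted = weight * alternative$hazard +
                 (1 - weight) * control$hazard)
  p_event <- event_probability(ph, accrual, followup)
  pat <- required_patients(ev$events, p_event, dropout_rate)
  ni_null <- if (!is.null(nim)) shifted_null(control, nim)
  structure(
    list(control = control, alternative = alternative,
         alpha = alpha, sided = sided, power = power,
         accrual = accrual, followup = followup, dropout_rate = dropout_rate,
         nim = if (!is.null(nim)) nim_value(nim),
         hr = hr,
         events_exact = ev$events_exact, events = ev$events,
         event_probability = p_event, event_hazard = ph,
         patients_exact = pat$patients_exact,
         patients_inflated = pat$patients_inflated,
         patients = pat$patients,
         superiority_null = control, ni_null = ni_null),
    class = "onearm_design")
}

#' @export
print.onearm_design <- function(x, ...) {
  cat("Single-arm exponential time-to-event design\n\n")
  cat(sprintf("  control:       median %s months (hazard %.3g/month)\n",
              format(signif(x$control$median, 4)), x$control$hazard))
  cat(sprintf("  alternative:   median %s months (hazard %.3g/month)\n",
              format(signif(x$alternative$median, 4)), x$alternative$hazard))
  cat(sprintf("  hazard ratio:  %.3g\n", x$hr))
  cat(sprintf("  alpha:         %g (%s-sided), power %g\n",
              x$alpha, x$sided, x$power))
  cat(sprintf("  accrual %g m, follow-up %g m, dropout %g%%\n",
              x$accrual, x$followup, 100 * x$dropout_rate))
  cat(sprintf("\n  required events:    %.2f -> %d\n",
              x$events_exact, x$events))
  cat(sprintf("  P(event):           %.3f\n", x$event_probability))
  cat(sprintf("  patients:           %.1f -> %.1f after dropout -> %d\n",
              x$patients_exact, x$patients_inflated, x$patients))
  if (!is.null(x$ni_null)) {
    cat(sprintf("\n  NIM %g: NI null median %s m (hazard %.3g/month)\n",
                x$nim, format(signif(x$ni_null$median, 4)), x$ni_null$hazard))
    cat(sprintf("  superiority null median %s m (hazard %.3g/month)\n",
                format(signif(x$superiority_null$median, 4)),
                x$superiority_null$hazard))
  }
  invisible(x)
}
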