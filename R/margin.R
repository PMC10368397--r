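# Fixed-margin derivation of the non-inferiority margin from a historical
# active-vs-placebo hazard ratio, and construction of the shifted NI null.

#' Historical active-versus-placebo effect
#'
#' Records the hazard ratio (with confidence bounds) observed for the active
#' control against placebo in earlier trials, together with the fraction of
#' that effect the new trial must retain. The loss-direction convention is
#' used internally: the ratio is placebo hazard over active-control hazard,
#' hence greater than 1 when the control works. A benefit-direction ratio
#' (active over placebo, below 1) can be supplied with
#' `direction = "benefit"`; point estimate and CI bounds are then inverted
#' and the bounds swapped.
#'
#' @param hr Point estimate of the historical hazard ratio.
#' @param ci_lower,ci_upper Confidence bounds of the historical ratio
#'   (conventionally 95%).
#' @param retention Fraction of the historical effect to retain, between 0 and 1.
#'   Defaults to 0.5, the usual "retain at least half the effect" rule.
#' @param direction `"loss"` (ratio > 1, default) or `"benefit"` (ratio < 1).
#' @return An object of class `"historical_effect"`.
#' @examples
#' historical_effect(2.4, 1.44, 3.56)
#' # same effect quoted in the benefit direction:
#' historical_effect(1/2.4, 1/3.56, 1/1.44, direction = "benefit")
#' @export
historical_effect <- function(hr, ci_lower, ci_upper, retention = 0.5,
                              direction = c("loss", "benefit")) {
  direction <- match.arg(direction)
  for (v in list(hr = hr, ci_lower = ci_lower, ci_upper = ci_upper)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("'hr', 'ci_lower' and 'ci_upper' must be single positive numbers",
           call. = FALSE)
  }
  if (direction == "benefit") {
    tmp <- 1 / ci_lower
    ci_lower <- 1 / ci_upper
    ci_upper <- tmp
    hr <- 1 / hr
  }
  if (!is.numeric(retention) || length(retention) != 1L || is.na(retention) ||
      retention < 0 || retention > 1)
    stop("'retention' must be a fraction in [0, 1]", call. = FALSE)
  if (ci_lower < 1)
    stop("historical CI lower bound is below 1: the historical effect must ",
         "favor the active control for a non-inferiority margin to exist",
         call. = FALSE)
  if (!(ci_lower <= hr && hr <= ci_upper))
    stop("'ci_lower' <= 'hr' <= 'ci_upper' must hold", call. = FALSE)
  structure(list(hr = hr, ci_lower = ci_lower, ci_upper = ci_upper,
                 retention = retention),
            class = "historical_effect")
}

#' @export
print.historical_effect <- function(x, ...) {
  cat(sprintf("Historical effect: HR %g (CI %g-%g), retention %g\n",
              signif(x$hr, 4), signif(x$ci_lower, 4), signif(x$ci_upper, 4),
              x$retention))
  invisible(x)
}

#' Non-inferiority margin by the fixed-margin method
#'
#' Applies the fixed-margin (95-95) rule: take the lower confidence bound
#' \eqn{L} of the historical active-vs-placebo hazard ratio — the most
#' pessimistic estimate of the control's effect — and discount it so a
#' fraction \eqn{f} of that (log-scale) effect is retained:
#' \deqn{\mathrm{NIM} = L^{\,1-f}.}
#' The margin is a hazard-ratio multiplier at least 1: the new treatment's
#' hazard may exceed the historical control's by at most this factor. Full
#' retention (`retention = 1`) gives a unit margin; zero retention allows the
#' entire lower-bound effect.
#'
#' @param effect A [historical_effect()], or the numeric CI lower bound.
#' @param retention Retention fraction; read from `effect` when it is a
#'   `historical_effect`, otherwise defaults to 0.5.
#' @return An object of class `"ni_margin"` with elements `nim`, `ci_lower`,
#'   `retention`.
#' @examples
#' fixed_margin_nim(historical_effect(2.4, 1.44, 3.56, retention = 0.5))
#' fixed_margin_nim(1.44)          # same margin from the bound alone: 1.2
#' @export
fixed_margin_nim <- function(effect, retention = NULL) {
  if (inherits(effect, "historical_effect")) {
    ci_lower <- effect$ci_lower
    if (is.null(retention)) retention <- effect$retention
  } else if (is.numeric(effect) && length(effect) == 1L) {
    ci_lower <- effect
    if (is.null(retention)) retention <- 0.5
    if (is.na(ci_lower) || ci_lower < 1)
      stop("historical CI lower bound is below 1: the historical effect must ",
           "favor the active control for a non-inferiority margin to exist",
           call. = FALSE)
  } else {
    stop("'effect' must be a historical_effect or a numeric CI lower bound",
         call. = FALSE)
  }
  if (!is.numeric(retention) || length(retention) != 1L || is.na(retention) ||
      retention < 0 || retention > 1)
    stop("'retention' must be a fraction in [0, 1]", call. = FALSE)
  structure(list(nim = ci_lower^(1 - retention),
                 ci_lower = ci_lower, retention = retention),
            class = "ni_margin")
}

#' @export
print.ni_margin <- function(x, ...) {
  cat(sprintf(
    "Non-inferiority margin: %g (fixed-margin method, CI lower bound %g, retention %g)\n",
    signif(x$nim, 4), signif(x$ci_lower, 4), x$retention))
  invisible(x)
}

# Accept an ni_margin object or a bare ratio >= 1 wherever a margin is needed.
nim_value <- function(nim) {
  if (inherits(nim, "ni_margin")) nim <- nim$nim
  if (!is.numeric(nim) || length(nim) != 1L || is.na(nim) || nim < 1)
    stop("'nim' must be an ni_margin or a single ratio >= 1", call. = FALSE)
  nim
}

#' Shift a control survival summary by a non-inferiority margin
#'
#' The NI null divides the control median by the margin, or equivalently
#' multiplies the control hazard by it: the null now states that the treatment
#' is worse than the control by more than the tolerable margin. With a unit
#' margin the shifted null coincides with the superiority null; with any
#' margin above 1 the shifted median lies below the control median and the
#' shifted hazard above the control hazard, which is what makes the NI test
#' uniformly easier to reject than the superiority test on the same data.
#'
#' @param control A [surv_summary()] (or a bare control median in months).
#' @param nim An [fixed_margin_nim()] result or a ratio >= 1.
#' @return A `surv_summary` describing the non-inferiority boundary.
#' @examples
#' shifted_null(surv_summary(median = 12), 1.2)   # median 10, hazard 0.0693
#' @export
shifted_null <- function(control, nim) {
  control <- as_surv_summary(control)
  nim <- nim_value(nim)
  if (control$anchor == "landmark")
    new_surv_summary(control$hazard * nim, "landmark",
                     landmark_rate = control$landmark_rate^nim,
                     landmark_time = control$landmark_time)
  else
    new_surv_summary(control$hazard * nim, "median")
}
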