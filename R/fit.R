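# One-sample exponential maximum-likelihood fit of right-censored
# time-to-event data: the analysis engine behind the final-analysis tests.

#' Fit a one-sample exponential survival model
#'
#' Maximum-likelihood fit of a constant-hazard (exponential) model to
#' right-censored times: with \eqn{d} events over a total exposure
#' \eqn{E = \sum t_i} the MLE is \eqn{\hat\lambda = d/E}, and the fitted
#' median is \eqn{\ln 2 / \hat\lambda}. The log-hazard estimate has
#' asymptotic variance \eqn{1/d}, which is what the one-sided tests in
#' [exp_hazard_test()] and [dual_test()] rely on.
#'
#' The default method takes a time vector and an event indicator; the formula
#' method takes `survival::Surv(time, event) ~ 1` with a data frame, the
#' idiom of the survival modelling functions.
#'
#' @param x A numeric vector of observed times (months, positive), or a
#'   model formula with a right-censored [survival::Surv()] response and
#'   intercept-only right-hand side.
#' @param event Integer event indicator (1 = event, 0 = censored), recycled
#'   to 1 if omitted (fully observed data).
#' @param entry Optional entry times (months from study start), used only to
#'   validate that no observation outlasts the study window.
#' @param study_duration Optional total study duration; with `entry` given,
#'   each observed time must be at most `study_duration - entry`.
#' @param data Data frame for the formula method.
#' @param ... Passed between methods.
#' @return An object of class `"onearm_fit"` with elements `n`, `events`,
#'   `exposure`, `hazard`, `median`, `loglik`, `time`, `status`, `call`.
#' @examples
#' fit <- onearm_fit(c(3, 8, 14, 20, 20), event = c(1, 1, 1, 0, 0))
#' fit
#' coef(fit)
#' confint(fit)
#' predict(fit, times = c(6, 12, 24))
#' @export
onearm_fit <- function(x, ...) UseMethod("onearm_fit")

#' @rdname onearm_fit
#' @export
onearm_fit.formula <- function(x, data = parent.frame(), ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right")
    stop("the formula response must be a right-censored survival::Surv object",
         call. = FALSE)
  out <- onearm_fit.default(as.numeric(y[, "time"]),
                            as.integer(y[, "status"]), ...)
  out$call <- match.call()
  out
}

#' @rdname onearm_fit
#' @export
onearm_fit.default <- function(x, event = NULL, entry = NULL,
                               study_duration = NULL, ...) {
  time <- as.numeric(x)
  if (length(time) < 1L || anyNA(time) || any(time <= 0))
    stop("observed times must be positive and free of NA", call. = FALSE)
  if (is.null(event)) event <- rep(1L, length(time))
  event <- as.integer(event)
  if (length(event) != length(time) || anyNA(event) ||
      !all(event %in% c(0L, 1L)))
    stop("'event' must be 0/1 with one entry per time", call. = FALSE)
  if (!is.null(entry)) {
    entry <- as.numeric(entry)
    if (length(entry) != length(time) || anyNA(entry) || any(entry < 0))
      stop("'entry' must be non-negative with one entry time per record",
           call. = FALSE)
    if (!is.null(study_duration)) {
      bad <- which(time > study_duration - entry + 1e-8)
      if (length(bad))
        stop("records outlast the study window (rows ",
             paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  d <- sum(event)
  if (d == 0L)
    stop("no events observed: the exponential hazard is not estimable; ",
         "use the nonparametric path (km_decision) instead", call. = FALSE)
  exposure <- sum(time)
  hazard <- d / exposure
  structure(
    list(n = length(time), events = d, exposure = exposure,
         hazard = hazard, median = log(2) / hazard,
         loglik = d * log(hazard) - hazard * exposure,
         time = time, status = event, call = match.call()),
    class = "onearm_fit")
}

#' @export
print.onearm_fit <- function(x, digits = 4, ...) {
  cat("One-sample exponential fit\n")
  cat(sprintf("  n = %d, events = %d, exposure = %s person-months\n",
              x$n, x$events, format(signif(x$exposure, digits))))
  cat(sprintf("  hazard = %s per month, median = %s months\n",
              format(signif(x$hazard, digits)),
              format(signif(x$median, digits))))
  invisible(x)
}

#' @export
summary.onearm_fit <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  structure(list(fit = object, level = level, ci = ci),
            class = "summary.onearm_fit")
}

#' @export
print.summary.onearm_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  %g%% CI hazard: %s-%s, median: %s-%s\n",
              100 * x$level,
              format(signif(x$ci["hazard", 1], digits)),
              format(signif(x$ci["hazard", 2], digits)),
              format(signif(x$ci["median", 1], digits)),
              format(signif(x$ci["median", 2], digits))))
  invisible(x)
}

#' @export
coef.onearm_fit <- function(object, ...) c(hazard = object$hazard)

#' @export
logLik.onearm_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n, class = "logLik")
}

#' Confidence interval for the fitted hazard and median
#'
#' Wald interval on the log-hazard scale, \eqn{\ln\hat\lambda \pm
#' z_{1-\alpha/2}/\sqrt{d}}, exponentiated; the median interval is the
#' reciprocal transform (lower hazard bound gives the upper median bound).
#'
#' @param object An [onearm_fit()] result.
#' @param parm Ignored; both rows are always returned.
#' @param level Confidence level.
#' @param ... Unused.
#' @return A 2 x 2 matrix with rows `hazard` and `median`.
#' @export
confint.onearm_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- 1 / sqrt(object$events)
  haz <- exp(log(object$hazard) + c(-1, 1) * z * se)
  out <- rbind(hazard = haz, median = rev(log(2) / haz))
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' @export
predict.onearm_fit <- function(object, times,
                               type = c("survival", "cumhaz"), ...) {
  type <- match.arg(type)
  if (missing(times))
    stop("'times' (months) must be supplied", call. = FALSE)
  ch <- object$hazard * times
  switch(type, survival = exp(-ch), cumhaz = ch)
}

#' @export
residuals.onearm_fit <- function(object,
                                 type = c("martingale", "coxsnell"), ...) {
  type <- match.arg(type)
  cs <- object$hazard * object$time   # Cox-Snell: cumulative hazard at exit
  switch(type, coxsnell = cs, martingale = object$status - cs)
}

#' @export
simulate.onearm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(
    matrix(stats::rexp(object$n * nsim, rate = object$hazard),
           nrow = object$n,
           dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
  out
}

#' @export
plot.onearm_fit <- function(x, xlab = "Months", ylab = "Survival", ...) {
  sf <- survival::survfit(survival::Surv(x$time, x$status) ~ 1)
  plot(sf, conf.int = TRUE, xlab = xlab, ylab = ylab, ...)
  grid <- seq(0, max(x$time), length.out = 200)
  graphics::lines(grid, exp(-x$hazard * grid), col = 2, lwd = 2)
  graphics::legend("topright", bty = "n", lwd = c(1, 2), col = c(1, 2),
                   legend = c("Kaplan-Meier", "exponential fit"))
  invisible(x)
}
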