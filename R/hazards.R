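# Conversions between survival-scale anchors (medians, landmark survival
# fractions) and constant hazards, under the exponential model.

#' Convert a median survival time to a constant hazard rate
#'
#' Under an exponential event-time model the survival function is
#' \eqn{S(t) = e^{-\lambda t}}, so the hazard implied by a median \eqn{m} is
#' \eqn{\lambda = \ln(2)/m}.
#'
#' @param median Median survival time (months). Must be positive; `Inf` is
#'   accepted and maps to a zero hazard.
#' @return Hazard rate per month.
#' @seealso [median_from_hazard()], [hazard_from_landmark()]
#' @examples
#' hazard_from_median(12)   # 0.0578, often reported as 0.058
#' hazard_from_median(18)   # 0.0385
#' @export
hazard_from_median <- function(median) {
  if (!is.numeric(median) || length(median) != 1L || is.na(median) || median <= 0)
    stop("'median' must be a single positive number", call. = FALSE)
  log(2) / median
}

#' Convert a constant hazard rate to a median survival time
#'
#' Inverse of [hazard_from_median()]: \eqn{m = \ln(2)/\lambda}. A zero hazard
#' maps to an infinite median.
#'
#' @param hazard Hazard rate per month (non-negative).
#' @return Median survival time in months.
#' @export
median_from_hazard <- function(hazard) {
  if (!is.numeric(hazard) || length(hazard) != 1L || is.na(hazard) || hazard < 0)
    stop("'hazard' must be a single non-negative number", call. = FALSE)
  if (hazard == 0) return(Inf)
  log(2) / hazard
}

#' Convert a landmark survival fraction to a constant hazard rate
#'
#' For a survival fraction \eqn{S(t^*)} observed at landmark time \eqn{t^*},
#' the exponential model gives \eqn{\lambda = -\ln S(t^*) / t^*}. This is how
#' disease-free-survival rates (which rarely cross 50%, so the median is not
#' estimable) are brought onto the hazard scale in adjuvant settings.
#'
#' @param rate Survival fraction in (0, 1] at the landmark.
#' @param landmark Landmark time (months), positive.
#' @return Hazard rate per month; 0 when `rate == 1`.
#' @examples
#' hazard_from_landmark(0.95, 60)  # 0.000855, reported as 0.0009
#' hazard_from_landmark(0.92, 60)  # 0.00139, reported as 0.0014
#' @export
hazard_from_landmark <- function(rate, landmark) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate <= 0 || rate > 1)
    stop("'rate' must be a single probability in (0, 1]", call. = FALSE)
  if (!is.numeric(landmark) || length(landmark) != 1L || is.na(landmark) ||
      landmark <= 0)
    stop("'landmark' must be a single positive time", call. = FALSE)
  -log(rate) / landmark
}

new_surv_summary <- function(hazard, anchor,
                             landmark_rate = NULL, landmark_time = NULL) {
  structure(
    list(median = median_from_hazard(hazard),
         hazard = hazard,
         landmark_rate = landmark_rate,
         landmark_time = landmark_time,
         anchor = anchor),
    class = "surv_summary")
}

#' Summarise a survival scale by its median or a landmark rate
#'
#' A `surv_summary` anchors a survival distribution by exactly one of a median
#' survival time or a survival fraction at a landmark time, and carries the
#' constant (exponential) hazard those imply. It is the common currency for the
#' historical control and the alternative in design and analysis: null
#' hypotheses are stated on both the median and the hazard scale, and the two
#' are kept mutually consistent (\eqn{m = \ln 2 / \lambda}).
#'
#' @param median Median survival time in months. Supply either this or the
#'   landmark pair, never both.
#' @param landmark_rate Survival fraction in (0, 1] at `landmark_time`.
#' @param landmark_time Landmark time in months.
#' @return An object of class `"surv_summary"` with elements `median`,
#'   `hazard`, `landmark_rate`, `landmark_time`, `anchor`.
#' @examples
#' surv_summary(median = 12)
#' surv_summary(landmark_rate = 0.95, landmark_time = 60)
#' @export
surv_summary <- function(median = NULL, landmark_rate = NULL,
                         landmark_time = NULL) {
  has_median <- !is.null(median)
  has_landmark <- !is.null(landmark_rate) || !is.null(landmark_time)
  if (has_median == has_landmark)
    stop("supply exactly one of 'median' or ('landmark_rate', 'landmark_time')",
         call. = FALSE)
  if (has_median)
    return(new_surv_summary(hazard_from_median(median), "median"))
  if (is.null(landmark_rate) || is.null(landmark_time))
    stop("'landmark_rate' and 'landmark_time' must be supplied together",
         call. = FALSE)
  new_surv_summary(hazard_from_landmark(landmark_rate, landmark_time),
                   "landmark", landmark_rate, landmark_time)
}

#' @export
print.surv_summary <- function(x, digits = 4, ...) {
  cat("Exponential survival summary (months)\n")
  if (x$anchor == "landmark")
    cat(sprintf("  landmark: S(%g) = %g\n", x$landmark_time, x$landmark_rate))
  cat(sprintf("  median:   %s\n",
              if (is.finite(x$median)) format(signif(x$median, digits)) else "Inf"))
  cat(sprintf("  hazard:   %s per month\n", format(signif(x$hazard, digits))))
  invisible(x)
}

as_surv_summary <- function(x, what = "control") {
  if (inherits(x, "surv_summary")) return(x)
  if (is.numeric(x) && length(x) == 1L)  # a bare number is read as a median
    return(surv_summary(median = x))
  stop(sprintf("'%s' must be a surv_summary or a single median time", what),
       call. = FALSE)
}
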