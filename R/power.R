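# Precision-to-power translation for longitudinal designs.

#' Convert a mean percent error to the session-difference SD
#'
#' The test-retest percent error is the absolute value of an
#' approximately Normal session difference of relative values; under
#' normality \eqn{E|\Delta| = \sigma\sqrt{2/\pi}}, so the SD is the mean
#' percent error times \eqn{\sqrt{\pi/2} \approx 1.2533}.
#'
#' @param percentErrorMean mean percent error (>= 0, vectorised).
#' @return SD of the session difference of relative values, in percent.
#' @examples
#' errorToSD(2.5)  # 3.1333
#' @export
errorToSD <- function(percentErrorMean) {
  if (any(percentErrorMean < 0))
    stop("percent error must be >= 0", call. = FALSE)
  percentErrorMean * sqrt(pi / 2)
}

#' Required sample size to detect longitudinal change
#'
#' Normal-approximation power calculation for detecting a mean change
#' (one-group) or a group difference in change (two-group, per-group n)
#' between two timepoints, when the only noise is morphometric
#' measurement error. The per-timepoint SD comes from the mean percent
#' error via [errorToSD()] divided by \eqn{\sqrt 2} (the session
#' difference of two timepoints has variance \eqn{2\sigma_{tp}^2}), so
#' the change score has SD \eqn{\sigma_{\Delta} =
#' \sqrt{2}\,\sigma_{tp}}. Then
#' \deqn{n = \lceil (z_{1-\alpha/2} + z_{power})^2\, m\,
#'       \sigma_\Delta^2 / (rate \cdot years)^2 \rceil}
#' with design multiplier \eqn{m = 1} (one-group) or 2 (two-group).
#' An optional between-subject SD of change rates (percent per follow-up,
#' biological heterogeneity) adds to \eqn{\sigma_\Delta^2}; the default 0
#' quantifies the measurement-error floor only. z-formulas slightly
#' understate n for n < 10 relative to a t-based calculation.
#'
#' @param annualChange true annual change, percent per year (> 0).
#' @param perTimepointError mean percent error of one timepoint's
#'   (possibly pooled) estimate.
#' @param followUpYears follow-up duration in years.
#' @param alpha two-sided type-I error rate.
#' @param power target power.
#' @param design "one-group" or "two-group".
#' @param sdBiological between-subject SD of total change over follow-up,
#'   in percent (default 0).
#' @return required subjects (per group), integer.
#' @examples
#' requiredN(annualChange = 3, perTimepointError = 2.5)
#' @export
requiredN <- function(annualChange, perTimepointError,
                      followUpYears = 1, alpha = 0.05, power = 0.80,
                      design = c("one-group", "two-group"),
                      sdBiological = 0) {
  design <- match.arg(design)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  if (followUpYears <= 0)
    stop("follow-up must be > 0", call. = FALSE)
  effect <- annualChange * followUpYears
  if (any(effect <= 0))
    stop("effect (annualChange x followUpYears) must be > 0",
         call. = FALSE)
  sigmaTp <- errorToSD(perTimepointError) / sqrt(2)
  sigmaChange2 <- 2 * sigmaTp^2 + sdBiological^2
  mult <- if (design == "two-group") 2 else 1
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling(z^2 * mult * sigmaChange2 / effect^2))
}

#' Best pooling depth under a scan-time budget
#'
#' Given a total per-session scan-time budget, finds the number of
#' same-protocol scans that fit and the expected pooled error under the
#' equicorrelation model ([equicorrPooledSD()] scaling of the single-scan
#' error). With any \code{rho < 1} expected error is non-increasing in
#' the budget; with \code{rho = 1} pooling gives no benefit.
#'
#' @param budgetSeconds per-session scan-time budget.
#' @param rho inter-scan error correlation in [0, 1].
#' @param e1 single-scan mean percent error.
#' @param scanType,resolution scan protocol to repeat (default CS 1.0 mm).
#' @return list with \code{k}, \code{expectedError} (percent),
#'   \code{durationUsed} (seconds).
#' @examples
#' precisionBudget(312, rho = 0, e1 = 3.01)  # k = 4, 1.505%
#' @export
precisionBudget <- function(budgetSeconds, rho, e1, scanType = "CS",
                            resolution = 1.0) {
  dur <- scanDuration(scanType, resolution)
  if (budgetSeconds < dur)
    stop("budget (", budgetSeconds, " s) below one ", scanType, " ",
         resolution, " mm scan (", dur, " s)", call. = FALSE)
  k <- as.integer(floor(budgetSeconds / dur))
  list(k = k,
       expectedError = e1 * equicorrPooledSD(1, rho, k),
       durationUsed = k * dur)
}

#' Required-n over a grid of errors and change rates
#'
#' Convenience table for study planning: [requiredN()] evaluated over all
#' combinations of per-timepoint errors and annual change rates.
#'
#' @param errors per-timepoint mean percent errors.
#' @param annualChanges annual change rates, percent per year.
#' @param ... passed to [requiredN()].
#' @return data.frame with columns \code{per_timepoint_error_pct},
#'   \code{annual_change_pct}, \code{n}.
#' @export
requiredNGrid <- function(errors, annualChanges, ...) {
  grid <- expand.grid(per_timepoint_error_pct = errors,
                      annual_change_pct = annualChanges)
  grid$n <- mapply(function(e, a)
    requiredN(annualChange = a, perTimepointError = e, ...),
    grid$per_timepoint_error_pct, grid$annual_change_pct)
  grid
}
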