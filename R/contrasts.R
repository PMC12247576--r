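# Paired contrasts between pooling schemes.

#' Paired comparison of two pooling schemes
#'
#' For each measure, forms the per-subject difference in percent error
#' (reference minus candidate; positive favours the candidate), reports
#' the mean delta, the percent reduction relative to the reference
#' measure's mean error, and a two-sided paired test across subjects
#' (Wilcoxon signed-rank by default, robust to the skewed non-negative
#' error distribution; paired t-test as an option). Summary fractions are
#' computed over measures, counting zero deltas as half improved.
#' P-values are uncorrected, with an optional Benjamini-Hochberg column.
#'
#' @param reference,candidate data.frames from [schemeErrors()] over the
#'   same subjects and measures.
#' @param alpha significance level for the summary fraction.
#' @param method "wilcoxon" or "ttest".
#' @param adjust also report BH-adjusted p-values (column
#'   \code{p_adjusted}; the summary fraction always uses raw p).
#' @return a \linkS4class{SchemeContrast}.
#' @examples
#' \dontrun{compareSchemes(schemeErrors(me, adniScheme()),
#'                         schemeErrors(me, csPoolingScheme(4)))}
#' @export
compareSchemes <- function(reference, candidate, alpha = 0.05,
                           method = c("wilcoxon", "ttest"),
                           adjust = FALSE) {
  method <- match.arg(method)
  keyR <- paste(reference$subject_id, reference$measure, sep = "\r")
  keyC <- paste(candidate$subject_id, candidate$measure, sep = "\r")
  if (!setequal(keyR, keyC))
    stop("schemes cover different subject x measure sets", call. = FALSE)
  candidate <- candidate[match(keyR, keyC), ]
  d <- reference$percent_error - candidate$percent_error
  measures <- unique(reference$measure)
  res <- lapply(split(seq_along(d), reference$measure), function(ii) {
    di <- d[ii]
    n <- length(di)
    if (n < 2L) {
      warning("fewer than 2 paired subjects; test skipped for measure ",
              reference$measure[ii[1]], call. = FALSE)
      p <- NA_real_
    } else if (all(di == 0)) {
      p <- 1
    } else {
      p <- suppressWarnings(if (method == "wilcoxon")
        wilcox.test(reference$percent_error[ii],
                    candidate$percent_error[ii],
                    paired = TRUE, exact = n <= 25,
                    correct = TRUE)$p.value
        else t.test(reference$percent_error[ii],
                    candidate$percent_error[ii], paired = TRUE)$p.value)
    }
    data.frame(measure = reference$measure[ii[1]],
               delta = mean(di),
               percent_reduction =
                 100 * mean(di) / mean(reference$percent_error[ii]),
               p_value = p, n_subjects = n)
  })
  per <- do.call(rbind, res)
  per <- per[match(measures, per$measure), ]
  rownames(per) <- NULL
  if (adjust) per$p_adjusted <- stats::p.adjust(per$p_value, "BH")
  nz <- sum(per$delta == 0)
  if (nz > 0)
    message(nz, " tied measure(s) counted as half-improved")
  refMean <- mean(tapply(reference$percent_error, reference$measure,
                         mean))
  new("SchemeContrast",
      reference = reference$scheme[1], candidate = candidate$scheme[1],
      perMeasure = per,
      meanDelta = mean(per$delta),
      meanReduction = 100 * mean(per$delta) / refMean,
      fractionImproved =
        100 * (sum(per$delta > 0) + 0.5 * nz) / nrow(per),
      fractionSignificant =
        100 * mean(per$p_value < alpha, na.rm = TRUE),
      alpha = alpha)
}

#' @export
setMethod("show", "SchemeContrast", function(object) {
  cat("SchemeContrast:", object@reference, "(reference) vs",
      object@candidate, "(candidate)\n")
  cat(sprintf("  mean delta %+.3f pct points (%.1f%% reduction)\n",
              object@meanDelta, object@meanReduction))
  cat(sprintf("  measures improved: %.1f%%; significant at alpha=%.2g: %.1f%% (n=%d measures)\n",
              object@fractionImproved, object@alpha,
              object@fractionSignificant, nrow(object@perMeasure)))
})

#' Pooling curve: first-k CS schemes against a reference scan
#'
#' Computes error summaries for the first-k CS 1.0 mm pooling schemes,
#' the square-root-law overlay anchored at the single-scan error, and the
#' paired contrast of every scheme against the reference.
#'
#' @param x a \linkS4class{MorphoExperiment}.
#' @param ks pooling depths (default 1, 2, 4, 8).
#' @param reference reference \linkS4class{PoolingScheme} (default
#'   [adniScheme()]; pass NULL to skip the contrasts).
#' @param alpha significance level for contrasts.
#' @return list with \code{summary}: data.frame (k, scheme, mean error,
#'   SD, expected \eqn{e_1/\sqrt{k}}, scan seconds, and contrast columns
#'   when a reference is given); \code{contrasts}: list of
#'   \linkS4class{SchemeContrast}; \code{errors}: list of error-record
#'   data.frames keyed by scheme label.
#' @export
poolingCurve <- function(x, ks = c(1L, 2L, 4L, 8L),
                         reference = adniScheme(), alpha = 0.05) {
  schemes <- lapply(ks, csPoolingScheme)
  errs <- lapply(schemes, function(s) schemeErrors(x, s))
  names(errs) <- vapply(schemes, function(s) s@label, character(1))
  sums <- lapply(errs, summarizeErrors)
  e1 <- sums[[which(ks == min(ks))]]$mean_pct
  cs1Dur <- scanDuration("CS", 1.0)
  out <- data.frame(
    k = ks,
    scheme = names(errs),
    mean_pct = vapply(sums, function(s) s$mean_pct, numeric(1)),
    sd_pct = vapply(sums, function(s) s$sd_pct, numeric(1)),
    expected_sqrt_pct = expectedSqrtCurve(e1, ks / min(ks)),
    duration_s = ks * cs1Dur,
    row.names = NULL)
  contrasts <- NULL
  if (!is.null(reference)) {
    refErr <- schemeErrors(x, reference)
    refSum <- summarizeErrors(refErr)
    contrasts <- lapply(errs, function(e)
      compareSchemes(refErr, e, alpha = alpha))
    out$reference_mean_pct <- refSum$mean_pct
    out$delta_vs_reference <-
      vapply(contrasts, function(cc) cc@meanDelta, numeric(1))
    out$reduction_vs_reference_pct <-
      vapply(contrasts, function(cc) cc@meanReduction, numeric(1))
    out$fraction_improved_pct <-
      vapply(contrasts, function(cc) cc@fractionImproved, numeric(1))
    out$fraction_significant_pct <-
      vapply(contrasts, function(cc) cc@fractionSignificant, numeric(1))
  }
  list(summary = out, contrasts = contrasts, errors = errs)
}

#' Break moderator contrast
#'
#' Compares pooled pairs acquired within one head positioning (CS 1.0 mm
#' scans 1 and 2, the reference) against pairs spanning the repositioning
#' break (scans 1 and 5, the candidate). A positive mean delta means the
#' break pair had lower error.
#'
#' @param x a \linkS4class{MorphoExperiment} with CS 1.0 mm type indices
#'   1, 2 and 5.
#' @param alpha significance level.
#' @return a \linkS4class{SchemeContrast}.
#' @export
breakContrast <- function(x, alpha = 0.05) {
  compareSchemes(schemeErrors(x, serialPairScheme()),
                 schemeErrors(x, breakPairScheme()), alpha = alpha)
}

#' Multi-resolution moderator contrast
#'
#' Compares pooling four CS 1.0 mm scans (reference) against pooling one
#' CS scan each at 0.8, 0.9, 1.1 and 1.2 mm (candidate). A positive mean
#' delta means multi-resolution pooling had lower error.
#'
#' @param x a \linkS4class{MorphoExperiment} with CS 1.0 mm indices 1-4
#'   and one scan at each non-1.0 mm resolution.
#' @param alpha significance level.
#' @return a \linkS4class{SchemeContrast}.
#' @export
multiresContrast <- function(x, alpha = 0.05) {
  compareSchemes(schemeErrors(x, csPoolingScheme(4)),
                 schemeErrors(x, multiresScheme()), alpha = alpha)
}

#' Per-group error summaries and reductions
#'
#' Summarises a scheme's percent errors within each participant group
#' (two-stage aggregation within group) and, when a reference scheme's
#' records are supplied, the per-group mean percent reduction relative to
#' that reference.
#'
#' @param records data.frame from [schemeErrors()].
#' @param reference optional reference records over the same subjects.
#' @return data.frame: one row per group with mean/SD/SEM/n and, if a
#'   reference was given, \code{reference_mean_pct} and
#'   \code{reduction_pct}.
#' @export
subgroupSummaries <- function(records, reference = NULL) {
  out <- summarizeErrors(records, grouping = "group")
  if (!is.null(reference)) {
    refSum <- summarizeErrors(reference, grouping = "group")
    i <- match(out$level, refSum$level)
    out$reference_mean_pct <- refSum$mean_pct[i]
    out$reduction_pct <-
      100 * (out$reference_mean_pct - out$mean_pct) /
      out$reference_mean_pct
  }
  out
}
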