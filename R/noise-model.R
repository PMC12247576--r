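# Noise model construction and its implied correlation structure.

#' Construct a NoiseModel
#'
#' See \linkS4class{NoiseModel} for the generative model. All error SDs are
#' on the fraction scale (an SD of 0.02 means 2% relative error).
#'
#' @param regionMeans data.frame (\code{structure}, \code{hemisphere},
#'   \code{measure_class}, \code{mean}); \code{structure}/\code{hemisphere}
#'   may be NA to match any. Defaults to [defaultRegionMeans()].
#' @param subjectCV between-subject CV of true values.
#' @param groupShift data.frame (\code{group}, \code{measure_class},
#'   \code{structure_pattern}, \code{shift}); default [defaultGroupShift()].
#' @param sigmaSession,sigmaBlock,sigmaScan,sigmaScanADNI error-component
#'   SDs (fractions).
#' @param resolutionBias,resolutionNoiseScale named numeric vectors keyed
#'   by resolution in mm; unlisted resolutions default to 1.
#' @param groupNoiseScale named numeric, per-group multiplier on all error
#'   SDs.
#' @param seed default master seed for [simulateStudy()].
#' @return a validated \linkS4class{NoiseModel}.
#' @seealso [defaultNoiseModel()]
#' @export
noiseModel <- function(regionMeans = defaultRegionMeans(),
                       subjectCV = 0.1,
                       groupShift = defaultGroupShift(),
                       sigmaSession = 0, sigmaBlock = 0,
                       sigmaScan = 0, sigmaScanADNI = sigmaScan,
                       resolutionBias = c(`1` = 1),
                       resolutionNoiseScale = c(`1` = 1),
                       groupNoiseScale = c(`YA-CU` = 1, `OA-CU` = 1,
                                           `MCI/AD` = 1),
                       seed = 1L) {
  new("NoiseModel", regionMeans = regionMeans, subjectCV = subjectCV,
      groupShift = groupShift, sigmaSession = sigmaSession,
      sigmaBlock = sigmaBlock, sigmaScan = sigmaScan,
      sigmaScanADNI = sigmaScanADNI, resolutionBias = resolutionBias,
      resolutionNoiseScale = resolutionNoiseScale,
      groupNoiseScale = groupNoiseScale, seed = as.integer(seed))
}

#' Default region means for synthetic true values
#'
#' Plausible adult values in native units: per-hemisphere subcortical
#' volumes in mm3, 2.5 mm cortical thickness and a GWR of 1.25 for every
#' parcel. Percent error is scale-invariant, so downstream precision
#' results do not depend on these magnitudes.
#'
#' @return data.frame usable as the \code{regionMeans} slot.
#' @export
defaultRegionMeans <- function() {
  vol <- data.frame(
    structure = .ASEG_STRUCTURES,
    hemisphere = NA_character_,
    measure_class = "volume",
    mean = c(1700, 600, 1800, 3700, 4200, 5000, 7500, 4000))
  rbind(vol,
        data.frame(structure = NA_character_, hemisphere = NA_character_,
                   measure_class = "thickness", mean = 2.5),
        data.frame(structure = NA_character_, hemisphere = NA_character_,
                   measure_class = "gwr", mean = 1.25))
}

#' Default group-level true-value shifts
#'
#' Placeholder atrophy effects for the MCI/AD group: hippocampal and
#' amygdala volumes reduced 15%, temporal-lobe cortical thickness reduced
#' 8%. These only shift true values between groups; they do not affect
#' percent-error statistics, which are scale-invariant.
#'
#' @return data.frame usable as the \code{groupShift} slot.
#' @export
defaultGroupShift <- function() {
  data.frame(
    group = "MCI/AD",
    measure_class = c("volume", "thickness"),
    structure_pattern = c("^(Hippocampus|Amygdala)$",
                          "temporal|entorhinal|parahippocampal|fusiform"),
    shift = c(-0.15, -0.08))
}

#' Default calibrated noise model
#'
#' Error SDs are calibrated so that, at the default study design, a single
#' CS 1.0 mm scan yields a mean test-retest percent error of about 3.0%
#' and the ADNI scan about 2.9%, with a same-block inter-scan error
#' correlation of \code{rhoSame} (default 0.2) split equally between the
#' session and block components. Under the model the session difference of
#' a single scan's relative value is Normal with SD
#' \eqn{\sqrt{2}\,\sigma_{tot}}, so the mean absolute (percent) error is
#' \eqn{100 \cdot (2/\sqrt{\pi})\,\sigma_{tot}} and the calibration solves
#' \eqn{\sigma_{tot} = (e_1/100) \cdot \sqrt{\pi}/2}.
#'
#' @param e1CS,e1ADNI target single-scan mean percent errors.
#' @param rhoSame target same-block error correlation among CS scans.
#' @param ... passed to [noiseModel()] (e.g. \code{seed}).
#' @return a \linkS4class{NoiseModel}.
#' @examples
#' m <- defaultNoiseModel()
#' impliedRho(m)               # 0.2
#' impliedRho(m, sameBlock = FALSE)
#' @export
defaultNoiseModel <- function(e1CS = 3.0, e1ADNI = 2.9, rhoSame = 0.2, ...) {
  sigmaTot <- (e1CS / 100) * sqrt(pi) / 2
  sigmaShared2 <- rhoSame * sigmaTot^2
  sigmaSession <- sqrt(sigmaShared2 / 2)
  sigmaBlock <- sigmaSession
  sigmaScan <- sqrt(sigmaTot^2 - sigmaShared2)
  sigmaTotADNI <- (e1ADNI / 100) * sqrt(pi) / 2
  if (sigmaTotADNI^2 <= sigmaShared2)
    stop("e1ADNI too small for the shared-component calibration",
         call. = FALSE)
  sigmaScanADNI <- sqrt(sigmaTotADNI^2 - sigmaShared2)
  noiseModel(sigmaSession = sigmaSession, sigmaBlock = sigmaBlock,
             sigmaScan = sigmaScan, sigmaScanADNI = sigmaScanADNI,
             resolutionBias = c(`0.8` = 1, `0.9` = 1, `1` = 1,
                                `1.1` = 1, `1.2` = 1),
             resolutionNoiseScale = c(`0.8` = 1, `0.9` = 1, `1` = 1,
                                      `1.1` = 1, `1.2` = 1),
             ...)
}

#' Implied inter-scan error correlation of a NoiseModel
#'
#' Closed form of the correlation between the relative errors of two scans
#' of the same session: scans in the same block share the session and
#' block components, scans in different blocks share only the session
#' component.
#'
#' @param model a \linkS4class{NoiseModel}.
#' @param sameBlock if TRUE (default) return \eqn{\rho_{same}}, else
#'   \eqn{\rho_{cross}}.
#' @return correlation in [0, 1].
#' @examples
#' m <- noiseModel(sigmaSession = 0.01, sigmaBlock = 0, sigmaScan = 0.02)
#' impliedRho(m)  # 0.0001 / 0.0005 = 0.2
#' @export
setMethod("impliedRho", "NoiseModel", function(model, sameBlock = TRUE) {
  tot <- model@sigmaSession^2 + model@sigmaBlock^2 + model@sigmaScan^2
  if (tot == 0)
    stop("all error SDs are zero: inter-scan correlation is undefined",
         call. = FALSE)
  if (sameBlock) (model@sigmaSession^2 + model@sigmaBlock^2) / tot
  else model@sigmaSession^2 / tot
})

#' @export
setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel\n")
  cat(sprintf("  sigma: session=%.5f block=%.5f scan=%.5f scanADNI=%.5f\n",
              object@sigmaSession, object@sigmaBlock, object@sigmaScan,
              object@sigmaScanADNI))
  tot <- object@sigmaSession^2 + object@sigmaBlock^2 + object@sigmaScan^2
  if (tot > 0)
    cat(sprintf("  implied rho: same-block=%.3f cross-block=%.3f\n",
                impliedRho(object), impliedRho(object, sameBlock = FALSE)))
  cat(sprintf("  subject CV: %.3f; %d region-mean rules, %d group shifts\n",
              object@subjectCV, nrow(object@regionMeans),
              nrow(object@groupShift)))
})
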