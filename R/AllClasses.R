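#' @import methods
#' @importFrom stats rnorm qnorm sd wilcox.test t.test lm coef quantile
#' @importFrom utils read.csv write.csv head
NULL

#' MorphoExperiment: per-scan morphometric estimates
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"value"},
#' with one row per morphometric measure and one column per acquired scan.
#' Row metadata carries the measure key (\code{structure},
#' \code{hemisphere}, \code{measure_class}, \code{units}); column metadata
#' carries the scan record (\code{subject_id}, \code{group}, \code{session},
#' \code{scan_type}, \code{resolution_mm}, \code{block}, \code{type_index},
#' \code{order_index}, \code{duration_s}).
#'
#' Validity requires all values finite, volume and thickness values strictly
#' positive, and at most one value per (subject, session, scan, measure) —
#' enforced through unique column identities.
#'
#' @seealso [MorphoExperiment()] for construction from a long table,
#'   [simulateStudy()] for synthetic data, [readLongCsv()] for file input.
#' @export
setClass("MorphoExperiment", contains = "SummarizedExperiment")

.ROWDATA_COLS <- c("structure", "hemisphere", "measure_class", "units")
.COLDATA_COLS <- c("subject_id", "group", "session", "scan_type",
                   "resolution_mm", "block", "type_index", "order_index",
                   "duration_s")
.MEASURE_CLASSES <- c(volume = "mm3", thickness = "mm", gwr = "ratio")
.GROUPS <- c("YA-CU", "OA-CU", "MCI/AD")

setValidity("MorphoExperiment", function(object) {
  msgs <- character()
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(.ROWDATA_COLS %in% colnames(rd)))
    msgs <- c(msgs, paste("rowData must contain:",
                          paste(.ROWDATA_COLS, collapse = ", ")))
  if (!all(.COLDATA_COLS %in% colnames(cd)))
    msgs <- c(msgs, paste("colData must contain:",
                          paste(.COLDATA_COLS, collapse = ", ")))
  if (!"value" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'value' is required")
  if (length(msgs) == 0L) {
    v <- SummarizedExperiment::assay(object, "value")
    if (any(!is.finite(v)))
      msgs <- c(msgs, "all values must be finite")
    pos <- rd$measure_class %in% c("volume", "thickness")
    if (any(pos) && any(v[pos, , drop = FALSE] <= 0))
      msgs <- c(msgs, "volume and thickness values must be > 0")
    bad <- !rd$measure_class %in% names(.MEASURE_CLASSES)
    if (any(bad))
      msgs <- c(msgs, "measure_class must be volume, thickness or gwr")
    exp_units <- unname(.MEASURE_CLASSES[rd$measure_class])
    if (!any(bad) && any(rd$units != exp_units))
      msgs <- c(msgs, "units must match measure_class (mm3/mm/ratio)")
    if (anyDuplicated(colnames(object)))
      msgs <- c(msgs, "duplicate scan columns (subject/session/scan)")
    if (anyDuplicated(rownames(object)))
      msgs <- c(msgs, "duplicate measure rows")
  }
  if (length(msgs)) msgs else TRUE
})

#' NoiseModel: generative parameters for synthetic estimate tables
#'
#' Hierarchical multiplicative error model for per-scan morphometric
#' estimates. A subject's true value is drawn once per measure around a
#' region mean (between-subject coefficient of variation
#' \code{subjectCV}), then each observed scan value multiplies in a
#' session-level, a block-level (head position before/after the
#' mid-session break) and an independent per-scan error, all Normal on
#' the fraction scale, plus a per-resolution bias and noise scale.
#'
#' The shared components imply an equicorrelation structure among the
#' relative errors of scans within a session:
#' \deqn{\rho_{same} = (\sigma_{sess}^2 + \sigma_{block}^2) /
#'       (\sigma_{sess}^2 + \sigma_{block}^2 + \sigma_{scan}^2)}
#' for scans in the same block, and
#' \eqn{\rho_{cross} = \sigma_{sess}^2 / (\sigma_{sess}^2 +
#' \sigma_{block}^2 + \sigma_{scan}^2)} across blocks.
#'
#' @slot regionMeans data.frame with columns \code{structure} (NA = any),
#'   \code{hemisphere} (NA = both), \code{measure_class}, \code{mean};
#'   resolved against a measure registry at simulation time.
#' @slot subjectCV between-subject coefficient of variation of true values.
#' @slot groupShift data.frame with columns \code{group},
#'   \code{measure_class}, \code{structure_pattern} (regex, NA = all) and
#'   \code{shift} (fractional multiplicative shift of the true value).
#' @slot sigmaSession SD of the session-level multiplicative error.
#' @slot sigmaBlock SD of the block-level multiplicative error.
#' @slot sigmaScan SD of the independent per-scan error (CS scans).
#' @slot sigmaScanADNI per-scan error SD for the ADNI scan type.
#' @slot resolutionBias named numeric, multiplicative bias per resolution
#'   (names "0.8", "0.9", "1", "1.1", "1.2").
#' @slot resolutionNoiseScale named numeric, multiplier on sigmaScan per
#'   resolution.
#' @slot groupNoiseScale named numeric, per-group multiplier applied to all
#'   error SDs (default 1 for every group).
#' @slot seed default master seed used when none is passed to
#'   [simulateStudy()].
#' @seealso [defaultNoiseModel()], [impliedRho()], [simulateStudy()]
#' @export
setClass("NoiseModel",
  representation(
    regionMeans = "data.frame",
    subjectCV = "numeric",
    groupShift = "data.frame",
    sigmaSession = "numeric",
    sigmaBlock = "numeric",
    sigmaScan = "numeric",
    sigmaScanADNI = "numeric",
    resolutionBias = "numeric",
    resolutionNoiseScale = "numeric",
    groupNoiseScale = "numeric",
    seed = "integer"
  )
)

setValidity("NoiseModel", function(object) {
  msgs <- character()
  sds <- c(session = object@sigmaSession, block = object@sigmaBlock,
           scan = object@sigmaScan, scan_adni = object@sigmaScanADNI,
           cv = object@subjectCV)
  if (any(!is.finite(sds)) || any(sds < 0))
    msgs <- c(msgs, "all SD fields and subjectCV must be finite and >= 0")
  if (nrow(object@regionMeans) == 0L ||
      any(object@regionMeans$mean <= 0))
    msgs <- c(msgs, "all region means must be > 0")
  if (any(object@resolutionBias <= 0))
    msgs <- c(msgs, "all resolution biases must be > 0")
  if (any(object@resolutionNoiseScale < 0))
    msgs <- c(msgs, "resolution noise scales must be >= 0")
  if (any(object@groupNoiseScale < 0))
    msgs <- c(msgs, "group noise scales must be >= 0")
  tot <- object@sigmaSession^2 + object@sigmaBlock^2 + object@sigmaScan^2
  if (tot > 0) {
    r_same <- (object@sigmaSession^2 + object@sigmaBlock^2) / tot
    r_cross <- object@sigmaSession^2 / tot
    if (r_same < 0 || r_same > 1 || r_cross > r_same)
      msgs <- c(msgs, "implied correlations must satisfy 0 <= rho_cross <= rho_same <= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' StudyDesign: participant groups and the per-session scan plan
#'
#' @slot groups data.frame with columns \code{group} and \code{n}.
#' @slot sessions number of test-retest sessions (default 2).
#' @slot scanPlan data.frame with one row per scan in a session:
#'   \code{scan_type} (ADNI/CS), \code{resolution_mm}, \code{block}
#'   (pre/post), \code{order_index} (acquisition order within the session),
#'   \code{type_index} (index within scan type x resolution, e.g. CS 1.0 mm
#'   scan 5) and \code{duration_s}.
#' @seealso [defaultStudyDesign()]
#' @export
setClass("StudyDesign",
  representation(groups = "data.frame", sessions = "integer",
                 scanPlan = "data.frame")
)

setValidity("StudyDesign", function(object) {
  msgs <- character()
  sp <- object@scanPlan
  need <- c("scan_type", "resolution_mm", "block", "order_index",
            "type_index", "duration_s")
  if (!all(need %in% colnames(sp)))
    msgs <- c(msgs, paste("scanPlan must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(sp$order_index))
      msgs <- c(msgs, "order indices must be unique within a session")
    key <- paste(sp$scan_type, sp$resolution_mm, sp$type_index)
    if (anyDuplicated(key))
      msgs <- c(msgs, "type_index must be unique within scan_type x resolution")
    cs1 <- sp$scan_type == "CS" & sp$resolution_mm == 1.0
    if (any(cs1)) {
      ti <- sort(sp$type_index[cs1])
      if (!identical(ti, seq_along(ti)))
        msgs <- c(msgs, "CS 1.0 mm type_index must be 1..k")
      pre <- sp$type_index[cs1 & sp$block == "pre"]
      post <- sp$type_index[cs1 & sp$block == "post"]
      if (length(pre) && length(post) && max(pre) > min(post))
        msgs <- c(msgs, "CS 1.0 mm pre-break scans must precede post-break indices")
    }
  }
  if (!all(c("group", "n") %in% colnames(object@groups)))
    msgs <- c(msgs, "groups must have columns group, n")
  else if (any(object@groups$n < 0))
    msgs <- c(msgs, "group sizes must be >= 0")
  if (object@sessions < 1L)
    msgs <- c(msgs, "at least one session required")
  if (length(msgs)) msgs else TRUE
})

#' PoolingScheme: which scans within each session are averaged
#'
#' A scheme selects scans by type, resolution, block and type index; the
#' pooled estimate for a subject and session is the arithmetic mean of the
#' selected scans' values. \code{k} is the number of scans the selector is
#' expected to match per session; the selector must match identically in
#' both sessions (checked at pooling time).
#'
#' @slot label scheme name used in outputs.
#' @slot scanType "CS", "ADNI", or NA for any.
#' @slot resolutions numeric vector of resolutions to keep (NA = any).
#' @slot blocks character vector of blocks to keep (NA = any).
#' @slot typeIndex integer vector of type indices to keep, applied within
#'   each selected scan type x resolution (NA = any).
#' @slot k expected number of selected scans per session.
#' @seealso [poolingScheme()], [csPoolingScheme()], [poolEstimates()]
#' @export
setClass("PoolingScheme",
  representation(label = "character", scanType = "character",
                 resolutions = "numeric", blocks = "character",
                 typeIndex = "integer", k = "integer")
)

setValidity("PoolingScheme", function(object) {
  msgs <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msgs <- c(msgs, "label must be a non-empty string")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msgs <- c(msgs, "k must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

#' SchemeContrast: paired comparison between two pooling schemes
#'
#' Per-measure paired deltas (reference error minus candidate error,
#' positive favouring the candidate), percent reductions and two-sided
#' paired test p-values, together with summary fractions over measures.
#'
#' @slot reference,candidate scheme labels.
#' @slot perMeasure data.frame: one row per measure with \code{delta}
#'   (percentage points), \code{percent_reduction}, \code{p_value},
#'   \code{n_subjects}.
#' @slot meanDelta mean per-measure delta (percentage points).
#' @slot meanReduction mean error of reference minus candidate, as percent
#'   of the reference mean error.
#' @slot fractionImproved percent of measures with positive delta (ties
#'   counted half).
#' @slot fractionSignificant percent of measures with p below alpha.
#' @slot alpha significance level used.
#' @seealso [compareSchemes()]
#' @export
setClass("SchemeContrast",
  representation(reference = "character", candidate = "character",
                 perMeasure = "data.frame", meanDelta = "numeric",
                 meanReduction = "numeric", fractionImproved = "numeric",
                 fractionSignificant = "numeric", alpha = "numeric")
)
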