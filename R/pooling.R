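# Pooling schemes, percent error, summaries and closed forms.

#' Construct a PoolingScheme
#'
#' @param label scheme name.
#' @param scanType "CS", "ADNI" or NA (any).
#' @param resolutions resolutions (mm) to keep; NA = any.
#' @param typeIndex type indices to keep (within each scan type x
#'   resolution); NA = any.
#' @param blocks blocks ("pre"/"post") to keep; NA = any.
#' @param k number of scans the selector must match per subject-session.
#' @return a \linkS4class{PoolingScheme}.
#' @seealso [csPoolingScheme()], [adniScheme()], [multiresScheme()],
#'   [breakPairScheme()], [serialPairScheme()]
#' @export
poolingScheme <- function(label, scanType = NA_character_,
                          resolutions = NA_real_,
                          typeIndex = NA_integer_,
                          blocks = NA_character_, k) {
  new("PoolingScheme", label = label, scanType = scanType,
      resolutions = resolutions, blocks = blocks,
      typeIndex = as.integer(typeIndex), k = as.integer(k))
}

#' First-k CS 1.0 mm pooling scheme
#'
#' Pools the first \code{k} CS 1.0 mm scans by type index (the scan labels
#' of the protocol, not acquisition order).
#'
#' @param k number of scans pooled per session.
#' @param typeIndex explicit type indices instead of \code{1:k}.
#' @param label scheme label.
#' @return a \linkS4class{PoolingScheme}.
#' @export
csPoolingScheme <- function(k, typeIndex = seq_len(k),
                            label = sprintf("cs1mm_first_%d", k)) {
  poolingScheme(label, scanType = "CS", resolutions = 1.0,
                typeIndex = typeIndex, k = length(typeIndex))
}

#' @rdname csPoolingScheme
#' @export
adniScheme <- function() {
  poolingScheme("adni", scanType = "ADNI", resolutions = 1.0,
                typeIndex = 1L, k = 1L)
}

#' Moderator schemes: serial pair, break pair, multi-resolution
#'
#' \code{serialPairScheme} pools CS 1.0 mm scans 1 and 2 (same head
#' position); \code{breakPairScheme} pools scans 1 and 5 (one before, one
#' after the repositioning break); \code{multiresScheme} pools the first
#' 0.8, 0.9, 1.1 and 1.2 mm CS scans.
#'
#' @return a \linkS4class{PoolingScheme}.
#' @name moderatorSchemes
#' @export
serialPairScheme <- function() csPoolingScheme(2, typeIndex = c(1L, 2L),
                                               label = "cs_pair_no_break")

#' @rdname moderatorSchemes
#' @export
breakPairScheme <- function() csPoolingScheme(2, typeIndex = c(1L, 5L),
                                              label = "cs_pair_break")

#' @rdname moderatorSchemes
#' @export
multiresScheme <- function() {
  poolingScheme("multires4", scanType = "CS",
                resolutions = c(0.8, 0.9, 1.1, 1.2), typeIndex = 1L,
                k = 4L)
}

.matchScheme <- function(cd, scheme) {
  sel <- rep(TRUE, nrow(cd))
  if (!is.na(scheme@scanType))
    sel <- sel & cd$scan_type == scheme@scanType
  if (!all(is.na(scheme@resolutions)))
    sel <- sel & sapply(cd$resolution_mm, function(r)
      any(abs(r - scheme@resolutions) < 1e-9))
  if (!all(is.na(scheme@blocks)))
    sel <- sel & cd$block %in% scheme@blocks
  if (!all(is.na(scheme@typeIndex)))
    sel <- sel & cd$type_index %in% scheme@typeIndex
  sel
}

#' Pooled estimates under a scheme
#'
#' The pooled estimate is the arithmetic mean of the selected scans'
#' values, per subject x session x measure. Subjects whose sessions do not
#' all contain exactly \code{k} matching scans are dropped with a warning
#' (missing scans are never imputed).
#'
#' @param x a \linkS4class{MorphoExperiment}.
#' @param scheme a \linkS4class{PoolingScheme}.
#' @param ... unused.
#' @return list with \code{value}: measures x (subject, session) matrix of
#'   pooled values; \code{info}: data.frame of subject_id, group, session
#'   per column.
#' @export
setMethod("poolEstimates", signature(x = "MorphoExperiment",
                                     scheme = "PoolingScheme"),
  function(x, scheme, ...) {
    validObject(scheme)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    sel <- .matchScheme(cd, scheme)
    if (!any(sel))
      stop("scheme '", scheme@label, "' selects no scans", call. = FALSE)
    cds <- cd[sel, , drop = FALSE]
    cell <- paste(cds$subject_id, cds$session, sep = "\r")
    cnt <- table(cell)
    perSubj <- tapply(cds$session, cds$subject_id,
                      function(s) length(unique(s)))
    nSess <- max(as.data.frame(cd)$session)
    bySubj <- tapply(cell, cds$subject_id, function(z) {
      tab <- table(z)
      length(tab) == nSess && all(tab == scheme@k)
    })
    keep <- names(bySubj)[bySubj]
    if (length(keep) == 0L)
      stop("scheme '", scheme@label, "' matches ",
           paste(sort(unique(as.vector(cnt))), collapse = "/"),
           " scans per session, expected k = ", scheme@k, call. = FALSE)
    if (length(keep) < length(bySubj))
      warning("scheme '", scheme@label, "': dropped ",
              length(bySubj) - length(keep),
              " subject(s) with incomplete scan sets", call. = FALSE)
    use <- sel & cd$subject_id %in% keep
    A <- SummarizedExperiment::assay(x, "value")[, use, drop = FALSE]
    grp <- paste(cd$subject_id[use], cd$session[use], sep = "\r")
    pooled <- t(rowsum(t(A), group = grp) / scheme@k)
    parts <- do.call(rbind, strsplit(colnames(pooled), "\r", fixed = TRUE))
    info <- data.frame(subject_id = parts[, 1],
                       session = as.integer(parts[, 2]))
    info$group <- cd$group[match(info$subject_id, cd$subject_id)]
    list(value = pooled, info = info)
  })

#' Test-retest percent error
#'
#' \eqn{100\,|v_1 - v_2| / ((v_1 + v_2)/2)}: the absolute difference
#' between the Session 1 and Session 2 estimates divided by their mean.
#' Symmetric in its arguments and invariant to rescaling both.
#'
#' @param v1,v2 estimates of the same measure from the two sessions
#'   (vectorised).
#' @return percent error, non-negative.
#' @examples
#' percentError(102, 98)  # 4
#' @export
percentError <- function(v1, v2) {
  if (any(!is.finite(v1)) || any(!is.finite(v2)))
    stop("percent error requires finite inputs", call. = FALSE)
  m <- (v1 + v2) / 2
  if (any(m <= 0))
    stop("percent error undefined for non-positive mean values",
         call. = FALSE)
  100 * abs(v1 - v2) / m
}

#' Per-subject per-measure percent errors under a scheme
#'
#' Pools each session's scans under the scheme, then applies
#' [percentError()] to the Session 1 vs Session 2 pooled values.
#'
#' @param x a \linkS4class{MorphoExperiment} containing both sessions.
#' @param scheme a \linkS4class{PoolingScheme}.
#' @param ... unused.
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{measure}, \code{structure}, \code{hemisphere},
#'   \code{measure_class}, \code{scheme}, \code{percent_error}.
#' @export
setMethod("schemeErrors", signature(x = "MorphoExperiment",
                                    scheme = "PoolingScheme"),
  function(x, scheme, ...) {
    p <- poolEstimates(x, scheme)
    s1 <- p$info$session == 1L
    s2 <- p$info$session == 2L
    sub1 <- p$info$subject_id[s1]
    o2 <- match(sub1, p$info$subject_id[s2])
    if (anyNA(o2))
      stop("subjects missing a session after pooling", call. = FALSE)
    A <- p$value[, s1, drop = FALSE]
    B <- p$value[, s2, drop = FALSE][, o2, drop = FALSE]
    pe <- percentError(A, B)
    rd <- measureKeys(x)
    nM <- nrow(pe)
    nS <- ncol(pe)
    data.frame(
      subject_id = rep(sub1, each = nM),
      group = rep(p$info$group[s1], each = nM),
      measure = rep(rownames(pe), nS),
      structure = rep(rd$structure, nS),
      hemisphere = rep(rd$hemisphere, nS),
      measure_class = rep(rd$measure_class, nS),
      scheme = scheme@label,
      percent_error = as.vector(pe),
      row.names = NULL)
  })

#' Summarise percent-error records
#'
#' The default "overall" aggregation is two-stage: mean percent error per
#' measure across subjects first, then mean/SD/SEM across measures (n =
#' number of measures). Alternatives: per measure (across subjects), per
#' group or per measure class (two-stage within the stratum), or per
#' subject x measure record ("records").
#'
#' @param records data.frame from [schemeErrors()].
#' @param grouping one of "overall", "measure", "group", "measure_class",
#'   "records".
#' @return data.frame with columns \code{scheme}, \code{grouping},
#'   \code{level}, \code{mean_pct}, \code{sd_pct}, \code{sem_pct},
#'   \code{n}.
#' @examples
#' \dontrun{summarizeErrors(schemeErrors(me, csPoolingScheme(4)))}
#' @export
summarizeErrors <- function(records,
                            grouping = c("overall", "measure", "group",
                                         "measure_class", "records")) {
  grouping <- match.arg(grouping)
  if (nrow(records) == 0L)
    stop("no error records to summarise", call. = FALSE)
  one <- function(x, level) {
    s <- if (length(x) > 1L) sd(x) else {
      warning("SD of a single record defined as 0", call. = FALSE)
      0
    }
    data.frame(scheme = records$scheme[1], grouping = grouping,
               level = level, mean_pct = mean(x), sd_pct = s,
               sem_pct = s / sqrt(length(x)), n = length(x))
  }
  twoStage <- function(rec, level) {
    perMeasure <- tapply(rec$percent_error, rec$measure, mean)
    one(as.vector(perMeasure), level)
  }
  out <- switch(grouping,
    overall = twoStage(records, "all"),
    records = one(records$percent_error, "all"),
    measure = do.call(rbind, lapply(split(records, records$measure),
      function(r) one(r$percent_error, r$measure[1]))),
    group = do.call(rbind, lapply(split(records, records$group),
      function(r) twoStage(r, r$group[1]))),
    measure_class = do.call(rbind,
      lapply(split(records, records$measure_class),
             function(r) twoStage(r, r$measure_class[1]))))
  rownames(out) <- NULL
  out
}

#' Expected error when pooling k uncorrelated estimates
#'
#' If per-scan errors are uncorrelated, the error of the mean of \code{k}
#' estimates declines as the square root of \code{k}:
#' \eqn{e_k = e_1/\sqrt{k}}.
#'
#' @param e1 single-scan error (any non-negative error scale).
#' @param k number of pooled estimates (>= 1), vectorised.
#' @return expected pooled error, same scale as \code{e1}.
#' @examples
#' expectedSqrtCurve(3.01, 4)           # 1.505
#' round(100 * (1 - expectedSqrtCurve(1, 8)))  # 65% expected reduction
#' @export
expectedSqrtCurve <- function(e1, k) {
  if (any(e1 < 0)) stop("e1 must be >= 0", call. = FALSE)
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  e1 / sqrt(k)
}

#' SD of the mean of k equicorrelated errors
#'
#' Closed form for pooling under the equicorrelation model: if each scan's
#' error has SD \code{sigma} and every pair correlates at \code{rho}, the
#' mean of \code{k} has SD
#' \eqn{\sigma\sqrt{(1 + (k-1)\rho)/k}}. With \code{rho = 0} this is the
#' square-root law; with \code{rho = 1} pooling gives no benefit.
#'
#' @param sigma per-scan error SD (fraction or percent, vectorised).
#' @param rho pairwise error correlation in [0, 1].
#' @param k number of pooled scans (>= 1).
#' @return SD of the pooled error, same scale as \code{sigma}.
#' @examples
#' equicorrPooledSD(1, 0.2, 4)  # sqrt(1.6/4)
#' @export
equicorrPooledSD <- function(sigma, rho, k) {
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]", call. = FALSE)
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  sigma * sqrt((1 + (k - 1) * rho) / k)
}

#' Per-measure and mean error reduction of one scheme over another
#'
#' Aligns two sets of error records on subject x measure, averages each
#' measure's percent error across subjects, and reports the per-measure
#' delta (reference minus candidate, percentage points; positive favours
#' the candidate) and percent reduction, plus their means.
#'
#' @param reference,candidate data.frames from [schemeErrors()] over the
#'   same subjects and measures.
#' @return list with \code{perMeasure} (data.frame: measure, reference,
#'   candidate, delta, percent_reduction), \code{meanDelta} and
#'   \code{meanReduction} (100 x meanDelta / reference mean error).
#' @export
relativeReduction <- function(reference, candidate) {
  keyR <- paste(reference$subject_id, reference$measure)
  keyC <- paste(candidate$subject_id, candidate$measure)
  if (!setequal(keyR, keyC))
    stop("reference and candidate cover different subject x measure sets",
         call. = FALSE)
  refM <- tapply(reference$percent_error, reference$measure, mean)
  canM <- tapply(candidate$percent_error, candidate$measure, mean)
  canM <- canM[names(refM)]
  delta <- refM - canM
  per <- data.frame(measure = names(refM), reference = as.vector(refM),
                    candidate = as.vector(canM), delta = as.vector(delta),
                    percent_reduction = as.vector(100 * delta / refM),
                    row.names = NULL)
  list(perMeasure = per, meanDelta = mean(delta),
       meanReduction = 100 * mean(delta) / mean(refM))
}

#' Total acquisition time of one session's selected scans
#'
#' @param scheme a \linkS4class{PoolingScheme}.
#' @param design the \linkS4class{StudyDesign} whose plan the scheme is
#'   resolved against (default [defaultStudyDesign()]).
#' @param ... unused.
#' @return seconds of scan time per session.
#' @examples
#' schemeDuration(csPoolingScheme(4))  # 288 s = 4'48"
#' schemeDuration(csPoolingScheme(8))  # 576 s = 9'36"
#' schemeDuration(multiresScheme())    # 305 s
#' @export
setMethod("schemeDuration", "PoolingScheme",
  function(scheme, design = defaultStudyDesign(), ...) {
    sp <- scanPlan(design)
    sel <- .matchScheme(sp, scheme)
    if (sum(sel) != scheme@k)
      stop("scheme '", scheme@label, "' matches ", sum(sel),
           " scans in the design plan, expected ", scheme@k,
           call. = FALSE)
    sum(sp$duration_s[sel])
  })

#' Estimate inter-scan error autocorrelation from pooled differences
#'
#' Under the equicorrelation model the mean squared session difference of
#' the k-scan pooled relative value follows \eqn{E[\Delta_k^2] = a + b/k}
#' with \eqn{a = 2\rho\sigma^2} and \eqn{b = 2(1-\rho)\sigma^2}. The
#' estimator pools \eqn{\Delta_k^2} across subjects (and measures), fits
#' the line by least squares over k = 1..\code{maxK}, and returns
#' \eqn{\hat\rho = a/(a+b)} clipped to [0, 1], with a subject-level
#' bootstrap confidence interval.
#'
#' @param x a \linkS4class{MorphoExperiment} with at least \code{maxK}
#'   CS 1.0 mm scans per session.
#' @param measures measure ids to use (default: all rows of \code{x}).
#' @param maxK largest pooling depth (>= 2).
#' @param nBoot bootstrap replicates for the CI (0 to skip).
#' @param conf confidence level.
#' @param ... unused.
#' @return list with \code{rho} (clipped), \code{rhoUnclipped}, \code{ci},
#'   \code{fit} (a, b), \code{msd} (per-k mean squared differences).
#' @export
setMethod("estimateRho", "MorphoExperiment",
  function(x, measures = NULL, maxK = 8L, nBoot = 200L, conf = 0.95,
           ...) {
    if (maxK < 2L) stop("maxK must be >= 2", call. = FALSE)
    if (!is.null(measures)) x <- x[measures, ]
    ks <- seq_len(maxK)
    # subject x k matrix of mean (over measures) squared relative diffs
    perSubj <- NULL
    for (k in ks) {
      p <- poolEstimates(x, csPoolingScheme(k))
      s1 <- p$info$session == 1L
      s2 <- p$info$session == 2L
      o2 <- match(p$info$subject_id[s1], p$info$subject_id[s2])
      A <- p$value[, s1, drop = FALSE]
      B <- p$value[, s2, drop = FALSE][, o2, drop = FALSE]
      d2 <- (2 * (A - B) / (A + B))^2
      colMeansD2 <- colMeans(d2)
      if (is.null(perSubj))
        perSubj <- matrix(NA_real_, length(colMeansD2), maxK,
                          dimnames = list(p$info$subject_id[s1], NULL))
      perSubj[, k] <- colMeansD2
    }
    fitRho <- function(m) {
      cf <- coef(lm(m ~ I(1 / ks)))
      a <- unname(cf[1]); b <- unname(cf[2])
      if (!is.finite(a + b) || a + b <= 0) return(NA_real_)
      a / (a + b)
    }
    msd <- colMeans(perSubj)
    rhoRaw <- fitRho(msd)
    if (is.na(rhoRaw))
      stop("degenerate fit: a + b <= 0; cannot estimate rho",
           call. = FALSE)
    ci <- c(NA_real_, NA_real_)
    if (nBoot > 0L) {
      n <- nrow(perSubj)
      boot <- vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        r <- fitRho(colMeans(perSubj[idx, , drop = FALSE]))
        min(max(r, 0), 1)
      }, numeric(1))
      ci <- unname(quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            na.rm = TRUE))
    }
    list(rho = min(max(rhoRaw, 0), 1), rhoUnclipped = rhoRaw, ci = ci,
         fit = c(a = unname(coef(lm(msd ~ I(1 / ks)))[1]),
                 b = unname(coef(lm(msd ~ I(1 / ks)))[2])),
         msd = msd)
  })
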