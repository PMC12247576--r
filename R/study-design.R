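# Study designs: participant groups and per-session scan plans.

#' Construct a StudyDesign
#'
#' @param groups data.frame with columns \code{group}, \code{n}.
#' @param sessions number of test-retest sessions.
#' @param scanPlan data.frame with one row per scan in a session
#'   (\code{scan_type}, \code{resolution_mm}, \code{block},
#'   \code{order_index}, \code{type_index}; \code{duration_s} is filled
#'   from the duration registry when absent).
#' @return a validated \linkS4class{StudyDesign}.
#' @seealso [defaultStudyDesign()], [csOnlyDesign()]
#' @export
studyDesign <- function(groups, sessions = 2L, scanPlan) {
  if (!"duration_s" %in% colnames(scanPlan))
    scanPlan$duration_s <- mapply(scanDuration, scanPlan$scan_type,
                                  scanPlan$resolution_mm)
  scanPlan <- scanPlan[order(scanPlan$order_index), , drop = FALSE]
  rownames(scanPlan) <- NULL
  new("StudyDesign", groups = groups, sessions = as.integer(sessions),
      scanPlan = scanPlan)
}

#' The default cluster-scanning test-retest design
#'
#' Two sessions per subject; each session acquires 17 scans: one ADNI
#' reference scan, eight CS 1.0 mm scans (type indices 1-4 before the
#' mid-session repositioning break, 5-8 after), and eight multi-resolution
#' CS scans (0.8, 0.9, 1.1 and 1.2 mm, one of each before and one after
#' the break). Default groups: 12 younger cognitively unimpaired adults
#' (YA-CU), 18 cognitively unimpaired older adults (OA-CU) and 10 adults
#' with mild cognitive impairment or Alzheimer's dementia (MCI/AD).
#'
#' Scan order within a session is fixed (the real protocol counterbalanced
#' order across participants; order effects are not simulated).
#'
#' @param groups optional replacement group table (columns \code{group},
#'   \code{n}).
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' d <- defaultStudyDesign()
#' nrow(scanPlan(d))        # 17 scans per session
#' groupTable(d)$n          # 12 18 10
#' @export
defaultStudyDesign <- function(groups = NULL) {
  if (is.null(groups))
    groups <- data.frame(group = .GROUPS, n = c(12L, 18L, 10L))
  half <- function(block, cs1Idx, mrIdx, offset) {
    data.frame(
      scan_type = c(if (block == "pre") "ADNI", "CS", "CS", rep("CS", 4),
                    "CS", "CS"),
      resolution_mm = c(if (block == "pre") 1.0, 1.2, 0.8, rep(1.0, 4),
                        1.1, 0.9),
      block = block,
      type_index = c(if (block == "pre") 1L, mrIdx, mrIdx, cs1Idx,
                     mrIdx, mrIdx),
      order_index = offset + seq_len(if (block == "pre") 9L else 8L))
  }
  plan <- rbind(half("pre", 1:4, 1L, 0L), half("post", 5:8, 2L, 9L))
  studyDesign(groups = groups, sessions = 2L, scanPlan = plan)
}

#' A minimal design with only CS 1.0 mm scans
#'
#' Convenience design for simulation studies of pooling: \code{nScans}
#' CS 1.0 mm scans per session, the first half before the break and the
#' second half after, one participant group.
#'
#' @param nSubjects subjects in the single group.
#' @param nScans CS 1.0 mm scans per session (default 8).
#' @param group group label.
#' @return a \linkS4class{StudyDesign}.
#' @export
csOnlyDesign <- function(nSubjects, nScans = 8L, group = "OA-CU") {
  nScans <- as.integer(nScans)
  plan <- data.frame(
    scan_type = "CS", resolution_mm = 1.0,
    block = rep(c("pre", "post"), c(ceiling(nScans / 2), floor(nScans / 2))),
    type_index = seq_len(nScans), order_index = seq_len(nScans))
  studyDesign(groups = data.frame(group = group, n = as.integer(nSubjects)),
              sessions = 2L, scanPlan = plan)
}

#' @rdname scanPlan
#' @export
scanPlan <- function(design) design@scanPlan

#' Accessors for StudyDesign slots
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return \code{scanPlan}: the per-session scan table; \code{groupTable}:
#'   the group/n table; \code{sessionDuration}: total acquisition seconds
#'   of one session's plan.
#' @name scanPlan
#' @export
groupTable <- function(design) design@groups

#' @rdname scanPlan
#' @export
sessionDuration <- function(design) sum(design@scanPlan$duration_s)

#' @export
setMethod("show", "StudyDesign", function(object) {
  g <- object@groups
  cat("StudyDesign:", sum(g$n), "subjects (",
      paste(g$group, g$n, sep = "=", collapse = ", "), "),",
      object@sessions, "sessions\n")
  sp <- object@scanPlan
  cat("  ", nrow(sp), " scans/session (",
      sum(sp$scan_type == "ADNI"), " ADNI + ",
      sum(sp$scan_type == "CS"), " CS), session duration ",
      sum(sp$duration_s), " s\n", sep = "")
})
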