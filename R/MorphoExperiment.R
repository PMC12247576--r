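# Construction of and access to the central estimate container.

.scanId <- function(cd) {
  paste(cd$subject_id, paste0("s", cd$session),
        paste0(cd$scan_type, cd$resolution_mm, ".", cd$type_index),
        sep = "_")
}

#' Build a MorphoExperiment from a long estimate table
#'
#' Assembles per-scan morphometric estimates into the package's central
#' container. The long table carries one row per subject x session x scan x
#' measure with the canonical columns (see [readLongCsv()]).
#'
#' @param long data.frame with columns \code{subject_id}, \code{group},
#'   \code{session}, \code{scan_type}, \code{resolution_mm}, \code{block},
#'   \code{type_index}, \code{order_index}, \code{duration_s},
#'   \code{structure}, \code{hemisphere}, \code{measure_class},
#'   \code{units}, \code{value}.
#' @return a \linkS4class{MorphoExperiment}.
#' @examples
#' long <- data.frame(subject_id = "s1", group = "YA-CU", session = 1:2,
#'   scan_type = "CS", resolution_mm = 1, block = "pre", type_index = 1L,
#'   order_index = 1L, duration_s = 72L, structure = "Hippocampus",
#'   hemisphere = "left", measure_class = "volume", units = "mm3",
#'   value = c(4208.3, 4102.7))
#' me <- MorphoExperiment(long)
#' dim(me)
#' @export
MorphoExperiment <- function(long) {
  need <- c(.COLDATA_COLS, .ROWDATA_COLS, "value")
  miss <- setdiff(need, colnames(long))
  if (length(miss))
    stop("long table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(long) == 0L)
    stop("long table is empty", call. = FALSE)
  mid <- measureId(long)
  sid <- .scanId(long)
  if (anyDuplicated(paste(sid, mid)))
    stop("duplicate (subject, session, scan, measure) rows", call. = FALSE)

  rd <- unique(long[, .ROWDATA_COLS, drop = FALSE])
  rownames(rd) <- measureId(rd)
  cd <- unique(long[, .COLDATA_COLS, drop = FALSE])
  rownames(cd) <- .scanId(cd)

  m <- matrix(NA_real_, nrow = nrow(rd), ncol = nrow(cd),
              dimnames = list(rownames(rd), rownames(cd)))
  m[cbind(match(mid, rownames(rd)), match(sid, rownames(cd)))] <- long$value
  if (anyNA(m))
    stop("estimate table is ragged: every scan must report every measure",
         call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = m),
    rowData = S4Vectors::DataFrame(rd),
    colData = S4Vectors::DataFrame(cd))
  new("MorphoExperiment", se)
}

#' Long-format view of a MorphoExperiment
#'
#' @param x a \linkS4class{MorphoExperiment}.
#' @param ... unused.
#' @return data.frame with the canonical long columns, one row per
#'   subject x session x scan x measure.
#' @export
setMethod("longTable", "MorphoExperiment", function(x, ...) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  v <- SummarizedExperiment::assay(x, "value")
  long <- cbind(
    cd[rep(seq_len(nrow(cd)), each = nrow(rd)), .COLDATA_COLS, drop = FALSE],
    rd[rep(seq_len(nrow(rd)), times = nrow(cd)), .ROWDATA_COLS, drop = FALSE])
  long$value <- as.vector(v)
  rownames(long) <- NULL
  long
})

#' Measure keys of a MorphoExperiment
#'
#' @param x a \linkS4class{MorphoExperiment}.
#' @return data.frame of measure keys (structure, hemisphere,
#'   measure_class, units), rownames = measure ids.
#' @export
setMethod("measureKeys", "MorphoExperiment", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))[, .ROWDATA_COLS]
})

#' Scan records of a MorphoExperiment
#'
#' @param x a \linkS4class{MorphoExperiment}.
#' @return data.frame of per-scan records (one row per column of x).
#' @export
setMethod("scanInfo", "MorphoExperiment", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))[, .COLDATA_COLS]
})

#' @export
setMethod("show", "MorphoExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("MorphoExperiment:", nrow(object), "measures x", ncol(object),
      "scans\n")
  cat("  subjects:", length(unique(cd$subject_id)),
      " sessions:", length(unique(cd$session)),
      " groups:", paste(unique(cd$group), collapse = ", "), "\n")
  cls <- table(SummarizedExperiment::rowData(object)$measure_class)
  cat("  measures:", paste(names(cls), cls, sep = "=", collapse = ", "),
      "\n")
})
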