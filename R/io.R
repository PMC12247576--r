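# Readers and writers: FreeSurfer stats dialects and the canonical long CSV.

.parseStatsTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(hdr) != 1L)
    stop("malformed stats file (no '# ColHeaders' line): ", path,
         call. = FALSE)
  cols <- strsplit(sub("^# ColHeaders\\s+", "", hdr), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L)
    stop("stats file has no data rows: ", path, call. = FALSE)
  tab <- read.table(text = body, col.names = cols,
                    stringsAsFactors = FALSE)
  attr(tab, "headerLines") <- lines[grepl("^#", lines)]
  tab
}

.statsHemi <- function(headerLines, fallback) {
  hemiLine <- grep("^# hemi\\s", headerLines, value = TRUE)
  if (length(hemiLine) == 1L) {
    h <- trimws(sub("^# hemi\\s+", "", hemiLine[1]))
    return(switch(h, lh = "left", rh = "right",
                  stop("unknown hemisphere code '", h, "'",
                       call. = FALSE)))
  }
  if (is.null(fallback))
    stop("hemisphere not recorded in file header; pass `hemisphere`",
         call. = FALSE)
  fallback
}

.scanRecordDf <- function(scan) {
  scan <- as.data.frame(as.list(scan), stringsAsFactors = FALSE)
  miss <- setdiff(.COLDATA_COLS, colnames(scan))
  if (length(miss))
    stop("scan record is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  scan[, .COLDATA_COLS]
}

#' Describe one acquired scan
#'
#' Convenience constructor for the scan record attached to rows read from
#' FreeSurfer stats files. Duration is filled from the registry when not
#' given.
#'
#' @param subject_id,group,session,scan_type,resolution_mm,block,type_index,order_index,duration_s
#'   scan record fields (see \linkS4class{MorphoExperiment}).
#' @return one-row data.frame.
#' @export
scanRecord <- function(subject_id, group, session, scan_type,
                       resolution_mm = 1.0, block = "pre",
                       type_index = 1L, order_index = type_index,
                       duration_s = scanDuration(scan_type,
                                                 resolution_mm)) {
  if (scan_type == "ADNI" &&
      (abs(resolution_mm - 1.0) > 1e-9 || type_index != 1L))
    stop("ADNI scans have resolution 1.0 mm and type_index 1",
         call. = FALSE)
  data.frame(subject_id = subject_id, group = group,
             session = as.integer(session), scan_type = scan_type,
             resolution_mm = resolution_mm, block = block,
             type_index = as.integer(type_index),
             order_index = as.integer(order_index),
             duration_s = as.integer(duration_s))
}

#' Read subcortical volumes from a FreeSurfer aseg.stats table
#'
#' Parses the whitespace-separated table ('#'-prefixed headers, columns
#' named on the \code{# ColHeaders} line, including \code{StructName} and
#' \code{Volume_mm3}), keeps the registry's eight bilateral subcortical
#' structures, and maps FreeSurfer labels (e.g. "Left-Thalamus-Proper") to
#' measure keys via the packaged name-normalisation table. Segments not in
#' the registry are ignored; a registry structure absent from the file is
#' an error naming it.
#'
#' @param path aseg.stats file.
#' @param scan one-row data.frame from [scanRecord()].
#' @return long-format data.frame of 16 volume rows (canonical columns).
#' @export
readAsegStats <- function(path, scan) {
  tab <- .parseStatsTable(path)
  if (!all(c("StructName", "Volume_mm3") %in% colnames(tab)))
    stop("aseg.stats is missing StructName/Volume_mm3 columns: ", path,
         call. = FALSE)
  map <- .asegStructureMap()
  hit <- match(map$fs_label, tab$StructName)
  if (anyNA(hit))
    stop("aseg.stats is missing registry structure(s): ",
         paste(map$fs_label[is.na(hit)], collapse = ", "), call. = FALSE)
  scan <- .scanRecordDf(scan)
  out <- cbind(scan[rep(1L, nrow(map)), , drop = FALSE],
               structure = map$structure, hemisphere = map$hemisphere,
               measure_class = "volume", units = "mm3",
               value = tab$Volume_mm3[hit])
  rownames(out) <- NULL
  out
}

#' Read cortical parcel measures from FreeSurfer aparc-style tables
#'
#' For \code{measure_class = "thickness"} reads an aparc.stats dialect
#' (\code{StructName} and \code{ThickAvg} columns). For
#' \code{measure_class = "gwr"} reads a w-g.pct.stats dialect
#' (\code{StructName} and \code{Mean} percent-contrast columns) and, by
#' default, converts the white-minus-gray percent contrast to a
#' gray-to-white intensity ratio via \eqn{gwr = 1/(1 - pct/100)}
#' (\code{convert = FALSE} keeps the raw percent value, relabelled as gwr).
#' The hemisphere is taken from a \code{# hemi lh|rh} header line, or from
#' the \code{hemisphere} argument.
#'
#' @param path stats file.
#' @param scan one-row data.frame from [scanRecord()].
#' @param measure_class "thickness" or "gwr".
#' @param hemisphere "left"/"right" fallback when the file header lacks a
#'   hemi line.
#' @param convert convert w-g percent contrast to a ratio (default TRUE).
#' @return long-format data.frame of 34 rows (canonical columns).
#' @export
readAparcStats <- function(path, scan,
                           measure_class = c("thickness", "gwr"),
                           hemisphere = NULL, convert = TRUE) {
  measure_class <- match.arg(measure_class)
  tab <- .parseStatsTable(path)
  hemi <- .statsHemi(attr(tab, "headerLines"), hemisphere)
  valueCol <- if (measure_class == "thickness") "ThickAvg" else "Mean"
  if (!all(c("StructName", valueCol) %in% colnames(tab)))
    stop("stats file is missing StructName/", valueCol, " columns: ",
         path, call. = FALSE)
  unknown <- setdiff(tab$StructName, .DK_PARCELS)
  if (length(unknown))
    stop("unknown parcel name(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hit <- match(.DK_PARCELS, tab$StructName)
  if (anyNA(hit))
    stop("stats file is missing parcel(s): ",
         paste(.DK_PARCELS[is.na(hit)], collapse = ", "), call. = FALSE)
  val <- tab[[valueCol]][hit]
  if (measure_class == "gwr" && convert) {
    if (any(val >= 100))
      stop("w-g percent contrast >= 100 cannot be converted to a ratio",
           call. = FALSE)
    val <- 1 / (1 - val / 100)
  }
  scan <- .scanRecordDf(scan)
  out <- cbind(scan[rep(1L, length(val)), , drop = FALSE],
               structure = .DK_PARCELS, hemisphere = hemi,
               measure_class = measure_class,
               units = unname(.MEASURE_CLASSES[measure_class]),
               value = val)
  rownames(out) <- NULL
  out
}

.LONG_COLS <- c("subject_id", "group", "session", "scan_type",
                "resolution_mm", "block", "type_index", "order_index",
                "duration_s", "structure", "hemisphere", "measure_class",
                "units", "value")

#' Write / read the canonical long CSV
#'
#' One row per subject x session x scan x measure; comma-separated, UTF-8,
#' '.' decimal, header required. Values are written with 17 significant
#' digits so that write-then-read is an identity. Duplicated
#' (subject, session, scan, measure) rows and non-finite values are
#' integrity errors.
#'
#' @param x a \linkS4class{MorphoExperiment} or a long data.frame with the
#'   canonical columns.
#' @param path file path.
#' @return \code{readLongCsv} returns a \linkS4class{MorphoExperiment}
#'   (or, with \code{as = "data.frame"}, the long table);
#'   \code{writeLongCsv} returns \code{path} invisibly.
#' @export
writeLongCsv <- function(x, path) {
  long <- if (is(x, "MorphoExperiment")) longTable(x) else x
  miss <- setdiff(.LONG_COLS, colnames(long))
  if (length(miss))
    stop("long table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  long <- long[, .LONG_COLS]
  if (any(!is.finite(long$value)))
    stop("non-finite values cannot be written", call. = FALSE)
  long$value <- sprintf("%.17g", long$value)
  long$resolution_mm <- sprintf("%.17g", long$resolution_mm)
  write.csv(long, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeLongCsv
#' @param as return type for \code{readLongCsv}: "MorphoExperiment"
#'   (default) or "data.frame". An empty file (header only) is only
#'   representable as a data.frame.
#' @export
readLongCsv <- function(path, as = c("MorphoExperiment", "data.frame")) {
  as <- match.arg(as)
  long <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(subject_id = "character",
                                  group = "character",
                                  structure = "character",
                                  hemisphere = "character"),
                   fileEncoding = "UTF-8")
  miss <- setdiff(.LONG_COLS, colnames(long))
  if (length(miss))
    stop("long CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  long <- long[, .LONG_COLS]
  if (nrow(long) > 0L) {
    if (any(!is.finite(long$value)))
      stop("long CSV contains non-finite values", call. = FALSE)
    key <- paste(.scanId(long), measureId(long))
    if (anyDuplicated(key))
      stop("long CSV contains duplicate (subject, session, scan, ",
           "measure) rows", call. = FALSE)
  }
  if (as == "data.frame") return(long)
  MorphoExperiment(long)
}

#' Write syntactically valid FreeSurfer-style stats fixtures
#'
#' Emits aseg.stats / aparc.stats / w-g.pct.stats files for one scan of
#' one subject from an estimate table, for testing the readers. The GWR
#' values are converted back to the w-g percent-contrast scale
#' (\eqn{pct = 100 (1 - 1/gwr)}) so that reading the fixture with the
#' default conversion reproduces the input.
#'
#' @param x a \linkS4class{MorphoExperiment}.
#' @param dir output directory (created if needed).
#' @param subject,session,column subject id, session, or an explicit
#'   column name of \code{x} selecting the scan to write.
#' @return invisibly, the named vector of written file paths.
#' @export
writeFixtureStats <- function(x, dir, subject = NULL, session = 1L,
                              column = NULL) {
  cd <- scanInfo(x)
  if (is.null(column)) {
    if (is.null(subject)) subject <- cd$subject_id[1]
    idx <- which(cd$subject_id == subject & cd$session == session)[1]
    if (is.na(idx)) stop("no such subject/session", call. = FALSE)
  } else {
    idx <- match(column, colnames(x))
    if (is.na(idx)) stop("no such column: ", column, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rd <- measureKeys(x)
  v <- SummarizedExperiment::assay(x, "value")[, idx]
  paths <- c()

  vol <- rd$measure_class == "volume"
  map <- .asegStructureMap()
  lab <- map$fs_label[match(paste(rd$structure[vol], rd$hemisphere[vol]),
                            paste(map$structure, map$hemisphere))]
  asegPath <- file.path(dir, "aseg.stats")
  writeLines(c(
    "# Title Segmentation Statistics (synthetic fixture)",
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    sprintf("%3d %4d %7d %12.4f %s", seq_along(lab), 100 + seq_along(lab),
            as.integer(round(v[vol])), v[vol], lab)), asegPath)
  paths["aseg"] <- asegPath

  for (h in c("left", "right")) {
    code <- if (h == "left") "lh" else "rh"
    th <- rd$measure_class == "thickness" & rd$hemisphere == h
    p <- file.path(dir, paste0(code, ".aparc.stats"))
    writeLines(c(
      "# Title Cortical Parcellation Statistics (synthetic fixture)",
      paste("# hemi", code),
      "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd",
      sprintf("%s %6d %7.1f %8.1f %7.4f %6.3f", rd$structure[th],
              5000L, 3000.0, 9000.0, v[th], 0.5)), p)
    paths[paste0("aparc.", h)] <- p

    gw <- rd$measure_class == "gwr" & rd$hemisphere == h
    pct <- 100 * (1 - 1 / v[gw])
    p2 <- file.path(dir, paste0(code, ".w-g.pct.stats"))
    writeLines(c(
      "# Title White-Gray Percent Contrast (synthetic fixture)",
      paste("# hemi", code),
      "# ColHeaders Index SegId NVertices Area_mm2 StructName Mean StdDev",
      sprintf("%3d %4d %7d %8.1f %s %12.8f %6.3f", seq_len(sum(gw)),
              1000L + seq_len(sum(gw)), 5000L, 3000.0,
              rd$structure[gw], pct, 2.0)), p2)
    paths[paste0("wg.", h)] <- p2
  }
  invisible(paths)
}
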