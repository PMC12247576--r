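# Run configuration and end-to-end orchestration.

.CONFIG_VERSION <- 1L

#' Default run configuration
#'
#' A list mirroring the full synthetic study: the default noise model and
#' study design, the standard scheme set (ADNI reference, first-1/2/4/8
#' CS pooling, break pair, serial pair, multi-resolution), alpha 0.05,
#' two-stage aggregation.
#'
#' @param outputDir where [runSimulate()] / [runAnalyze()] write.
#' @param seed master seed.
#' @return a run-config list (see [readRunConfig()] for the YAML form).
#' @export
defaultRunConfig <- function(outputDir = tempfile("morphopool_run_"),
                             seed = 1L) {
  list(version = .CONFIG_VERSION,
       input = list(synthetic = list()),
       schemes = c("adni", "cs1", "cs2", "cs4", "cs8",
                   "serial_pair", "break_pair", "multires4"),
       reference = "adni",
       contrasts = c("pooling_curve", "break", "multires"),
       alpha = 0.05,
       aggregation = "overall",
       output_dir = outputDir,
       seed = as.integer(seed))
}

#' Read / write a run configuration as YAML
#'
#' The YAML schema is versioned (field \code{version}, currently 1).
#' Exactly one input source must be given under \code{input}: a
#' \code{csv} path to a canonical long CSV, or \code{synthetic} with
#' optional overrides (\code{subjects}: per-group sizes named by group;
#' noise fields \code{e1_cs}, \code{e1_adni}, \code{rho_same} passed to
#' [defaultNoiseModel()]). The reference scheme must be among
#' \code{schemes}.
#'
#' @param path YAML file.
#' @return a validated run-config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  for (f in names(base))
    if (is.null(cfg[[f]])) cfg[[f]] <- base[[f]]
  .validateRunConfig(cfg)
  cfg
}

#' @rdname readRunConfig
#' @param config a run-config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.validateRunConfig <- function(cfg) {
  fail <- function(field, why)
    stop("invalid config at '", field, "': ", why, call. = FALSE)
  if (!identical(as.integer(cfg$version), .CONFIG_VERSION))
    fail("version", paste("expected", .CONFIG_VERSION))
  src <- intersect(names(cfg$input), c("csv", "synthetic"))
  if (length(src) != 1L)
    fail("input", "exactly one of csv / synthetic required")
  if (!cfg$reference %in% cfg$schemes)
    fail("reference", "reference scheme must be among schemes")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    fail("alpha", "must lie in (0, 1)")
  invisible(cfg)
}

#' Resolve a scheme name from a run configuration
#'
#' Known names: \code{adni}, \code{cs<k>} or \code{cs1mm_first_<k>}
#' (first-k CS 1.0 mm), \code{serial_pair}, \code{break_pair},
#' \code{multires4}.
#'
#' @param name scheme name.
#' @return a \linkS4class{PoolingScheme}.
#' @export
resolveScheme <- function(name) {
  if (name == "adni") return(adniScheme())
  if (grepl("^cs([0-9]+)$", name))
    return(csPoolingScheme(as.integer(sub("^cs", "", name))))
  if (grepl("^cs1mm_first_([0-9]+)$", name))
    return(csPoolingScheme(as.integer(sub("^cs1mm_first_", "", name))))
  switch(name,
         serial_pair = serialPairScheme(),
         break_pair = breakPairScheme(),
         multires4 = multiresScheme(),
         stop("unknown scheme name '", name, "'", call. = FALSE))
}

.configModelDesign <- function(cfg) {
  syn <- cfg$input$synthetic
  args <- list()
  if (!is.null(syn$e1_cs)) args$e1CS <- syn$e1_cs
  if (!is.null(syn$e1_adni)) args$e1ADNI <- syn$e1_adni
  if (!is.null(syn$rho_same)) args$rhoSame <- syn$rho_same
  model <- do.call(defaultNoiseModel, args)
  design <- defaultStudyDesign()
  if (!is.null(syn$subjects)) {
    g <- groupTable(design)
    n <- unlist(syn$subjects)
    i <- match(names(n), g$group)
    if (anyNA(i))
      stop("invalid config at 'input.synthetic.subjects': unknown group ",
           paste(names(n)[is.na(i)], collapse = ", "), call. = FALSE)
    g$n[i] <- as.integer(n)
    design <- defaultStudyDesign(groups = g)
  }
  list(model = model, design = design)
}

#' Simulate a study from a run configuration
#'
#' Generates the synthetic estimate table, writes it as the canonical
#' long CSV plus a YAML provenance sidecar (model parameters, design
#' summary, seed, package version), and returns the table.
#'
#' @param config run-config list (default [defaultRunConfig()]).
#' @return invisibly, a list with \code{table}
#'   (\linkS4class{MorphoExperiment}), \code{csv} and \code{provenance}
#'   file paths.
#' @export
runSimulate <- function(config = defaultRunConfig()) {
  .validateRunConfig(config)
  if (is.null(config$input$synthetic))
    stop("runSimulate requires a synthetic input source", call. = FALSE)
  md <- .configModelDesign(config)
  me <- simulateStudy(md$model, md$design, seed = config$seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(config$output_dir, "estimates.csv")
  writeLongCsv(me, csv)
  prov <- file.path(config$output_dir, "estimates.provenance.yaml")
  yaml::write_yaml(list(
    package = "morphopool",
    version = as.character(utils::packageVersion("morphopool")),
    seed = config$seed,
    model = list(sigma_session = md$model@sigmaSession,
                 sigma_block = md$model@sigmaBlock,
                 sigma_scan = md$model@sigmaScan,
                 sigma_scan_adni = md$model@sigmaScanADNI,
                 subject_cv = md$model@subjectCV,
                 rho_same = impliedRho(md$model),
                 rho_cross = impliedRho(md$model, sameBlock = FALSE)),
    design = list(groups = as.list(stats::setNames(
                    groupTable(md$design)$n, groupTable(md$design)$group)),
                  sessions = md$design@sessions,
                  scans_per_session = nrow(scanPlan(md$design)))), prov)
  invisible(list(table = me, csv = csv, provenance = prov))
}

#' Run the full precision analysis and write a report bundle
#'
#' Reads the configured input (long CSV or fresh simulation), evaluates
#' every configured pooling scheme, and writes per-scheme error
#' summaries, the pooling-curve table with its square-root-law overlay,
#' the break and multi-resolution contrasts, per-group subgroup tables,
#' inter-scan autocorrelation diagnostics and a plain-text report. On any
#' integrity failure, partial outputs are removed and the error is
#' re-raised.
#'
#' @param config run-config list (default [defaultRunConfig()]).
#' @return invisibly, a list of the computed objects and written paths.
#' @export
runAnalyze <- function(config = defaultRunConfig()) {
  .validateRunConfig(config)
  me <- if (!is.null(config$input$csv)) readLongCsv(config$input$csv)
        else {
          md <- .configModelDesign(config)
          simulateStudy(md$model, md$design, seed = config$seed)
        }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  out <- tryCatch({
    emit <- function(df, name) {
      p <- file.path(config$output_dir, name)
      write.csv(df, p, row.names = FALSE)
      written <<- c(written, p)
      # self-consistency: outputs must be readable by the same dialect
      stopifnot(nrow(read.csv(p)) == nrow(df))
      p
    }
    errs <- lapply(config$schemes,
                   function(nm) schemeErrors(me, resolveScheme(nm)))
    names(errs) <- config$schemes
    sums <- do.call(rbind, lapply(errs, summarizeErrors))
    emit(sums, "scheme_summaries.csv")
    emit(do.call(rbind, errs), "error_records.csv")

    cd <- scanInfo(me)
    nCS1 <- length(unique(
      cd$type_index[cd$scan_type == "CS" & cd$resolution_mm == 1.0]))
    ks <- c(1L, 2L, 4L, 8L)
    ks <- ks[ks <= nCS1]
    ref <- if (config$reference %in% config$schemes)
      resolveScheme(config$reference) else NULL
    curve <- if ("pooling_curve" %in% config$contrasts && length(ks))
      poolingCurve(me, ks = ks, reference = ref, alpha = config$alpha)
    if (!is.null(curve)) emit(curve$summary, "pooling_curve.csv")

    brk <- if ("break" %in% config$contrasts && nCS1 >= 5L)
      breakContrast(me, alpha = config$alpha)
    mres <- if ("multires" %in% config$contrasts &&
                length(setdiff(unique(cd$resolution_mm), 1.0)) >= 4L)
      multiresContrast(me, alpha = config$alpha)
    contrastRow <- function(cc, what) data.frame(
      contrast = what, reference = cc@reference, candidate = cc@candidate,
      mean_delta = cc@meanDelta, mean_reduction_pct = cc@meanReduction,
      fraction_improved_pct = cc@fractionImproved,
      fraction_significant_pct = cc@fractionSignificant,
      alpha = cc@alpha)
    mods <- rbind(if (!is.null(brk)) contrastRow(brk, "break"),
                  if (!is.null(mres)) contrastRow(mres, "multires"))
    if (!is.null(mods)) emit(mods, "moderator_contrasts.csv")

    subs <- if (length(unique(cd$group)) > 1L && !is.null(ref))
      subgroupSummaries(errs[[config$schemes[
        which(config$schemes != config$reference)[1]]]],
        reference = errs[[config$reference]])
    if (!is.null(subs)) emit(subs, "subgroup_summaries.csv")

    rho <- if (nCS1 >= 2L) {
      set.seed(config$seed)
      tryCatch(estimateRho(me, maxK = min(nCS1, 8L)),
               error = function(e) {
                 message("rho diagnostics skipped: ",
                         conditionMessage(e))
                 NULL
               })
    }
    if (!is.null(rho))
      emit(data.frame(rho = rho$rho, rho_unclipped = rho$rhoUnclipped,
                      ci_lo = rho$ci[1], ci_hi = rho$ci[2]),
           "rho_diagnostics.csv")

    reportPath <- file.path(config$output_dir, "report.txt")
    .writeTextReport(reportPath, sums, curve, brk, mres, subs, rho)
    written <- c(written, reportPath)
    list(table = me, summaries = sums, curve = curve,
         breakContrast = brk, multiresContrast = mres,
         subgroups = subs, rho = rho, outputDir = config$output_dir,
         files = written)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(out)
}

.fmtMinSec <- function(s) sprintf("%d'%02d\"", s %/% 60, s %% 60)

.writeTextReport <- function(path, sums, curve, brk, mres, subs, rho) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("morphopool precision report")
  w("===========================")
  w("")
  w("Mean percent error by scheme (two-stage aggregation over measures):")
  for (i in seq_len(nrow(sums)))
    w("  %-18s mean %5.2f%%  SD %5.2f%%  (n=%d measures)",
      sums$scheme[i], sums$mean_pct[i], sums$sd_pct[i], sums$n[i])
  if (!is.null(curve)) {
    w("")
    w("Pooling curve (first-k CS 1.0 mm; sqrt-k overlay anchored at k=%d):",
      min(curve$summary$k))
    for (i in seq_len(nrow(curve$summary))) {
      s <- curve$summary[i, ]
      extra <- if (!is.null(s$reduction_vs_reference_pct))
        sprintf("  vs ref: %+.2f pts (%.0f%% lower), improved %.0f%%, signif %.0f%%",
                s$delta_vs_reference, s$reduction_vs_reference_pct,
                s$fraction_improved_pct, s$fraction_significant_pct)
      else ""
      w("  k=%d (%s): %5.2f%%  expected %5.2f%%%s", s$k,
        .fmtMinSec(s$duration_s), s$mean_pct, s$expected_sqrt_pct, extra)
    }
  }
  modLine <- function(cc, what)
    w("  %s: mean delta %+.3f pts (%.0f%% reduction), improved %.0f%%, signif %.0f%% at alpha=%.2g",
      what, cc@meanDelta, cc@meanReduction, cc@fractionImproved,
      cc@fractionSignificant, cc@alpha)
  if (!is.null(brk) || !is.null(mres)) {
    w("")
    w("Moderator contrasts (positive delta favours the candidate):")
    if (!is.null(brk)) modLine(brk, "break pair {1,5} vs serial {1,2}")
    if (!is.null(mres)) modLine(mres, "multires {0.8,0.9,1.1,1.2} vs CS 1.0 x4")
  }
  if (!is.null(subs)) {
    w("")
    w("Subgroups:")
    for (i in seq_len(nrow(subs))) {
      extra <- if (!is.null(subs$reduction_pct))
        sprintf("  (ref %5.2f%%, reduction %.0f%%)",
                subs$reference_mean_pct[i], subs$reduction_pct[i])
      else ""
      w("  %-8s mean %5.2f%% SD %5.2f%%%s", subs$level[i],
        subs$mean_pct[i], subs$sd_pct[i], extra)
    }
  }
  if (!is.null(rho))
    w("\nInter-scan error autocorrelation: rho = %.3f (95%% CI %.3f-%.3f)",
      rho$rho, rho$ci[1], rho$ci[2])
}
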