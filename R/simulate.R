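# Synthetic estimate tables with hierarchical multiplicative error.

# Per-subject substream: changing the subject count leaves earlier
# subjects' draws untouched. Linear congruential mix kept below 2^31.
.subjectSeed <- function(master, i) {
  as.integer((as.numeric(master) %% 1e6) * 1009 + i * 7919) %% 2147483647L
}

.lookupRes <- function(map, res) {
  key <- as.character(res)
  out <- unname(map[key])
  out[is.na(out)] <- 1
  out
}

# Resolve regionMeans rules against the registry; the most specific
# matching rule wins (structure+hemisphere > structure > class-wide).
.resolveMeans <- function(rules, reg) {
  means <- rep(NA_real_, nrow(reg))
  spec <- rep(-1L, nrow(reg))
  for (r in seq_len(nrow(rules))) {
    rule <- rules[r, ]
    hit <- reg$measure_class == rule$measure_class
    s <- 0L
    if (!is.na(rule$structure)) {
      hit <- hit & reg$structure == rule$structure
      s <- s + 1L
    }
    if (!is.na(rule$hemisphere)) {
      hit <- hit & reg$hemisphere == rule$hemisphere
      s <- s + 2L
    }
    take <- hit & s > spec
    means[take] <- rule$mean
    spec[take] <- s
  }
  if (anyNA(means))
    stop("regionMeans does not cover all registry measures (e.g. ",
         rownames(reg)[which(is.na(means))[1]], ")", call. = FALSE)
  means
}

.resolveShift <- function(shifts, reg, group) {
  fac <- rep(1, nrow(reg))
  if (nrow(shifts) == 0L) return(fac)
  for (r in which(shifts$group == group)) {
    rule <- shifts[r, ]
    hit <- reg$measure_class == rule$measure_class
    if (!is.na(rule$structure_pattern))
      hit <- hit & grepl(rule$structure_pattern, reg$structure)
    fac[hit] <- fac[hit] * (1 + rule$shift)
  }
  fac
}

# Redraw standard-normal entries of z until fn(z) is strictly positive
# everywhere; at most `limit` redraws per cell.
.drawPositive <- function(z, fn, limit = 100L, what = "value") {
  v <- fn(z)
  tries <- 0L
  while (any(bad <- v <= 0)) {
    tries <- tries + 1L
    if (tries > limit)
      stop("simulated ", what, " still non-positive after ", limit,
           " redraws; error SDs are pathologically large", call. = FALSE)
    z[bad] <- rnorm(sum(bad))
    v <- fn(z)
  }
  if (tries > 0L)
    warning("redrew ", what, " for non-positive simulated values (",
            tries, " pass(es))", call. = FALSE)
  v
}

#' Simulate a cluster-scanning test-retest study
#'
#' Generates per-scan morphometric estimates under the hierarchical
#' multiplicative error model: for subject i, measure m, session s, block
#' b and scan j,
#' \deqn{y = T_{im} (1+\delta_{ism}) (1+\beta_{isbm})\, b_{res}\,
#'       (1+\epsilon_{isjm}\, c_{res})}
#' with \eqn{T_{im}} drawn once per subject around the region mean
#' (CV \code{subjectCV}, times the group shift), \eqn{\delta \sim
#' N(0,\sigma_{sess})}, \eqn{\beta \sim N(0,\sigma_{block})}, and
#' \eqn{\epsilon \sim N(0,\sigma_{scan})} (or \eqn{\sigma_{scan,ADNI}});
#' \eqn{b_{res}} and \eqn{c_{res}} are the per-resolution bias and noise
#' scale. All components are drawn independently per measure. Non-positive
#' simulated values are redrawn (at most 100 passes) with a warning.
#'
#' Determinism: identical (model, design, seed) give bit-identical output,
#' and each subject uses its own derived substream, so increasing the
#' subject count does not reshuffle existing subjects.
#'
#' @param model a \linkS4class{NoiseModel}.
#' @param design a \linkS4class{StudyDesign}.
#' @param seed master integer seed; defaults to the model's seed slot.
#' @param registry measure registry (default [defaultMeasureRegistry()]).
#' @return a \linkS4class{MorphoExperiment}.
#' @examples
#' me <- simulateStudy(defaultNoiseModel(),
#'                     csOnlyDesign(4, nScans = 2), seed = 7)
#' dim(me)  # 152 measures x 16 scans
#' @export
setMethod("simulateStudy", signature(model = "NoiseModel",
                                     design = "StudyDesign"),
  function(model, design, seed = NULL,
           registry = defaultMeasureRegistry()) {
    validObject(model)
    validObject(design)
    if (is.null(seed)) seed <- model@seed
    reg <- registry
    M <- nrow(reg)
    means <- .resolveMeans(model@regionMeans, reg)
    sp <- design@scanPlan
    J <- nrow(sp)
    S <- design@sessions
    sigScanBase <- ifelse(sp$scan_type == "ADNI",
                          model@sigmaScanADNI, model@sigmaScan) *
      .lookupRes(model@resolutionNoiseScale, sp$resolution_mm)
    biasRes <- .lookupRes(model@resolutionBias, sp$resolution_mm)
    blockIdx <- match(sp$block, c("pre", "post"))

    g <- design@groups
    subjGroup <- rep(g$group, g$n)
    nSubj <- length(subjGroup)
    if (nSubj == 0L)
      stop("design has no subjects", call. = FALSE)
    subjId <- sprintf("sub%03d", seq_len(nSubj))

    vals <- matrix(NA_real_, nrow = M, ncol = nSubj * S * J)
    cdList <- vector("list", nSubj)
    for (i in seq_len(nSubj)) {
      set.seed(.subjectSeed(seed, i))
      gscale <- .lookupRes(model@groupNoiseScale, subjGroup[i])
      shift <- .resolveShift(model@groupShift, reg, subjGroup[i])
      Tm <- .drawPositive(rnorm(M),
                          function(z) means * (1 + z * model@subjectCV),
                          what = "true value") * shift
      for (s in seq_len(S)) {
        delta <- rnorm(M) * model@sigmaSession * gscale
        beta <- matrix(rnorm(2 * M), M, 2) * model@sigmaBlock * gscale
        base <- Tm * (1 + delta)
        eps <- matrix(rnorm(M * J), M, J)
        sesMat <- .drawPositive(eps, function(z) {
          (base * (1 + beta[, blockIdx, drop = FALSE])) *
            rep(biasRes, each = M) *
            (1 + sweep(z, 2, sigScanBase * gscale, `*`))
        }, what = "scan value")
        cols <- ((i - 1L) * S + (s - 1L)) * J + seq_len(J)
        vals[, cols] <- sesMat
      }
      cdList[[i]] <- data.frame(
        subject_id = subjId[i], group = subjGroup[i],
        session = rep(seq_len(S), each = J),
        sp[rep(seq_len(J), S),
           c("scan_type", "resolution_mm", "block", "type_index",
             "order_index", "duration_s")],
        row.names = NULL)
    }
    cd <- do.call(rbind, cdList)
    cd <- cd[, .COLDATA_COLS]
    rownames(cd) <- .scanId(cd)
    dimnames(vals) <- list(rownames(reg), rownames(cd))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(value = vals),
      rowData = S4Vectors::DataFrame(reg),
      colData = S4Vectors::DataFrame(cd))
    new("MorphoExperiment", se)
  })
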