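# Canonical measure and scan-duration registries.

.ASEG_STRUCTURES <- c("Amygdala", "Accumbens-area", "Pallidum", "Caudate",
                      "Hippocampus", "Putamen", "Thalamus", "VentralDC")

# Desikan-Killiany cortical parcellation, 34 parcels per hemisphere
.DK_PARCELS <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

#' Canonical morphometric measure registry
#'
#' The 152 measures tracked by the analysis: bilateral volumes for eight
#' subcortical structures (16), average cortical thickness for the 68
#' Desikan-Killiany parcels, and gray-to-white matter signal intensity
#' ratio (GWR) for the same 68 parcels. Units are fixed by measure class:
#' volume in mm3, thickness in mm, GWR dimensionless.
#'
#' @return data.frame with columns \code{structure}, \code{hemisphere},
#'   \code{measure_class}, \code{units} and rownames giving the canonical
#'   measure id.
#' @examples
#' nrow(defaultMeasureRegistry())  # 152
#' @export
defaultMeasureRegistry <- function() {
  vol <- expand.grid(structure = .ASEG_STRUCTURES,
                     hemisphere = c("left", "right"),
                     stringsAsFactors = FALSE)
  vol$measure_class <- "volume"
  ctx <- expand.grid(structure = .DK_PARCELS,
                     hemisphere = c("left", "right"),
                     stringsAsFactors = FALSE)
  reg <- rbind(vol,
               cbind(ctx, measure_class = "thickness"),
               cbind(ctx, measure_class = "gwr"))
  reg$units <- unname(.MEASURE_CLASSES[reg$measure_class])
  rownames(reg) <- measureId(reg)
  reg
}

#' Canonical measure identifier
#'
#' @param key data.frame with columns \code{measure_class},
#'   \code{hemisphere}, \code{structure}.
#' @return character vector, e.g. \code{"volume.left.Hippocampus"}.
#' @export
measureId <- function(key) {
  paste(key$measure_class, key$hemisphere, key$structure, sep = ".")
}

.DURATIONS <- data.frame(
  scan_type = c("ADNI", "CS", "CS", "CS", "CS", "CS"),
  resolution_mm = c(1.0, 1.0, 0.8, 0.9, 1.1, 1.2),
  duration_s = c(312L, 72L, 109L, 86L, 61L, 49L)
)

#' Scan duration registry
#'
#' Acquisition durations of the study's T1-weighted protocols: the 1.0 mm
#' ADNI MPRAGE (5'12" = 312 s) and compressed-sensing (CS) scans at five
#' isotropic resolutions (1.0 mm 1'12"; 0.8 mm 1'49"; 0.9 mm 1'26";
#' 1.1 mm 1'01"; 1.2 mm 0'49").
#'
#' @return data.frame with columns \code{scan_type}, \code{resolution_mm},
#'   \code{duration_s}.
#' @seealso [scanDuration()] for single lookups.
#' @export
scanDurationRegistry <- function() .DURATIONS

#' Look up the acquisition duration of one scan protocol
#'
#' @param scanType "ADNI" or "CS".
#' @param resolution isotropic voxel size in mm.
#' @return duration in seconds.
#' @examples
#' scanDuration("ADNI", 1.0)  # 312
#' scanDuration("CS", 1.2)    # 49
#' @export
scanDuration <- function(scanType, resolution) {
  i <- which(.DURATIONS$scan_type == scanType &
             abs(.DURATIONS$resolution_mm - resolution) < 1e-9)
  if (length(i) != 1L)
    stop("no duration registered for scan type '", scanType,
         "' at ", resolution, " mm", call. = FALSE)
  .DURATIONS$duration_s[i]
}

# FreeSurfer label -> (structure, hemisphere) map, shipped as data
.asegStructureMap <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      path <- system.file("extdata", "aseg_structure_map.tsv",
                          package = "morphopool", mustWork = TRUE)
      map <<- read.delim(path, stringsAsFactors = FALSE)
    }
    map
  }
})
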