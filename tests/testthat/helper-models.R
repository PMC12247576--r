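# Shared builders for simulation-based tests.

# total relative-error SD that yields a given single-scan mean percent
# error: e1 = 100 * (2/sqrt(pi)) * sigma_tot
sigmaForE1 <- function(e1) (e1 / 100) * sqrt(pi) / 2

# model with a prescribed same-block correlation, carried entirely by the
# session component (so equicorrelation holds exactly across the break)
modelWithRho <- function(rho, e1 = 3.0, subjectCV = 0.1) {
  sTot <- sigmaForE1(e1)
  noiseModel(subjectCV = subjectCV,
             sigmaSession = sTot * sqrt(rho),
             sigmaBlock = 0,
             sigmaScan = sTot * sqrt(1 - rho))
}

noiselessModel <- function() noiseModel(subjectCV = 0.1)

# small registry subsets keep simulation loops cheap where measure count
# is not the quantity under test
volumeRegistry <- function() {
  reg <- defaultMeasureRegistry()
  reg[reg$measure_class == "volume", ]
}

smallRegistry <- function(n = 8) head(defaultMeasureRegistry(), n)

# hand-built two-subject, one-measure, k=1 long table
tinyLongTable <- function(values) {
  stopifnot(length(values) == 4L)
  data.frame(subject_id = rep(c("a", "b"), each = 2),
             group = "YA-CU", session = rep(1:2, 2), scan_type = "CS",
             resolution_mm = 1, block = "pre", type_index = 1L,
             order_index = 1L, duration_s = 72L,
             structure = "Hippocampus", hemisphere = "left",
             measure_class = "volume", units = "mm3", value = values)
}
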