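test_that("simulation is deterministic and subject substreams are stable", {
  m <- modelWithRho(0.2)
  d <- csOnlyDesign(4, nScans = 4)
  a <- simulateStudy(m, d, seed = 7, registry = smallRegistry())
  b <- simulateStudy(m, d, seed = 7, registry = smallRegistry())
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  # adding subjects leaves earlier subjects' draws untouched
  big <- simulateStudy(m, csOnlyDesign(7, nScans = 4), seed = 7,
                       registry = smallRegistry())
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(big)[, colnames(a)])
  # a different seed changes the data
  c2 <- simulateStudy(m, d, seed = 8, registry = smallRegistry())
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c2)))
})

test_that("a noiseless model returns the identical true value for every scan", {
  me <- simulateStudy(noiselessModel(), csOnlyDesign(3, nScans = 4),
                      seed = 1, registry = smallRegistry())
  v <- SummarizedExperiment::assay(me)
  cd <- scanInfo(me)
  for (s in unique(cd$subject_id)) {
    sub <- v[, cd$subject_id == s, drop = FALSE]
    expect_equal(apply(sub, 1, function(x) diff(range(x))),
                 rep(0, nrow(sub)), ignore_attr = TRUE)
  }
  # and zero percent error downstream
  errs <- schemeErrors(me, csPoolingScheme(2))
  expect_equal(errs$percent_error, rep(0, nrow(errs)))
})

test_that("grand means recover region means and group shifts (unit resolution bias)", {
  m <- modelWithRho(0.2)
  d <- defaultStudyDesign(groups = data.frame(
    group = c("YA-CU", "MCI/AD"), n = c(150L, 150L)))
  reg <- volumeRegistry()
  me <- simulateStudy(m, d, seed = 3, registry = reg)
  v <- SummarizedExperiment::assay(me)
  cd <- scanInfo(me)
  hip <- "volume.left.Hippocampus"
  for (g in c("YA-CU", "MCI/AD")) {
    subjMeans <- tapply(v[hip, cd$group == g],
                        cd$subject_id[cd$group == g], mean)
    target <- 4200 * (if (g == "MCI/AD") 0.85 else 1)
    se <- target * 0.1 / sqrt(length(subjMeans))
    expect_lt(abs(mean(subjMeans) - target), 3 * se)
  }
})

test_that("within-session inter-scan error correlation matches the model", {
  reg <- smallRegistry(16)
  for (rho in c(0, 0.3)) {
    # subjectCV = 0 so relative deviations from each scan's cohort mean
    # isolate the error components
    m <- modelWithRho(rho, subjectCV = 0)
    me <- simulateStudy(m, csOnlyDesign(250, nScans = 4), seed = 11,
                        registry = reg)
    v <- SummarizedExperiment::assay(me)
    cd <- scanInfo(me)
    s1 <- cd$session == 1
    rs <- sapply(seq_len(nrow(reg)), function(mi) {
      d1 <- v[mi, s1 & cd$type_index == 1]
      d2 <- v[mi, s1 & cd$type_index == 2]
      cor(d1 / mean(d1), d2 / mean(d2))
    })
    expect_lt(abs(mean(rs) - rho), 0.05)
  }
})

test_that("pathologically large error SDs trigger the resample-then-fail policy", {
  # a huge block SD makes some cells non-positive in a way no per-scan
  # redraw can repair (sigmaScan = 0), so the 100-pass limit must fire
  m <- noiseModel(subjectCV = 0, sigmaBlock = 50, sigmaScan = 0)
  expect_error(
    suppressWarnings(simulateStudy(m, csOnlyDesign(2, nScans = 2),
                                   seed = 1,
                                   registry = smallRegistry(2))),
    "non-positive|redraws")
})

test_that("group noise scaling multiplies the error of the scaled group", {
  m <- modelWithRho(0)
  m@groupNoiseScale <- c(`YA-CU` = 1, `MCI/AD` = 1.25)
  d <- defaultStudyDesign(groups = data.frame(
    group = c("YA-CU", "MCI/AD"), n = c(150L, 150L)))
  me <- simulateStudy(m, d, seed = 9, registry = smallRegistry(16))
  errs <- schemeErrors(me, csPoolingScheme(1))
  s <- summarizeErrors(errs, grouping = "group")
  ratio <- s$mean_pct[s$level == "MCI/AD"] / s$mean_pct[s$level == "YA-CU"]
  expect_lt(abs(ratio - 1.25), 0.05 * 1.25)
})
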