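test_that("comparing a scheme with itself yields zero deltas and no significance", {
  me <- simulateStudy(modelWithRho(0.2), csOnlyDesign(10, nScans = 2),
                      seed = 4, registry = smallRegistry())
  e <- schemeErrors(me, csPoolingScheme(1))
  suppressMessages(cc <- compareSchemes(e, e))
  expect_equal(cc@perMeasure$delta, rep(0, nrow(cc@perMeasure)))
  expect_equal(cc@meanDelta, 0)
  expect_equal(cc@fractionImproved, 50)  # ties counted half
  expect_equal(cc@fractionSignificant, 0)
  expect_true(all(cc@perMeasure$p_value == 1))
})

test_that("swapping reference and candidate negates deltas, keeps p-values", {
  me <- simulateStudy(modelWithRho(0), csOnlyDesign(20, nScans = 4),
                      seed = 6, registry = smallRegistry())
  a <- schemeErrors(me, csPoolingScheme(1))
  b <- schemeErrors(me, csPoolingScheme(4))
  ab <- compareSchemes(a, b)
  ba <- compareSchemes(b, a)
  expect_equal(ab@perMeasure$delta, -ba@perMeasure$delta)
  expect_equal(ab@perMeasure$p_value, ba@perMeasure$p_value)
  expect_equal(ab@fractionImproved, 100 - ba@fractionImproved)
})

test_that("pooling four scans beats a single scan for nearly all measures", {
  me <- simulateStudy(modelWithRho(0), csOnlyDesign(40, nScans = 4),
                      seed = 8, registry = defaultMeasureRegistry())
  cc <- compareSchemes(schemeErrors(me, csPoolingScheme(1)),
                       schemeErrors(me, csPoolingScheme(4)))
  expect_gt(cc@fractionImproved, 90)
  expect_gt(cc@meanDelta, 0)
})

test_that("pooling curve at k = 1 reproduces the single-scan summary exactly", {
  me <- simulateStudy(modelWithRho(0.2), csOnlyDesign(15, nScans = 8),
                      seed = 10, registry = smallRegistry())
  pc <- poolingCurve(me, ks = c(1L, 2L, 4L, 8L), reference = NULL)
  s1 <- summarizeErrors(schemeErrors(me, csPoolingScheme(1)))
  expect_equal(pc$summary$mean_pct[pc$summary$k == 1], s1$mean_pct)
  expect_equal(pc$summary$expected_sqrt_pct,
               s1$mean_pct / sqrt(c(1, 2, 4, 8)))
  expect_equal(pc$summary$duration_s, c(72, 144, 288, 576))
})

test_that("a noiseless study yields zero error at every pooling depth", {
  me <- simulateStudy(noiselessModel(), csOnlyDesign(3, nScans = 8),
                      seed = 1, registry = smallRegistry(4))
  pc <- poolingCurve(me, reference = NULL)
  expect_equal(pc$summary$mean_pct, rep(0, 4))
})

test_that("break contrast is a constructed tie when scans 2 and 5 are copies", {
  # two subjects, one measure; scan 5 duplicates scan 2 exactly
  long <- expand.grid(type_index = c(1L, 2L, 5L),
                      subject_id = c("a", "b"), session = 1:2,
                      stringsAsFactors = FALSE)
  base <- ifelse(long$subject_id == "a", 100, 200) +
    2.5 * long$session
  long$value <- base + ifelse(long$type_index == 1, 0, 7)
  long$group <- "YA-CU"; long$scan_type <- "CS"
  long$resolution_mm <- 1
  long$block <- ifelse(long$type_index <= 4, "pre", "post")
  long$order_index <- long$type_index; long$duration_s <- 72L
  long$structure <- "Hippocampus"; long$hemisphere <- "left"
  long$measure_class <- "volume"; long$units <- "mm3"
  me <- MorphoExperiment(long)
  suppressMessages(cc <- breakContrast(me))
  expect_equal(cc@meanDelta, 0)
  expect_equal(cc@fractionImproved, 50)
})

test_that("a block component makes the break pair beat the serial pair", {
  m <- noiseModel(subjectCV = 0.1, sigmaSession = 0,
                  sigmaBlock = 0.02, sigmaScan = 0.02)
  me <- simulateStudy(m, csOnlyDesign(300, nScans = 8), seed = 5,
                      registry = defaultMeasureRegistry())
  cc <- breakContrast(me)
  # closed form: serial shares session+block, break halves the block term
  b2 <- 0.02^2; s2 <- 0.02^2
  eSerial <- 100 * sqrt(2 * (b2 + s2 / 2)) * sqrt(2 / pi)
  eBreak <- 100 * sqrt(2 * (b2 / 2 + s2 / 2)) * sqrt(2 / pi)
  expect_equal(cc@meanDelta, eSerial - eBreak, tolerance = 0.05)
  expect_gt(cc@fractionImproved, 95)
})

test_that("multi-resolution contrast responds to resolution noise scaling", {
  # uniform resolution parameters: no systematic difference
  me <- simulateStudy(modelWithRho(0.2),
                      defaultStudyDesign(groups = data.frame(
                        group = "OA-CU", n = 150L)),
                      seed = 7, registry = smallRegistry(16))
  cc <- multiresContrast(me)
  sem <- sd(cc@perMeasure$delta) / sqrt(nrow(cc@perMeasure))
  expect_lt(abs(cc@meanDelta), 4 * sem + 1e-12)

  # noisier non-1.0 mm scans make multi-resolution pooling worse
  m2 <- modelWithRho(0)
  m2@resolutionNoiseScale <- c(`0.8` = 1.5, `0.9` = 1.5, `1` = 1,
                               `1.1` = 1.5, `1.2` = 1.5)
  me2 <- simulateStudy(m2, defaultStudyDesign(groups = data.frame(
    group = "OA-CU", n = 200L)), seed = 7,
    registry = smallRegistry(16))
  cc2 <- multiresContrast(me2)
  sTot <- sigmaForE1(3)
  e10 <- 100 * sqrt(2 * sTot^2 / 4) * sqrt(2 / pi)
  eMr <- 100 * sqrt(2 * (1.5 * sTot)^2 / 4) * sqrt(2 / pi)
  expect_lt(cc2@meanDelta, 0)  # candidate (multires) is worse
  expect_equal(abs(cc2@meanDelta), eMr - e10, tolerance = 0.05)
})

test_that("subgroup summaries restrict to groups and report reductions", {
  me <- simulateStudy(modelWithRho(0), defaultStudyDesign(),
                      seed = 12, registry = smallRegistry(8))
  ref <- schemeErrors(me, csPoolingScheme(1))
  cand <- schemeErrors(me, csPoolingScheme(4))
  subs <- subgroupSummaries(cand, reference = ref)
  expect_equal(sort(subs$level), sort(c("YA-CU", "OA-CU", "MCI/AD")))
  # sqrt-k law: ~50% reduction in every group
  expect_true(all(abs(subs$reduction_pct - 50) < 3))
  # a single-group table reproduces the overall summary
  one <- subgroupSummaries(cand[cand$group == "OA-CU", ])
  overall <- summarizeErrors(cand[cand$group == "OA-CU", ], "overall")
  expect_equal(one$mean_pct, overall$mean_pct)
})

test_that("under the null the significant fraction is near alpha", {
  # two disjoint single-scan schemes from the same session are iid under
  # rho = 0: the paired test should reject at ~5%
  m <- modelWithRho(0)
  reg <- smallRegistry(20)
  pvals <- c()
  for (r in 1:60) {
    me <- simulateStudy(m, csOnlyDesign(40, nScans = 2),
                        seed = 5000 + r, registry = reg)
    cc <- compareSchemes(
      schemeErrors(me, csPoolingScheme(1, typeIndex = 1L)),
      schemeErrors(me, csPoolingScheme(1, typeIndex = 2L)))
    pvals <- c(pvals, cc@perMeasure$p_value)
  }
  frac <- 100 * mean(pvals < 0.05)
  expect_gt(frac, 3.0)
  expect_lt(frac, 7.0)
})
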