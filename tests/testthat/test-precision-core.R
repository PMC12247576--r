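test_that("percent error follows the absolute-difference-over-mean formula", {
  expect_equal(percentError(100, 100), 0)
  expect_equal(percentError(102, 98), 4)
  # hand arithmetic on realistic hippocampal volumes
  expect_equal(percentError(4208.3, 4102.7),
               100 * (4208.3 - 4102.7) / ((4208.3 + 4102.7) / 2))
  expect_error(percentError(1, -1), "non-positive")
  expect_error(percentError(Inf, 1), "finite")
})

test_that("percent error is symmetric, non-negative, zero iff equal, scale-invariant", {
  set.seed(101)
  for (i in 1:50) {
    v1 <- runif(1, 0.5, 5000)
    v2 <- runif(1, 0.5, 5000)
    c0 <- runif(1, 0.01, 100)
    pe <- percentError(v1, v2)
    expect_gte(pe, 0)
    expect_equal(pe, percentError(v2, v1))
    expect_equal(pe, percentError(c0 * v1, c0 * v2))
    expect_equal(pe == 0, v1 == v2)
  }
})

test_that("pooling averages exactly the selected scans", {
  long <- expand.grid(type_index = 1:4, subject_id = c("a", "b"),
                      session = 1:2, stringsAsFactors = FALSE)
  long$value <- ifelse(long$subject_id == "a",
                       c(10, 12, 14, 16)[long$type_index] +
                         (long$session - 1) * 2,
                       100 + long$type_index)
  long$group <- "YA-CU"; long$scan_type <- "CS"; long$resolution_mm <- 1
  long$block <- ifelse(long$type_index <= 2, "pre", "post")
  long$order_index <- long$type_index; long$duration_s <- 72L
  long$structure <- "Hippocampus"; long$hemisphere <- "left"
  long$measure_class <- "volume"; long$units <- "mm3"
  me <- MorphoExperiment(long)

  p4 <- poolEstimates(me, csPoolingScheme(4))
  a1 <- p4$value[, p4$info$subject_id == "a" & p4$info$session == 1]
  expect_equal(unname(a1), mean(c(10, 12, 14, 16)))  # 13
  # k = 1 is the identity on the single selected scan
  p1 <- poolEstimates(me, csPoolingScheme(1))
  a11 <- p1$value[, p1$info$subject_id == "a" & p1$info$session == 1]
  expect_equal(unname(a11), 10)
  # scheme errors equal the direct percent error of the raw values
  e1 <- schemeErrors(me, csPoolingScheme(1))
  expect_equal(e1$percent_error[e1$subject_id == "a"],
               percentError(10, 12))
  expect_equal(e1$percent_error[e1$subject_id == "b"],
               percentError(101, 101))
})

test_that("copying session 1 into session 2 gives exactly zero error", {
  long <- tinyLongTable(c(123.4, 123.4, 99.9, 99.9))
  me <- MorphoExperiment(long)
  errs <- schemeErrors(me, csPoolingScheme(1))
  expect_equal(errs$percent_error, c(0, 0))
})

test_that("subjects with incomplete scan sets are dropped with a warning", {
  l2 <- tinyLongTable(c(100, 101, 200, 201))[1:3, ]  # b lacks session 2
  me <- MorphoExperiment(l2)
  expect_warning(p <- poolEstimates(me, csPoolingScheme(1)),
                 "incomplete")
  expect_equal(sort(unique(p$info$subject_id)), "a")
})

test_that("error summaries use sample SD with the documented conventions", {
  rec <- data.frame(subject_id = c("a", "b", "c"), group = "YA-CU",
                    measure = "m1", structure = "x", hemisphere = "left",
                    measure_class = "volume", scheme = "s",
                    percent_error = c(1, 2, 3))
  s <- summarizeErrors(rec, grouping = "measure")
  expect_equal(s$mean_pct, 2)
  expect_equal(s$sd_pct, 1)  # sample SD, n - 1
  expect_equal(s$sem_pct, 1 / sqrt(3))
  expect_warning(s1 <- summarizeErrors(rec[1, ], grouping = "measure"),
                 "single record")
  expect_equal(s1$sd_pct, 0)
  # overall aggregation is two-stage: per-measure means first
  rec2 <- rbind(rec, transform(rec, measure = "m2",
                               percent_error = c(4, 4, 4)))
  ov <- summarizeErrors(rec2, grouping = "overall")
  expect_equal(ov$mean_pct, mean(c(2, 4)))
  expect_equal(ov$n, 2L)
  expect_equal(ov$sd_pct, sd(c(2, 4)))
})

test_that("summaries by group track the grouping structure", {
  me <- simulateStudy(modelWithRho(0), defaultStudyDesign(),
                      seed = 2, registry = smallRegistry(4))
  s <- summarizeErrors(schemeErrors(me, csPoolingScheme(1)),
                       grouping = "group")
  expect_equal(sort(s$level), sort(c("YA-CU", "OA-CU", "MCI/AD")))
  expect_equal(s$n, rep(4L, 3))  # n counts measures under two-stage
})

test_that("sqrt-k curve and its printed expected reduction", {
  expect_equal(expectedSqrtCurve(3.01, 1), 3.01)
  expect_equal(expectedSqrtCurve(3.01, 4), 1.505)
  expect_equal(round(100 * (1 - expectedSqrtCurve(1, 8) / 1)), 65)
  expect_error(expectedSqrtCurve(3, 0), "k must be")
  expect_error(expectedSqrtCurve(-1, 2), "e1 must be")
})

test_that("equicorrelated pooled SD closed form and limits", {
  expect_equal(equicorrPooledSD(2, 0, 4), 2 / sqrt(4))
  expect_equal(equicorrPooledSD(2, 1, 8), 2)
  expect_equal(equicorrPooledSD(1, 0.2, 4), sqrt(1.6 / 4))
  expect_error(equicorrPooledSD(1, 1.2, 4), "rho")
})

test_that("relative reduction compares aligned per-measure means", {
  rec <- data.frame(subject_id = rep(c("a", "b"), 2),
                    group = "YA-CU",
                    measure = rep(c("m1", "m2"), each = 2),
                    structure = "x", hemisphere = "left",
                    measure_class = "volume", scheme = "ref",
                    percent_error = c(2, 2, 4, 4))
  cand <- transform(rec, scheme = "cand",
                    percent_error = c(1, 1, 2, 2))
  rr <- relativeReduction(rec, cand)
  expect_equal(rr$perMeasure$percent_reduction, c(50, 50))
  expect_equal(rr$meanReduction, 50)
  same <- relativeReduction(rec, rec)
  expect_equal(same$meanDelta, 0)
  expect_equal(same$perMeasure$delta, c(0, 0))
  cand2 <- cand[cand$measure == "m1", ]
  expect_error(relativeReduction(rec, cand2), "different")
})

test_that("scheme durations resolve against the default design plan", {
  expect_equal(schemeDuration(csPoolingScheme(4)), 288L)   # 4'48"
  expect_equal(schemeDuration(csPoolingScheme(8)), 576L)   # 9'36"
  expect_equal(schemeDuration(multiresScheme()), 305L)     # 5'05"
  expect_equal(schemeDuration(adniScheme()), 312L)         # 5'12"
  expect_equal(schemeDuration(serialPairScheme()), 144L)
  bad <- poolingScheme("cs16", scanType = "CS", resolutions = 1.0,
                       k = 16L)
  expect_error(schemeDuration(bad), "expected 16")
})

test_that("mean percent error matches the half-normal link on simulation", {
  me <- simulateStudy(modelWithRho(0), csOnlyDesign(200, nScans = 2),
                      seed = 13, registry = smallRegistry(16))
  p <- poolEstimates(me, csPoolingScheme(1))
  s1 <- p$info$session == 1
  o2 <- match(p$info$subject_id[s1], p$info$subject_id[!s1])
  A <- p$value[, s1]; B <- p$value[, !s1][, o2]
  delta <- 200 * (A - B) / (A + B)  # percent session difference
  meanErr <- mean(abs(delta))
  expect_equal(meanErr, sqrt(2 / pi) * sd(as.vector(delta)),
               tolerance = 0.03)
})

test_that("fully shared error yields rho clipped to one", {
  m <- noiseModel(subjectCV = 0.1, sigmaSession = 0.02, sigmaScan = 0)
  me <- simulateStudy(m, csOnlyDesign(30, nScans = 4), seed = 3,
                      registry = smallRegistry(4))
  set.seed(1)
  r <- estimateRho(me, maxK = 4, nBoot = 0)
  expect_equal(r$rho, 1)
})
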