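test_that("default design matches the cluster-scanning protocol", {
  d <- defaultStudyDesign()
  sp <- scanPlan(d)
  expect_equal(nrow(sp), 17L)                 # 1 ADNI + 16 CS
  expect_equal(sum(sp$scan_type == "ADNI"), 1L)
  expect_equal(sum(sp$scan_type == "CS"), 16L)
  expect_equal(groupTable(d)$n, c(12L, 18L, 10L))
  expect_equal(groupTable(d)$group, c("YA-CU", "OA-CU", "MCI/AD"))
  expect_equal(d@sessions, 2L)

  cs1 <- sp[sp$scan_type == "CS" & sp$resolution_mm == 1.0, ]
  expect_equal(nrow(cs1), 8L)
  expect_equal(sort(cs1$type_index), 1:8)
  expect_equal(cs1$block[order(cs1$type_index)],
               rep(c("pre", "post"), each = 4))

  mr <- sp[sp$scan_type == "CS" & sp$resolution_mm != 1.0, ]
  expect_equal(nrow(mr), 8L)
  expect_equal(sort(unique(mr$resolution_mm)), c(0.8, 0.9, 1.1, 1.2))
  # each resolution appears once before and once after the break
  expect_true(all(table(mr$resolution_mm, mr$block) == 1))
})

test_that("order indices are unique and durations come from the registry", {
  sp <- scanPlan(defaultStudyDesign())
  expect_false(anyDuplicated(sp$order_index) > 0)
  expect_equal(sp$duration_s,
               mapply(scanDuration, sp$scan_type, sp$resolution_mm),
               ignore_attr = TRUE)
  # whole-session accounting is deterministic
  expect_equal(sessionDuration(defaultStudyDesign()),
               312 + 8 * 72 + 2 * (109 + 86 + 61 + 49))
})

test_that("design validity rejects malformed plans", {
  plan <- scanPlan(defaultStudyDesign())
  bad <- plan
  bad$order_index[2] <- bad$order_index[1]
  expect_error(studyDesign(groupTable(defaultStudyDesign()),
                           scanPlan = bad), "unique")
  expect_error(studyDesign(data.frame(group = "YA-CU", n = -1L),
                           scanPlan = plan), "group sizes")
})

test_that("CS-only helper design splits scans around the break", {
  d <- csOnlyDesign(5, nScans = 8)
  sp <- scanPlan(d)
  expect_equal(sum(groupTable(d)$n), 5L)
  expect_equal(sp$block, rep(c("pre", "post"), each = 4))
  expect_equal(sp$type_index, 1:8)
})
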