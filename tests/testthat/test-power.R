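# Independent closed-form oracle for the normal-approximation sample
# size, coded directly from the textbook formula (kept free of any
# package internals).
oracleN <- function(change, err, years, alpha, power, twoGroup) {
  sigmaTp <- err * sqrt(pi / 2) / sqrt(2)
  sigmaD2 <- 2 * sigmaTp^2
  m <- if (twoGroup) 2 else 1
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  ceiling(z^2 * m * sigmaD2 / (change * years)^2)
}

test_that("half-normal bridge from mean percent error to difference SD", {
  expect_equal(errorToSD(0), 0)
  expect_equal(errorToSD(2.5), 2.5 * sqrt(pi / 2))
  expect_equal(errorToSD(2.5), 3.1333, tolerance = 1e-4)
  expect_error(errorToSD(-1), ">= 0")
})

test_that("required n matches the independent closed-form oracle on a grid", {
  grid <- expand.grid(change = c(1, 2, 3, 4, 6),
                      err = c(1, 1.5, 2.5, 3),
                      years = c(1, 2.5),
                      alpha = 0.05, power = c(0.8, 0.9),
                      twoGroup = c(FALSE, TRUE))
  grid <- grid[seq_len(100), ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_identical(
      requiredN(annualChange = g$change, perTimepointError = g$err,
                followUpYears = g$years, alpha = g$alpha,
                power = g$power,
                design = if (g$twoGroup) "two-group" else "one-group"),
      as.integer(oracleN(g$change, g$err, g$years, g$alpha, g$power,
                         g$twoGroup)))
  }
})

test_that("required n scales as error squared and is monotone", {
  n1 <- requiredN(3, 2.5)
  n2 <- requiredN(3, 1.25)
  # halving the error quarters n, up to ceiling granularity
  expect_lte(abs(n2 - n1 / 4), 1)
  errs <- c(0.5, 1, 1.5, 2, 3)
  ns <- sapply(errs, function(e) requiredN(3, e))
  expect_true(all(diff(ns) >= 0))  # non-decreasing in error
  chg <- c(1, 2, 3, 4, 5)
  ns2 <- sapply(chg, function(a) requiredN(a, 2.5))
  expect_true(all(diff(ns2) <= 0))  # non-increasing in change
  expect_error(requiredN(0, 2.5), "effect")
  expect_error(requiredN(3, 2.5, alpha = 1.2), "alpha")
})

test_that("biological heterogeneity adds to the change variance", {
  expect_gt(requiredN(3, 2.5, sdBiological = 2), requiredN(3, 2.5))
})

test_that("precision budget picks the largest feasible k and scales the error", {
  pb <- precisionBudget(312, rho = 0, e1 = 3.01)
  expect_equal(pb$k, 4L)  # floor(312 / 72)
  expect_equal(pb$expectedError, 3.01 / 2)
  expect_equal(pb$durationUsed, 288L)
  pb1 <- precisionBudget(72, rho = 0.3, e1 = 3.01)
  expect_equal(pb1$k, 1L)
  expect_equal(pb1$expectedError, 3.01)
  # rho = 1: pooling is useless at every feasible budget
  for (b in c(72, 200, 600))
    expect_equal(precisionBudget(b, rho = 1, e1 = 3.01)$expectedError,
                 3.01)
  expect_error(precisionBudget(60, 0, 3), "below one")
})

test_that("expected budgeted error is monotone in budget and rho", {
  budgets <- c(72, 144, 288, 576, 1000)
  errs <- sapply(budgets, function(b)
    precisionBudget(b, rho = 0.2, e1 = 3)$expectedError)
  expect_true(all(diff(errs) <= 0))
  rhos <- c(0, 0.2, 0.5, 0.8, 1)
  errs2 <- sapply(rhos, function(r)
    precisionBudget(576, rho = r, e1 = 3)$expectedError)
  expect_true(all(diff(errs2) >= 0))
})
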