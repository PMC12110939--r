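test_that("Zernike fits recover analytic spectra", {
  # pure plane in x: only the horizontal tilt term
  dT <- analyticDiff(function(X, Y) 5 * X)
  cf <- zernikeFit(dT, Zone(4))
  expect_gt(abs(cf[["Z1.1"]]), 4)
  others <- cf[setdiff(names(cf), c("Z1.1"))]
  expect_lt(max(abs(others)), 0.01)

  # A cos(2 theta) r^2 is exactly the cos-astigmatism term
  dA <- analyticDiff(function(X, Y) 10 * (X^2 - Y^2) / (X^2 + Y^2 + 1e-12) *
                       (sqrt(X^2 + Y^2))^2)
  cfA <- zernikeFit(dA, Zone(4))
  expect_gt(abs(cfA[["Z2.2"]]), 1)
  expect_lt(abs(cfA[["Z2.-2"]]), 1e-6)
  expect_lt(max(abs(cfA[c("Z1.-1", "Z1.1", "Z3.1", "Z4.4")])), 1e-6)
})

test_that("canonical analytic fields classify as constructed", {
  dZ <- analyticDiff(function(X, Y) matrix(0, nrow(X), ncol(X)))
  lz <- classifyPattern(dZ)
  expect_equal(lz@label, "flat")
  expect_equal(unname(lz@scores["flat"]), 1)

  expect_equal(classifyPattern(analyticDiff(function(X, Y) 5 * X))@label,
               "tilt")
  dA <- analyticDiff(function(X, Y) {
    th <- atan2(Y, X); r2 <- X^2 + Y^2
    10 * cos(2 * th) * r2
  })
  expect_equal(classifyPattern(dA)@label, "four_leaf")
  dC <- analyticDiff(function(X, Y) 20 * exp(-(X^2 + Y^2) / (2 * 0.8^2)))
  expect_equal(classifyPattern(dC)@label, "cone")
  # a negative (fellow-eye bulging) cone is still a cone
  dCn <- analyticDiff(function(X, Y) -20 * exp(-(X^2 + Y^2) / (2 * 0.8^2)))
  expect_equal(classifyPattern(dCn)@label, "cone")
})

test_that("scores are a normalized distribution with argmax at the label", {
  for (pat in c("flat", "tilt", "cone", "four_leaf")) {
    m <- simulatePatternMap(pat, seed = 5, noiseSd = 1)
    lab <- classifyPattern(m$diff)
    expect_equal(sum(lab@scores), 1, tolerance = 1e-6)
    expect_true(all(lab@scores >= 0 & lab@scores <= 1))
    expect_equal(names(which.max(lab@scores)), lab@label)
  }
})

test_that("classification ignores piston and astigmatism survives rotation", {
  d <- simulatePatternMap("four_leaf", seed = 9)$diff
  dShift <- d; dShift@signed <- d@signed + 50
  expect_equal(classifyPattern(dShift)@label, "four_leaf")
  expect_equal(classifyPattern(dShift)@rms, classifyPattern(d)@rms,
               tolerance = 1e-9)

  # rotating the quadrant pattern by 45 degrees swaps the two astigmatism
  # terms but stays four_leaf
  d45 <- analyticDiff(function(X, Y) {
    th <- atan2(Y, X); r2 <- X^2 + Y^2
    10 * cos(2 * (th - pi / 4)) * r2
  })
  expect_equal(classifyPattern(d45)@label, "four_leaf")
})

test_that("mixed fields with no dominant group are irregular", {
  dMix <- analyticDiff(function(X, Y) {
    th <- atan2(Y, X); r <- sqrt(X^2 + Y^2)
    4 * X + 8 * cos(2 * th) * r^2 + 6 * cos(3 * th) * r^3
  })
  expect_equal(classifyPattern(dMix)@label, "irregular")
})

test_that("the labeled scenario suite is classified correctly", {
  # noiseless canonical fields: every one of 25 maps per class
  for (pat in c("flat", "tilt", "cone", "four_leaf")) {
    labs <- vapply(1:25, function(s) {
      classifyPattern(simulatePatternMap(pat, seed = s)$diff)@label
    }, character(1))
    expect_true(all(labs == pat), info = pat)
  }
  # at noise SD 2 um, at least 90% per class
  for (pat in c("flat", "tilt", "cone", "four_leaf")) {
    labs <- vapply(1:25, function(s) {
      classifyPattern(simulatePatternMap(pat, seed = 2000 + s,
                                         noiseSd = 2)$diff)@label
    }, character(1))
    expect_gte(mean(labs == pat), 0.9)
  }
})

test_that("insufficient coverage is refused", {
  d <- analyticDiff(function(X, Y) X)
  d@signed[, 1:80] <- NA
  expect_error(classifyPattern(d), "coverage")
})
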