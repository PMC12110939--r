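test_that("manual evaluation reproduces constructed alignments exactly", {
  left <- renderSurface(typicalCornea(footprint = 9), n = 100, side = "OS")
  right <- applyFlip(left)
  ev <- evaluateRegistration(left, right, RegistrationParams(flip = TRUE))
  expect_equal(vbs(ev$report), 0)

  # a constant offset is cancelled exactly by dz
  right4 <- right; right4@values <- right4@values + 4
  ev0 <- evaluateRegistration(left, right4, RegistrationParams(flip = TRUE))
  expect_equal(vbs(ev0$report), 4)
  ev4 <- evaluateRegistration(left, right4,
                              RegistrationParams(flip = TRUE, dz = 4))
  expect_equal(vbs(ev4$report), 0)

  # parameters at the bounds are evaluated, not clipped
  evb <- evaluateRegistration(left, right,
                              RegistrationParams(flip = TRUE, dx = 2))
  expect_gt(vbs(evb$report), 0)
})

test_that("the inner L1 plane fit attains the lattice brute-force minimum", {
  set.seed(13)
  n <- 20
  x <- runif(n^2, -2, 2); y <- runif(n^2, -2, 2)
  for (k in 1:3) {
    d <- 2 - 1.5 * x + 0.8 * y + rnorm(n^2) + 5 * (runif(n^2) < 0.1)
    fit <- fitL1Plane(x, y, d)
    # exhaustive lattice over (dz, a, b)
    best <- Inf
    for (dz in seq(0, 4, by = 0.25)) {
      for (a in seq(-3, 0, by = 0.25)) {
        for (b in seq(-1, 2.5, by = 0.25)) {
          v <- mean(abs(d - dz - a * x - b * y))
          if (v < best) best <- v
        }
      }
    }
    expect_lte(fit$mean_abs, best + 1e-9)
  }
})

test_that("auto-registration solves the perfect mirror twin to numerical zero", {
  p <- makePair(PairSpec(seed = 1L, base = typicalCornea()))
  fit <- autoRegister(p$os, p$od)
  expect_lt(vbs(fit@report), 1e-6)
  expect_lt(abs(fit@params@dx), 0.01)
  expect_lt(abs(fit@params@dy), 0.01)
  expect_lt(abs(fit@params@rot), 0.05)
  expect_true(fit@params@flip)
})

test_that("accepted-step trace is monotone and runs are deterministic", {
  p <- makePair(PairSpec(seed = 41L, base = typicalCornea(), noiseSd = 1,
                         sharedIrrRms = 3,
                         misalign = RegistrationParams(dx = 0.3, rot = 2)))
  f1 <- autoRegister(p$os, p$od)
  expect_gt(nrow(f1@trace), 1)
  expect_true(all(diff(f1@trace$vbs_um) <= 0))
  f2 <- autoRegister(p$os, p$od)
  expect_identical(f1@trace, f2@trace)
  expect_identical(f1@params, f2@params)
})

test_that("left/right exchange reaches the same optimum on noiseless pairs", {
  for (s in c(51L, 52L)) {
    p <- makePair(PairSpec(seed = s, base = typicalCornea(), sharedIrrRms = 3,
                           misalign = RegistrationParams(dx = 0.2, dy = -0.15,
                                                         rot = 1.5)))
    fLR <- autoRegister(p$os, p$od)
    fRL <- autoRegister(p$od, p$os)
    expect_lt(abs(vbs(fLR@report) - vbs(fRL@report)), 0.05)
  }
})

test_that("symmetry mode auto prefers the anatomically correct flip", {
  # a torically asymmetric pair: mirror symmetry fits, direct does not
  p <- makePair(PairSpec(seed = 61L, base = typicalCornea(cyl = 60, axis = 25),
                         sharedIrrRms = 3))
  fit <- autoRegister(p$os, p$od,
                      control = registrationControl(symmetry = "auto"))
  expect_true(fit@params@flip)
  expect_lt(vbs(fit@report), 0.5)
  # direct mode on the same pair is clearly worse
  fitD <- autoRegister(p$os, p$od,
                       control = registrationControl(symmetry = "direct"))
  expect_gt(vbs(fitD@report), vbs(fit@report))
})

test_that("registration refuses pairs with no usable overlap", {
  v <- matrix(NA_real_, 140, 140); v[1:20, 1:20] <- 0
  left <- ElevationGrid(v, side = "OS")
  right <- renderSurface(CorneaSpec())
  expect_error(autoRegister(left, right), "insufficient overlap")
})

test_that("the analytic noise floor matches measured VBS at a known transform", {
  # pure-noise pair evaluated at the exact aligning parameters: the
  # resampling-aware expectation must match the measurement within a few
  # percent at ~1250 points
  for (s in c(71L, 72L)) {
    mis <- RegistrationParams(dx = 0.23, dy = -0.12, rot = 2.4)
    p <- makePair(PairSpec(seed = s, base = typicalCornea(), noiseSd = 2,
                           misalign = mis))
    al <- p$truth$aligning
    ev <- evaluateRegistration(p$os, p$od, al)
    fl <- noiseFloorVBS(al, applyFlip(p$os), Zone(4), 2)
    expect_lt(fl, 2 * 2 * 2 / sqrt(pi))
    expect_equal(vbs(ev$report), fl, tolerance = 0.08)
  }
})
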