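test_that("conicoid sagitta matches the closed form and its sphere limit", {
  # closed-form oracle z = r^2 / (R (1 + sqrt(1 - (1+Q) r^2 / R^2)))
  r <- 2; R <- 7.8; Q <- -0.25
  expect_equal(conicSagitta(r, R, Q),
               r^2 / (R * (1 + sqrt(1 - (1 + Q) * r^2 / R^2))))
  # sphere: exact circular sagitta R - sqrt(R^2 - r^2)
  expect_equal(conicSagitta(1.7, 7.8, 0), 7.8 - sqrt(7.8^2 - 1.7^2))
  # out of domain -> NA
  expect_true(is.na(conicSagitta(10, 3, 0.5)))
})

test_that("rendering the reference sphere itself gives zero elevation", {
  g <- renderSurface(CorneaSpec(apicalRadius = 7.8, q = 0),
                     referenceRadius = 7.8, n = 140)
  v <- elevationValues(g)
  expect_lt(max(abs(v), na.rm = TRUE), 1e-9)
  # footprint: only the 12 mm disc is measured
  pc <- physicalCoords(g)
  expect_identical(validMask(g), sqrt(pc$x^2 + pc$y^2) <= 6)
  expect_lt(sum(validMask(g)), 140^2)  # corners are missing
})

test_that("a cone bump adds exactly its amplitude at its center", {
  base <- CorneaSpec(cylAmp = 20, cylAxis = 40)
  withCone <- CorneaSpec(cylAmp = 20, cylAxis = 40,
                         cone = list(amplitude_um = 20, sigma_mm = 0.8,
                                     center_x_mm = 0, center_y_mm = 0))
  refR <- bestFitSphereRadius(base)
  g0 <- renderSurface(base, referenceRadius = refR, n = 140)
  g1 <- renderSurface(withCone, referenceRadius = refR, n = 140)
  d <- elevationValues(g1) - elevationValues(g0)
  pc <- physicalCoords(g0)
  bump <- 20 * exp(-(pc$x^2 + pc$y^2) / (2 * 0.8^2))
  ok <- !is.na(d)
  expect_equal(d[ok], bump[ok], tolerance = 1e-12)
  expect_equal(max(d, na.rm = TRUE), 20, tolerance = 1e-2)
})

test_that("best-fit sphere reference keeps elevations on the device scale", {
  g <- renderSurface(CorneaSpec(), n = 140)  # default best-fit reference
  expect_lt(max(abs(elevationValues(g)), na.rm = TRUE), 60)
  # fitting a sphere to a sphere returns its radius
  expect_equal(bestFitSphereRadius(CorneaSpec(apicalRadius = 7.4, q = 0)),
               7.4, tolerance = 1e-3)
})

test_that("a perfect twin pair registers to zero and carries its ground truth", {
  p <- makePair(PairSpec(seed = 2L, base = typicalCornea()))
  expect_equal(p$truth$vbs4, 0)
  expect_equal(p$truth$vbs6, 0)
  fit <- autoRegister(p$os, p$od)
  expect_lt(vbs(fit@report), 1e-6)
  expect_identical(eyeSide(p$od), "OD")
  expect_identical(eyeSide(p$os), "OS")
})

test_that("the aligning ground truth undoes the injected misalignment", {
  mis <- RegistrationParams(dx = 0.3, dy = -0.2, rot = 4, dz = 6,
                            tiltX = 5, tiltY = -8)
  p <- makePair(PairSpec(seed = 3L, base = typicalCornea(), misalign = mis))
  ev <- evaluateRegistration(p$os, p$od, p$truth$aligning)
  expect_lt(vbs(ev$report), 0.05)  # interpolation residual only
  # and the zero-parameter alignment is visibly worse
  ev0 <- evaluateRegistration(p$os, p$od, RegistrationParams(flip = TRUE))
  expect_gt(vbs(ev0$report), 20 * vbs(ev$report))
})

test_that("noise-only pairs sit at the folded-normal noise floor when aligned", {
  # E|N(0, sigma*sqrt(2))| = 2 sigma / sqrt(pi), exact at a lattice-aligned
  # registration (both eyes carry independent noise of sd sigma)
  for (sigma in c(0.5, 2)) {
    p <- makePair(PairSpec(seed = 100L + as.integer(10 * sigma),
                           base = typicalCornea(), noiseSd = sigma))
    ev <- evaluateRegistration(p$os, p$od, RegistrationParams(flip = TRUE))
    expect_equal(vbs(ev$report), 2 * sigma / sqrt(pi), tolerance = 0.05)
  }
})

test_that("pair generation is deterministic and delta fields perturb one eye", {
  s <- PairSpec(seed = 7L, n = 80L, noiseSd = 1, irrRms = 2,
                base = typicalCornea(footprint = 7))
  p1 <- makePair(s); p2 <- makePair(s)
  expect_identical(elevationValues(p1$od), elevationValues(p2$od))
  expect_identical(elevationValues(p1$os), elevationValues(p2$os))

  pd <- makePair(PairSpec(seed = 7L, n = 80L,
                          base = typicalCornea(footprint = 7),
                          delta = list(cylAmp = 10, cylAxis = 5)))
  expect_gt(pd$truth$vbs4, 0.1)
})

test_that("cohort generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- makeCohort(1, 1, dir = d1, scenario = "separated", seed = 3, n = 60)
  m2 <- makeCohort(1, 1, dir = d2, scenario = "separated", seed = 3, n = 60)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_equal(m1$label, c("normal", "keratoconus"))
  # manifest is loadable and complete
  rd <- readManifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(rd), 2)
  # ground truth is attached per pair
  tr <- attr(m1, "truth")
  expect_named(tr, m1$pair_id)
  expect_gt(tr[["pair002"]]$vbs4, tr[["pair001"]]$vbs4)
})

test_that("the null scenario draws no cones and the separated scenario does", {
  d <- withr::local_tempdir()
  mN <- makeCohort(1, 1, dir = d, scenario = "null", seed = 4, n = 60)
  trN <- attr(mN, "truth")
  # with no cone, case and control truths are on the same scale
  expect_lt(trN[["pair002"]]$vbs4, 2 * trN[["pair001"]]$vbs4 + 5)
  mS <- makeCohort(1, 1, dir = d, scenario = "separated", seed = 4, n = 60)
  trS <- attr(mS, "truth")
  expect_gt(trS[["pair002"]]$vbs4, trN[["pair002"]]$vbs4)
})

test_that("canonical pattern maps are reproducible and labeled", {
  m1 <- simulatePatternMap("cone", seed = 12, noiseSd = 1)
  m2 <- simulatePatternMap("cone", seed = 12, noiseSd = 1)
  expect_identical(m1$diff@signed, m2$diff@signed)
  expect_equal(m1$label, "cone")
  expect_error(simulatePatternMap("blob"), "should be one of")
})
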