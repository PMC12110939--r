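test_that("difference maps obey the subtraction and mask contracts", {
  g <- renderSurface(typicalCornea(footprint = 7), n = 80)
  d0 <- differenceMap(g, g)
  expect_true(all(d0@signed[validMask(d0)] == 0))

  g3 <- g; g3@values <- g@values + 3
  d3 <- differenceMap(g, g3)  # right = left + 3 -> signed = -3
  expect_true(all(abs(d3@signed[validMask(d3)] + 3) < 1e-9))
  expect_true(all(abs(absoluteDifference(d3)[validMask(d3)] - 3) < 1e-9))

  # a missing quadrant in one eye masks exactly that quadrant
  gq <- g
  pc <- physicalCoords(g)
  quad <- pc$x > 0 & pc$y > 0
  gq@values[quad] <- NA
  dq <- differenceMap(gq, g)
  expect_identical(validMask(dq), validMask(g) & !quad)

  g2 <- renderSurface(CorneaSpec(footprint = 6), n = 60)
  expect_error(differenceMap(g, g2), "shapes differ")
  gsp <- g; gsp@spacing <- 0.2
  expect_error(differenceMap(g, gsp), "spacings differ")
  gc <- g; gc@center <- c(40, 40)
  expect_error(differenceMap(g, gc), "centers differ")
})

test_that("VBS matches closed forms on analytic fields", {
  # constant field: VBS = c in every zone
  dC <- analyticDiff(function(X, Y) matrix(2.75, nrow(X), ncol(X)))
  for (dz in c(2, 4, 6)) expect_equal(vbs(vbsReport(dC, Zone(dz))), 2.75)

  # radial field |d| = r: lattice enumeration is the oracle, continuum 2R/3
  dR <- analyticDiff(function(X, Y) sqrt(X^2 + Y^2))
  rep4 <- vbsReport(dR, Zone(4))
  n <- 140; ctr <- (n + 1) / 2; xs <- (seq_len(n) - ctr) * 0.1
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  expect_equal(vbs(rep4), mean(rr[rr <= 2]))
  expect_equal(vbs(rep4), 2 * 2 / 3, tolerance = 0.02)

  # a single 10 um point among zeros: VBS = 10 / n_points
  nIn <- countLatticeInZone(140, 0.1, 2)
  dS <- analyticDiff(function(X, Y) {
    ifelse(abs(X - 0.05) < 1e-9 & abs(Y - 0.05) < 1e-9, 10, 0)
  })
  expect_equal(vbs(vbsReport(dS, Zone(4))), 10 / nIn)
  expect_equal(reportNPoints(vbsReport(dS, Zone(4))), nIn)
})

test_that("zone reports carry coverage, volume and consistent rings", {
  d <- analyticDiff(function(X, Y) abs(X) + 0.5)
  rep <- vbsReport(d, Zone(4))
  expect_equal(reportCoverage(rep), 1)
  expect_equal(zoneVolume(rep), vbs(rep) * pi * 4 / 1000)
  rings <- ringSummary(rep)
  expect_equal(rings$inner_mm, c(0, 0.5, 1, 1.5))
  expect_equal(rings$outer_mm, c(0.5, 1, 1.5, 2))
  expect_true(all(rings$mean_abs_um <= rings$max_abs_um))
  # rings partition the zone: counts and weighted ring means reassemble VBS
  expect_equal(sum(rings$n_points), reportNPoints(rep))
  expect_equal(sum(rings$mean_abs_um * rings$n_points) / sum(rings$n_points),
               vbs(rep))
})

test_that("VBS refuses empty zones and insufficient coverage, reporting it", {
  d <- analyticDiff(function(X, Y) X)
  half <- d
  half@signed[, 1:85] <- NA   # wipe most of the zone
  err <- tryCatch(vbsReport(half, Zone(4)), error = conditionMessage)
  expect_match(err, "insufficient coverage")
  expect_match(err, "0\\.9")
  # a lower floor lets it through
  expect_no_error(vbsReport(half, Zone(4), minCoverage = 0.05))
})

test_that("VBS is symmetric, 1-Lipschitz, and matches eye exchange", {
  p <- makePair(PairSpec(seed = 31L, n = 100L, irrRms = 3,
                         base = typicalCornea(footprint = 9)))
  dAB <- differenceMap(applyFlip(p$os), p$od)
  dBA <- differenceMap(p$od, applyFlip(p$os))
  expect_equal(vbs(vbsReport(dAB, Zone(4))), vbs(vbsReport(dBA, Zone(4))))

  # perturbing one surface by <= eps changes VBS by <= eps
  set.seed(5)
  for (eps in c(0.1, 1)) {
    pert <- p$od
    pert@values <- pert@values + matrix(runif(100^2, -eps, eps), 100, 100)
    v1 <- vbs(vbsReport(differenceMap(applyFlip(p$os), p$od), Zone(4)))
    v2 <- vbs(vbsReport(differenceMap(applyFlip(p$os), pert), Zone(4)))
    expect_lte(abs(v1 - v2), eps + 1e-12)
  }
})

test_that("area weighting only reweights the rim", {
  d <- analyticDiff(function(X, Y) sqrt(X^2 + Y^2))
  vLattice <- vbs(vbsReport(d, Zone(4)))
  vArea <- vbs(vbsReport(d, Zone(4), areaWeighted = TRUE))
  expect_false(isTRUE(all.equal(vLattice, vArea)))
  expect_lt(abs(vLattice - vArea), 0.01)  # rim cells only
})
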