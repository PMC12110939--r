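test_that("the mirror flip negates x exactly and is an involution", {
  # marker at x = +2 mm moves to x = -2 mm
  g <- analyticGrid(function(X, Y) {
    ifelse(abs(X - 1.95) < 1e-9 & abs(Y - 0.05) < 1e-9, 10, 0)
  })
  gf <- applyFlip(g)
  pc <- physicalCoords(gf)
  hit <- which(elevationValues(gf) == 10, arr.ind = TRUE)
  expect_equal(unname(pc$x[hit]), -1.95)
  expect_equal(unname(pc$y[hit]), 0.05)
  # involution, including the mask
  set.seed(3)
  v <- matrix(rnorm(60 * 60), 60, 60); v[sample(3600, 100)] <- NA
  g2 <- ElevationGrid(v)
  expect_identical(elevationValues(applyFlip(applyFlip(g2))),
                   elevationValues(g2))
  expect_equal(gridCenter(applyFlip(applyFlip(g2))), gridCenter(g2))
  # a rotationally symmetric surface is unchanged
  g3 <- analyticGrid(function(X, Y) (X^2 + Y^2))
  expect_equal(elevationValues(applyFlip(g3)), elevationValues(g3))
})

test_that("identity and pure-offset transforms are exact", {
  g <- renderSurface(typicalCornea(footprint = 7), n = 80)
  gi <- applyTransform(g, RegistrationParams())
  expect_equal(elevationValues(gi), elevationValues(g))
  gz <- applyTransform(g, RegistrationParams(dz = 5))
  d <- elevationValues(gz) - elevationValues(g)
  expect_true(all(abs(d[!is.na(d)] - 5) < 1e-9))
  expect_identical(validMask(gz), validMask(g))
})

test_that("rotation moves structure to the rotated location with preserved height", {
  # off-center Gaussian bump; analytic evaluation at rotated coordinates
  # is the oracle
  bump <- function(X, Y, cx, cy) 20 * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * 0.5^2))
  g <- analyticGrid(function(X, Y) bump(X, Y, 1, 0.5), n = 140)
  gr <- applyTransform(g, RegistrationParams(rot = 90),
                       bounds = transformBounds(rot_deg = 90))
  pc <- physicalCoords(gr)
  # forward rotation by +90 deg maps (1, 0.5) to (-0.5, 1)
  expected <- bump(pc$y, -pc$x, 1, 0.5)  # R_{-90}(x,y) = (y, -x)
  ok <- !is.na(elevationValues(gr))
  expect_lt(max(abs(elevationValues(gr)[ok] - expected[ok])), 0.2)  # 1% of peak
  peak <- which.max(elevationValues(gr))
  expect_lt(abs(pc$x[arrayInd(peak, c(140, 140))] + 0.5), 0.08)
  expect_lt(abs(pc$y[arrayInd(peak, c(140, 140))] - 1), 0.08)
  expect_gt(max(elevationValues(gr), na.rm = TRUE), 19.8)
})

test_that("tilt is exactly the added plane and shift composes with unshift", {
  g <- renderSurface(typicalCornea(footprint = 7), n = 80)
  p <- RegistrationParams(dz = 3, tiltX = 2, tiltY = -4)
  gt <- applyTransform(g, p)
  pc <- physicalCoords(g)
  d <- elevationValues(gt) - elevationValues(g)
  ok <- !is.na(d)
  expect_equal(d[ok], (3 + 2 * pc$x + 4 * -pc$y)[ok], tolerance = 1e-12)

  gs <- applyTransform(applyTransform(g, RegistrationParams(dx = 0.37)),
                       RegistrationParams(dx = -0.37))
  ok <- !is.na(elevationValues(gs)) & !is.na(elevationValues(g))
  pcok <- sqrt(pc$x^2 + pc$y^2) < 4  # interior
  sel <- ok & pcok
  expect_lt(max(abs(elevationValues(gs)[sel] - elevationValues(g)[sel])), 0.05)
})

test_that("transforms only shrink the validity mask, never invent data", {
  set.seed(9)
  for (k in 1:5) {
    v <- matrix(rnorm(60 * 60), 60, 60)
    v[sample(3600, 400)] <- NA
    g <- ElevationGrid(v)
    p <- randomMisalignment(maxShift = 0.5, maxRot = 8)
    gt <- applyTransform(g, p)
    # every valid output point must be interpolable from valid inputs:
    # check against the naive oracle interpolation
    pc <- physicalCoords(g)
    src <- corneaSym:::.sourceCoords(pc$x, pc$y, p)
    ref <- oracleBilinear(v, 0.1, gridCenter(g), as.vector(src$u),
                          as.vector(src$v))
    out <- as.vector(elevationValues(gt))
    plane <- p@dz + p@tiltX * as.vector(pc$x) + p@tiltY * as.vector(pc$y)
    both <- !is.na(out) & !is.na(ref)
    expect_equal(out[both], (ref + plane)[both], tolerance = 1e-9)
    # anywhere the oracle says "not interpolable", the output may only be
    # valid through the exact-lattice snap; those must sit on the lattice
    extra <- which(!is.na(out) & is.na(ref))
    if (length(extra)) {
      ju <- src$u[extra] / 0.1 + gridCenter(g)[2]
      iv <- src$v[extra] / 0.1 + gridCenter(g)[1]
      onLattice <- (abs(ju - round(ju)) < 1e-6) | (abs(iv - round(iv)) < 1e-6)
      expect_true(all(onLattice))
    }
  }
})

test_that("out-of-bounds parameters are refused with the bound named", {
  g <- renderSurface(CorneaSpec(footprint = 7), n = 80)
  expect_error(applyTransform(g, RegistrationParams(dx = 3)), "2.000 mm")
  expect_error(applyTransform(g, RegistrationParams(rot = 20)), "15.000 deg")
  expect_error(applyTransform(g, RegistrationParams(tiltX = 40)), "um/mm")
  # boundary values are evaluated, not clipped
  expect_no_error(applyTransform(g, RegistrationParams(dx = 0.8),
                                 bounds = transformBounds(shift_mm = 0.8)))
})

test_that("parameter inversion and mirror conjugation are exact on the interior", {
  g <- renderSurface(typicalCornea(footprint = 9), n = 100)
  p <- RegistrationParams(dx = 0.23, dy = -0.31, rot = 3.7, dz = 4,
                          tiltX = 2.5, tiltY = -1.2)
  gg <- applyTransform(applyTransform(g, p), corneaSym:::.invertParams(p))
  pc <- physicalCoords(g)
  sel <- sqrt(pc$x^2 + pc$y^2) < 3 & !is.na(elevationValues(gg))
  expect_lt(max(abs((elevationValues(gg) - elevationValues(g))[sel])), 0.1)

  # flip o T_p o flip equals the conjugated transform
  q <- corneaSym:::.mirrorConjugate(p)
  lhs <- applyFlip(applyTransform(applyFlip(g), p))
  rhs <- applyTransform(g, q)
  both <- !is.na(elevationValues(lhs)) & !is.na(elevationValues(rhs))
  expect_equal(elevationValues(lhs)[both], elevationValues(rhs)[both],
               tolerance = 1e-9)
})
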