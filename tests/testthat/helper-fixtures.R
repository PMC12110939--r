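# Small in-code fixtures shared across the suite.

# a grid whose values are a known analytic function of (x, y), full validity
analyticGrid <- function(f, n = 80, spacing = 0.1, side = "OD") {
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * spacing
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  ElevationGrid(f(X, Y), spacing = spacing, side = side)
}

# a difference map built directly from an analytic signed field
analyticDiff <- function(f, n = 140, spacing = 0.1, footprint = 12) {
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * spacing
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  v <- f(X, Y)
  v[sqrt(X^2 + Y^2) > footprint / 2] <- NA_real_
  new("DifferenceMap", signed = v, spacing = spacing, center = c(ctr, ctr))
}

# enumeration oracle: lattice points of an n x n grid with centered
# coordinates whose radius is at most `radius`, counted directly
countLatticeInZone <- function(n, spacing, radius) {
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * spacing
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (xs[i]^2 + xs[j]^2 <= radius^2 + 1e-12) cnt <- cnt + 1L
  }
  cnt
}

# a typical normal-cornea base used by registration tests
typicalCornea <- function(cyl = 60, axis = 30, footprint = 12) {
  CorneaSpec(apicalRadius = 7.8, q = -0.25, cylAmp = cyl, cylAxis = axis,
             footprint = footprint)
}

randomMisalignment <- function(maxShift = 0.5, maxRot = 5, maxTilt = 10,
                               maxDz = 10) {
  RegistrationParams(
    dx = stats::runif(1, -maxShift, maxShift),
    dy = stats::runif(1, -maxShift, maxShift),
    dz = stats::runif(1, -maxDz, maxDz),
    rot = stats::runif(1, -maxRot, maxRot),
    tiltX = stats::runif(1, -maxTilt, maxTilt),
    tiltY = stats::runif(1, -maxTilt, maxTilt))
}
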