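#' @include metrics.R
NULL

# OSA/ANSI-ordered Zernike terms up to radial order 4
.zernikeIndex <- data.frame(
  n = c(0, 1, 1, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 4),
  m = c(0, -1, 1, -2, 0, 2, -3, -1, 1, 3, -4, -2, 0, 2, 4)
)

# radial polynomials R_n^{|m|} for n <= 4
.zernikeRadial <- function(n, m, rho) {
  am <- abs(m)
  key <- paste(n, am)
  switch(key,
    "0 0" = rep(1, length(rho)),
    "1 1" = rho,
    "2 0" = 2 * rho^2 - 1,
    "2 2" = rho^2,
    "3 1" = 3 * rho^3 - 2 * rho,
    "3 3" = rho^3,
    "4 0" = 6 * rho^4 - 6 * rho^2 + 1,
    "4 2" = 4 * rho^4 - 3 * rho^2,
    "4 4" = rho^4,
    stop("unsupported Zernike order"))
}

# design matrix of unit-variance (orthonormal on the disc) Zernike terms
.zernikeDesign <- function(rho, theta) {
  idx <- .zernikeIndex
  cols <- lapply(seq_len(nrow(idx)), function(k) {
    n <- idx$n[k]; m <- idx$m[k]
    norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
    ang <- if (m < 0) sin(abs(m) * theta) else cos(m * theta)
    norm * .zernikeRadial(n, m, rho) * if (m == 0) 1 else ang
  })
  A <- do.call(cbind, cols)
  colnames(A) <- sprintf("Z%d.%d", idx$n, idx$m)
  A
}

#' Least-squares Zernike decomposition of a difference map
#'
#' Fits the orthonormal Zernike terms up to radial order 4 to the signed
#' difference over the valid in-zone points, with radial coordinates
#' normalized to the zone radius. Because the basis is orthonormal on the
#' unit disc, each coefficient is (approximately, up to lattice sampling)
#' the RMS contribution of its term in micrometers.
#'
#' @param diff a [DifferenceMap-class].
#' @param zone a [Zone-class].
#' @param minCoverage minimum in-zone coverage (default 0.9).
#' @return named numeric vector of 15 coefficients (\code{Zn.m}, um).
#' @export
zernikeFit <- function(diff, zone, minCoverage = 0.9) {
  .checkZoneFits(diff, zone)
  r <- .radiusFrom(diff, zone)
  radius <- zone@diameter / 2
  inzone <- r <= radius
  valid <- inzone & !is.na(diff@signed)
  coverage <- sum(valid) / sum(inzone)
  if (coverage < minCoverage) {
    stop(sprintf("insufficient coverage for Zernike fit: %.3f < %.3f",
                 coverage, minCoverage))
  }
  pc <- physicalCoords(diff)
  xs <- pc$x[valid] - zone@center[1]
  ys <- pc$y[valid] - zone@center[2]
  rho <- sqrt(xs^2 + ys^2) / radius
  theta <- atan2(ys, xs)
  A <- .zernikeDesign(rho, theta)
  qr.coef(qr(A), diff@signed[valid])
}
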