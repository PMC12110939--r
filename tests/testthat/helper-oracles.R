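# Independent oracle implementations, kept deliberately naive.

# naive bilinear interpolation of a masked grid at physical points; valid
# only when all four surrounding lattice points are valid (no lattice
# snapping, unlike the implementation under test)
oracleBilinear <- function(values, spacing, center, u, v) {
  n <- nrow(values)
  j <- u / spacing + center[2]
  i <- v / spacing + center[1]
  i0 <- floor(i); j0 <- floor(j)
  ok <- i0 >= 1 & j0 >= 1 & i0 + 1 <= n & j0 + 1 <= n
  out <- rep(NA_real_, length(u))
  ii <- i0[ok]; jj <- j0[ok]; fi <- (i - i0)[ok]; fj <- (j - j0)[ok]
  q11 <- values[cbind(ii, jj)];         q12 <- values[cbind(ii, jj + 1)]
  q21 <- values[cbind(ii + 1, jj)];     q22 <- values[cbind(ii + 1, jj + 1)]
  out[ok] <- (1 - fi) * (1 - fj) * q11 + (1 - fi) * fj * q12 +
    fi * (1 - fj) * q21 + fi * fj * q22
  out
}

# mean absolute residual on a zone for fixed (dx, dy, rot) with the offset
# and tilt absorbed by an L1 plane fit; used by the exhaustive grid search
oracleObjective <- function(moving, fixed, zone, par) {
  pc <- physicalCoords(fixed)
  r <- sqrt(pc$x^2 + pc$y^2)
  inz <- r <= zoneDiameter(zone) / 2
  x <- pc$x[inz]; y <- pc$y[inz]
  fv <- elevationValues(fixed)[inz]
  a <- par[3] * pi / 180
  xs <- x - par[1]; ys <- y - par[2]
  u <- cos(a) * xs + sin(a) * ys
  v <- -sin(a) * xs + cos(a) * ys
  mv <- oracleBilinear(elevationValues(moving), gridSpacing(moving),
                       gridCenter(moving), u, v)
  ok <- !is.na(mv) & !is.na(fv)
  resid <- fv[ok] - mv[ok]
  fit <- fitL1Plane(x[ok], y[ok], resid)
  fit$mean_abs
}

# exhaustive coarse grid search over (dx, dy, rot); returns the minimum
# objective value found
oracleGridSearch <- function(moving, fixed, zone,
                             shifts = seq(-0.5, 0.5, by = 0.1),
                             rots = seq(-5, 5, by = 1)) {
  best <- Inf
  for (dx in shifts) for (dy in shifts) for (ro in rots) {
    v <- oracleObjective(moving, fixed, zone, c(dx, dy, ro))
    if (v < best) best <- v
  }
  best
}

# closed-form Welch statistics, written out from the textbook formulas
oracleWelch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  ci <- (mean(a) - mean(b)) + c(-1, 1) * stats::qt(0.975, df) * sqrt(se2)
  list(t = tstat, df = df, p = p, ci = ci)
}

# confusion counts by direct loop enumeration
oracleScreen <- function(values, labels, threshold, positive = "keratoconus") {
  TP <- FP <- TN <- FN <- 0L
  for (k in seq_along(values)) {
    pos <- labels[k] == positive
    pred <- values[k] > threshold
    if (pred && pos) TP <- TP + 1L
    if (pred && !pos) FP <- FP + 1L
    if (!pred && !pos) TN <- TN + 1L
    if (!pred && pos) FN <- FN + 1L
  }
  c(TP = TP, FP = FP, TN = TN, FN = FN)
}
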