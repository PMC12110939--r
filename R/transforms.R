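#' @include elevation-grid.R
NULL

#' Bounds on registration parameters
#'
#' Shifts, rotation and tilt are bounded to the plausible range of
#' acquisition misalignment; [applyTransform()] and [autoRegister()] refuse
#' parameters outside these bounds (boundary values are evaluated, not
#' clipped).
#'
#' @param shift_mm maximum |dx|, |dy| (default 2 mm).
#' @param rot_deg maximum |rotation| (default 15 degrees).
#' @param tilt_um_per_mm maximum |tilt slope| (default 30 um/mm).
#' @return a named list of bounds.
#' @export
transformBounds <- function(shift_mm = 2, rot_deg = 15, tilt_um_per_mm = 30) {
  list(shift_mm = shift_mm, rot_deg = rot_deg, tilt_um_per_mm = tilt_um_per_mm)
}

.checkBounds <- function(params, bounds) {
  if (abs(params@dx) > bounds$shift_mm || abs(params@dy) > bounds$shift_mm) {
    stop(sprintf("shift (%.3f, %.3f) mm exceeds the bound %.3f mm",
                 params@dx, params@dy, bounds$shift_mm))
  }
  if (abs(params@rot) > bounds$rot_deg) {
    stop(sprintf("rotation %.3f deg exceeds the bound %.3f deg",
                 params@rot, bounds$rot_deg))
  }
  if (max(abs(params@tiltX), abs(params@tiltY)) > bounds$tilt_um_per_mm) {
    stop(sprintf("tilt (%.3f, %.3f) um/mm exceeds the bound %.3f um/mm",
                 params@tiltX, params@tiltY, bounds$tilt_um_per_mm))
  }
  invisible(TRUE)
}

# Mask-aware bilinear sampling of a gridded field at physical points (u, v).
# A sample is valid only if every lattice neighbor carrying non-zero weight
# is valid; weights within snapTol of the lattice are snapped so that exact
# lattice sampling is exact (no interpolation error, no spurious neighbor
# requirements).
.sampleBilinear <- function(values, spacing, center, u, v, snapTol = 1e-9) {
  n <- nrow(values)
  j <- u / spacing + center[2]   # fractional column
  i <- v / spacing + center[1]   # fractional row
  i0 <- floor(i); j0 <- floor(j)
  fi <- i - i0; fj <- j - j0
  snap <- fi < snapTol; fi[snap] <- 0
  snap <- fi > 1 - snapTol; i0[snap] <- i0[snap] + 1; fi[snap] <- 0
  snap <- fj < snapTol; fj[snap] <- 0
  snap <- fj > 1 - snapTol; j0[snap] <- j0[snap] + 1; fj[snap] <- 0

  w00 <- (1 - fi) * (1 - fj); w01 <- (1 - fi) * fj
  w10 <- fi * (1 - fj);       w11 <- fi * fj

  pick <- function(ii, jj, w) {
    use <- w > 0
    inb <- use & ii >= 1 & ii <= n & jj >= 1 & jj <= n
    val <- rep(NA_real_, length(ii))
    val[inb] <- values[cbind(ii[inb], jj[inb])]
    # a needed neighbor that is out of range or NA invalidates the sample
    ok <- !use | (inb & !is.na(val))
    val[!use] <- 0
    list(val = val, ok = ok)
  }
  p00 <- pick(i0, j0, w00);     p01 <- pick(i0, j0 + 1, w01)
  p10 <- pick(i0 + 1, j0, w10); p11 <- pick(i0 + 1, j0 + 1, w11)
  ok <- p00$ok & p01$ok & p10$ok & p11$ok
  out <- w00 * p00$val + w01 * p01$val + w10 * p10$val + w11 * p11$val
  out[!ok] <- NA_real_
  out
}

# source coordinates for the inverse mapping of (shift, rotation)
.sourceCoords <- function(x, y, params) {
  a <- params@rot * pi / 180
  xs <- x - params@dx
  ys <- y - params@dy
  list(u = cos(a) * xs + sin(a) * ys,
       v = -sin(a) * xs + cos(a) * ys)
}

#' @rdname applyFlip
setMethod("applyFlip", "ElevationGrid", function(x) {
  n <- ncol(x@values)
  out <- x
  out@values <- x@values[, n:1, drop = FALSE]
  out@center <- c(x@center[1], n + 1 - x@center[2])
  out@meta$flipped <- !isTRUE(x@meta$flipped)
  out
})

#' @rdname applyTransform
setMethod("applyTransform", "ElevationGrid", function(x, params, bounds) {
  .checkBounds(params, bounds)
  pc <- physicalCoords(x)
  src <- .sourceCoords(pc$x, pc$y, params)
  sampled <- .sampleBilinear(x@values, x@spacing, x@center,
                             as.vector(src$u), as.vector(src$v))
  n <- nrow(x@values)
  vals <- matrix(sampled, n, n) + params@dz +
    params@tiltX * pc$x + params@tiltY * pc$y
  out <- x
  out@values <- vals
  out@meta$transform <- .paramsAsList(params)
  out
})

# analytic inverse of a (shift, rotate, plane) adjustment: the params q with
# applyTransform(applyTransform(g, p), q) == g on the interior
.invertParams <- function(p) {
  a <- p@rot * pi / 180
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2) # rotation by -a
  d <- c(p@dx, p@dy)
  e <- -as.vector(R %*% d)
  t0 <- c(p@tiltX, p@tiltY)
  tRt <- as.vector(R %*% t0)     # R_{-a} t
  tq <- -tRt
  dzq <- -p@dz + sum(tRt * e)
  RegistrationParams(flip = p@flip, dx = e[1], dy = e[2], dz = dzq,
                     rot = -p@rot, tiltX = tq[1], tiltY = tq[2])
}

# mirror conjugation (x -> -x): the transform seen after flipping both the
# input and the output of p
.mirrorConjugate <- function(p) {
  RegistrationParams(flip = p@flip, dx = -p@dx, dy = p@dy, dz = p@dz,
                     rot = -p@rot, tiltX = -p@tiltX, tiltY = p@tiltY)
}
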