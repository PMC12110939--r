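#' @include transforms.R
NULL

#' Point-by-point interocular difference map
#'
#' Subtracts the fixed right-eye grid from the registered (moving, usually
#' mirrored) left-eye grid, point by point on the common lattice. The result
#' is valid exactly where both eyes are valid.
#'
#' @param left the registered left-eye [ElevationGrid-class].
#' @param right the right-eye [ElevationGrid-class].
#' @return a [DifferenceMap-class] (signed differences, um).
#' @export
differenceMap <- function(left, right) {
  if (!all(dim(left@values) == dim(right@values))) {
    stop(sprintf("grid shapes differ: %d x %d vs %d x %d",
                 nrow(left@values), ncol(left@values),
                 nrow(right@values), ncol(right@values)))
  }
  if (!isTRUE(all.equal(left@spacing, right@spacing))) {
    stop(sprintf("grid spacings differ: %g vs %g mm",
                 left@spacing, right@spacing))
  }
  if (!isTRUE(all.equal(left@center, right@center))) {
    stop("grid centers differ; resample or re-center before subtracting")
  }
  new("DifferenceMap", signed = left@values - right@values,
      spacing = left@spacing, center = left@center)
}

#' Signed and absolute difference matrices
#' @param x a [DifferenceMap-class].
#' @return numeric matrix (um); NA outside the joint validity mask.
#' @name difference-accessors
NULL

#' @rdname difference-accessors
#' @export
signedDifference <- function(x) x@signed

#' @rdname difference-accessors
#' @export
absoluteDifference <- function(x) abs(x@signed)

#' VBS index and ring summaries within a zone
#'
#' The VBS (Volume Between Spheres) index is the arithmetic mean of the
#' absolute interocular elevation differences over the valid lattice points
#' inside the zone, in micrometers. Ring summaries are computed on annuli of
#' \code{ringWidth} out to the zone radius; the rings partition the zone, so
#' the VBS equals the point-count-weighted mean of the ring means. A derived
#' volume interpretation (VBS times zone area) is reported but never used
#' for thresholds.
#'
#' @param x a [DifferenceMap-class].
#' @param zone a [Zone-class] (e.g. \code{Zone(4)} or \code{Zone(6)}).
#' @param minCoverage minimum fraction of in-zone lattice points that must
#'   be valid (default 0.9); below it the report is refused with the
#'   observed coverage in the error.
#' @param ringWidth annulus width in mm (default 0.5).
#' @param areaWeighted if TRUE, boundary lattice cells are down-weighted by
#'   the (approximate) fraction of their cell area inside the zone circle;
#'   the default is plain lattice-point averaging.
#' @param ... unused.
#' @return a [ZoneReport-class].
#' @examples
#' d <- new("DifferenceMap", signed = matrix(2, 140, 140),
#'          spacing = 0.1, center = c(70.5, 70.5))
#' vbs(vbsReport(d, Zone(4)))  # exactly 2
#' @rdname vbsReport
#' @export
setMethod("vbsReport", signature("DifferenceMap", "Zone"),
  function(x, zone, minCoverage = 0.9, ringWidth = 0.5,
           areaWeighted = FALSE, ...) {
    .checkZoneFits(x, zone)
    r <- .radiusFrom(x, zone)
    radius <- zone@diameter / 2
    inzone <- r <= radius
    nIn <- sum(inzone)
    if (nIn == 0) stop("zone contains no lattice points")
    valid <- inzone & !is.na(x@signed)
    coverage <- sum(valid) / nIn
    if (coverage < minCoverage) {
      stop(sprintf(
        "insufficient coverage in the %.1f mm zone: %.3f < %.3f required",
        zone@diameter, coverage, minCoverage))
    }
    a <- abs(x@signed[valid])
    w <- if (areaWeighted) {
      pmin(pmax((radius - r[valid]) / x@spacing + 0.5, 0), 1)
    } else rep(1, length(a))
    v <- sum(w * a) / sum(w)
    edges <- seq(0, radius, by = ringWidth)
    if (edges[length(edges)] < radius) edges <- c(edges, radius)
    rv <- r[valid]
    rings <- do.call(rbind, lapply(seq_len(length(edges) - 1), function(k) {
      inner <- edges[k]; outer <- edges[k + 1]
      sel <- if (k == 1) rv <= outer else rv > inner & rv <= outer
      data.frame(inner_mm = inner, outer_mm = outer,
                 mean_abs_um = if (any(sel)) mean(a[sel]) else NA_real_,
                 max_abs_um = if (any(sel)) max(a[sel]) else NA_real_,
                 n_points = sum(sel))
    }))
    new("ZoneReport", zone = zone, vbs = v,
        volume = v * pi * radius^2 / 1000,
        nPoints = as.integer(sum(valid)), coverage = coverage, rings = rings)
  })

#' @rdname vbs
setMethod("vbs", "ZoneReport", function(x) x@vbs)

#' @rdname ringSummary
setMethod("ringSummary", "ZoneReport", function(x) x@rings)

#' ZoneReport accessors
#' @param x a [ZoneReport-class].
#' @return \code{reportCoverage}: fraction of in-zone lattice points that
#'   were valid; \code{reportNPoints}: contributing point count;
#'   \code{zoneVolume}: derived volume (mm^3).
#' @name zonereport-accessors
NULL

#' @rdname zonereport-accessors
#' @export
reportCoverage <- function(x) x@coverage

#' @rdname zonereport-accessors
#' @export
reportNPoints <- function(x) x@nPoints

#' @rdname zonereport-accessors
#' @export
zoneVolume <- function(x) x@volume

setMethod("show", "ZoneReport", function(object) {
  cat(sprintf(
    "ZoneReport (%.1f mm zone): VBS = %.3f um over %d points (coverage %.1f%%)\n",
    object@zone@diameter, object@vbs, object@nPoints, 100 * object@coverage))
  cat(sprintf("  volume %.4f mm^3; %d rings\n",
              object@volume, nrow(object@rings)))
})
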