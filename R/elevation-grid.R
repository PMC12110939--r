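#' @include AllGenerics.R
NULL

#' Construct an ElevationGrid
#'
#' @param values numeric matrix (square) of elevations in micrometers; NA,
#'   NaN map to missing.
#' @param spacing grid step in mm (default 0.1).
#' @param center (row, col) index of the apex/grid center, 1-based; default
#'   the exact geometric center \code{(n + 1) / 2}.
#' @param side "OD" or "OS".
#' @param layer "anterior" or "posterior".
#' @param meta free-form list of source tags.
#' @return an [ElevationGrid-class].
#' @examples
#' g <- ElevationGrid(matrix(0, 140, 140))
#' gridCenter(g)   # 70.5 70.5
#' @export
ElevationGrid <- function(values, spacing = 0.1, center = NULL,
                          side = "OD", layer = "anterior", meta = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[is.nan(values)] <- NA_real_
  if (is.null(center)) center <- rep((nrow(values) + 1) / 2, 2)
  new("ElevationGrid", values = values, spacing = spacing,
      center = as.numeric(center), side = side, layer = layer, meta = meta)
}

#' Construct a Zone
#' @param diameter zone diameter in mm (e.g. 4 or 6).
#' @param center (x_mm, y_mm) offset of the zone center from the grid
#'   center; default centered.
#' @return a [Zone-class].
#' @export
Zone <- function(diameter, center = c(0, 0)) {
  new("Zone", diameter = as.numeric(diameter), center = as.numeric(center))
}

#' Construct RegistrationParams
#' @param flip mirror the moving eye (default FALSE).
#' @param dx,dy in-plane shift, mm.
#' @param dz elevation offset, um.
#' @param rot frontal-plane rotation, degrees.
#' @param tiltX,tiltY planar tilt slopes, um/mm.
#' @return a [RegistrationParams-class].
#' @export
RegistrationParams <- function(flip = FALSE, dx = 0, dy = 0, dz = 0,
                               rot = 0, tiltX = 0, tiltY = 0) {
  new("RegistrationParams", flip = flip,
      dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz),
      rot = as.numeric(rot), tiltX = as.numeric(tiltX),
      tiltY = as.numeric(tiltY))
}

# ---- accessors --------------------------------------------------------------

#' Grid accessors
#'
#' @param x an [ElevationGrid-class] (or [DifferenceMap-class] where noted).
#' @return \code{elevationValues}: the numeric matrix (um, NA = missing);
#'   \code{gridSpacing}: the step in mm; \code{gridCenter}: the (row, col)
#'   center index; \code{eyeSide}, \code{surfaceLayer}: metadata strings;
#'   \code{validMask}: logical matrix of present measurements.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
elevationValues <- function(x) x@values

#' @rdname grid-accessors
#' @export
gridSpacing <- function(x) x@spacing

#' @rdname grid-accessors
#' @export
gridCenter <- function(x) x@center

#' @rdname grid-accessors
#' @export
eyeSide <- function(x) x@side

#' @rdname grid-accessors
#' @export
surfaceLayer <- function(x) x@layer

#' @rdname grid-accessors
#' @export
validMask <- function(x) {
  if (is(x, "DifferenceMap")) !is.na(x@signed) else !is.na(x@values)
}

#' Zone accessors
#' @param x a [Zone-class].
#' @name zone-accessors
#' @return \code{zoneDiameter}: diameter in mm; \code{zoneCenter}: the
#'   (x_mm, y_mm) offset.
NULL

#' @rdname zone-accessors
#' @export
zoneDiameter <- function(x) x@diameter

#' @rdname zone-accessors
#' @export
zoneCenter <- function(x) x@center

# ---- coordinates ------------------------------------------------------------

#' Physical coordinates of every lattice point
#'
#' @param x an [ElevationGrid-class] or [DifferenceMap-class].
#' @return list with matrices \code{x} and \code{y} in millimeters;
#'   \code{x = (col - center_col) * spacing} (positive toward the patient's
#'   left on an unflipped OD image), \code{y = (row - center_row) * spacing}
#'   (positive superior). The center index maps to (0, 0).
#' @export
physicalCoords <- function(x) {
  n <- nrow(if (is(x, "DifferenceMap")) x@signed else x@values)
  ctr <- x@center
  s <- x@spacing
  xs <- (seq_len(n) - ctr[2]) * s
  ys <- (seq_len(n) - ctr[1]) * s
  list(x = matrix(xs, n, n, byrow = TRUE), y = matrix(ys, n, n))
}

# radial distance of each lattice point from a zone center
.radiusFrom <- function(obj, zone) {
  pc <- physicalCoords(obj)
  sqrt((pc$x - zone@center[1])^2 + (pc$y - zone@center[2])^2)
}

.checkZoneFits <- function(obj, zone) {
  n <- nrow(if (is(obj, "DifferenceMap")) obj@signed else obj@values)
  extent <- n * obj@spacing
  if (zone@diameter > extent) {
    stop(sprintf(
      "zone diameter %.2f mm exceeds the grid extent %.2f mm (%d points at %.3f mm)",
      zone@diameter, extent, n, obj@spacing))
  }
  invisible(TRUE)
}

.zoneMaskImpl <- function(obj, zone) {
  .checkZoneFits(obj, zone)
  r <- .radiusFrom(obj, zone)
  (r <= zone@diameter / 2) & validMask(obj)
}

#' @rdname zoneMask
setMethod("zoneMask", signature("ElevationGrid", "Zone"),
          function(x, zone) .zoneMaskImpl(x, zone))

#' @rdname zoneMask
setMethod("zoneMask", signature("DifferenceMap", "Zone"),
          function(x, zone) .zoneMaskImpl(x, zone))

# ---- show methods -----------------------------------------------------------

setMethod("show", "ElevationGrid", function(object) {
  v <- object@values
  cat(sprintf("ElevationGrid: %d x %d, %s %s, spacing %.3g mm\n",
              nrow(v), ncol(v), object@side, object@layer, object@spacing))
  cat(sprintf("  valid points: %d / %d (%.1f%%)\n",
              sum(!is.na(v)), length(v), 100 * mean(!is.na(v))))
  if (any(!is.na(v))) {
    cat(sprintf("  elevation range: [%.2f, %.2f] um\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
})

setMethod("show", "Zone", function(object) {
  cat(sprintf("Zone: %.1f mm diameter, center offset (%.2f, %.2f) mm\n",
              object@diameter, object@center[1], object@center[2]))
})

setMethod("show", "RegistrationParams", function(object) {
  cat(sprintf(
    "RegistrationParams: flip=%s dx=%.3f mm dy=%.3f mm rot=%.3f deg\n  dz=%.3f um tilt=(%.3f, %.3f) um/mm\n",
    object@flip, object@dx, object@dy, object@rot,
    object@dz, object@tiltX, object@tiltY))
})

setMethod("show", "DifferenceMap", function(object) {
  cat(sprintf("DifferenceMap: %d x %d, %d valid points\n",
              nrow(object@signed), ncol(object@signed), sum(!is.na(object@signed))))
  if (any(!is.na(object@signed))) {
    cat(sprintf("  signed range [%.2f, %.2f] um, mean |diff| %.2f um\n",
                min(object@signed, na.rm = TRUE), max(object@signed, na.rm = TRUE),
                mean(abs(object@signed), na.rm = TRUE)))
  }
})
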