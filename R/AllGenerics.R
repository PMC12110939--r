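#' @include AllClasses.R
NULL

#' Boolean zone mask over a grid
#'
#' TRUE exactly at lattice points whose physical distance from the zone
#' center is at most the zone radius and whose measurement is present.
#'
#' @param x an [ElevationGrid-class] or [DifferenceMap-class].
#' @param zone a [Zone-class].
#' @return logical matrix of the grid's dimensions.
#' @export
setGeneric("zoneMask", function(x, zone) standardGeneric("zoneMask"))

#' Mirror an elevation grid about the vertical axis
#'
#' Reverses the column order about the grid's vertical midline (x becomes
#' -x) and reflects the stored center column accordingly, so the operation
#' is an exact involution. This is the mirror (enantiomorph) relation
#' between fellow eyes.
#'
#' @param x an [ElevationGrid-class].
#' @return the flipped grid; \code{meta$flipped} records the flip.
#' @export
setGeneric("applyFlip", function(x) standardGeneric("applyFlip"))

#' Apply a shift/rotate/offset/tilt adjustment to a grid
#'
#' The output value at physical point \eqn{(x, y)} is
#' \deqn{E(R_{-\rho}(x - dx, y - dy)) + dz + t_x x + t_y y}
#' where \eqn{E} is the mask-aware bilinear interpolant of the input and
#' \eqn{\rho} the rotation in degrees. A target point is valid only if every
#' supporting lattice point with non-zero interpolation weight is valid, so
#' the transform never invents data across the missing-data boundary (and is
#' exact, not interpolated, when the sampling lands on the lattice). The
#' \code{flip} field of \code{params} is ignored here; mirroring is a
#' separate step (see [applyFlip()] and [evaluateRegistration()]).
#'
#' @param x an [ElevationGrid-class].
#' @param params a [RegistrationParams-class].
#' @param bounds parameter bounds, see [transformBounds()]; out-of-bounds
#'   parameters are an error naming the bound.
#' @return the transformed grid.
#' @export
setGeneric("applyTransform",
  function(x, params, bounds = transformBounds()) standardGeneric("applyTransform"))

#' @rdname vbsReport
#' @export
setGeneric("vbsReport", function(x, zone, ...) standardGeneric("vbsReport"))

#' VBS index stored in a zone report
#' @param x a [ZoneReport-class].
#' @return the VBS (mean absolute interocular elevation difference), um.
#' @export
setGeneric("vbs", function(x) standardGeneric("vbs"))

#' Ring (annulus) summaries of a zone report
#' @param x a [ZoneReport-class].
#' @return data.frame with one row per annulus.
#' @export
setGeneric("ringSummary", function(x) standardGeneric("ringSummary"))
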