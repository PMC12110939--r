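#' @import methods
NULL

#' ElevationGrid: one eye/surface corneal elevation matrix
#'
#' An \code{ElevationGrid} holds a square matrix of corneal surface elevation
#' values in micrometers, as exported by a Scheimpflug tomographer, together
#' with the grid geometry. Missing measurements (outside the measured
#' footprint, or dropped by the device quality check) are stored as \code{NA};
#' there are no sentinel fill values.
#'
#' Physical coordinates follow the convention
#' \code{x = (col - center[2]) * spacing}, \code{y = (row - center[1]) *
#' spacing}, both in millimeters, so the center index maps to (0, 0). The
#' default center is the exact geometric grid center \code{(n + 1) / 2}
#' (70.5 for the usual n = 140), which makes the mirror flip an exact column
#' reversal.
#'
#' @slot values numeric matrix, n x n, elevation in micrometers; \code{NA}
#'   marks missing points.
#' @slot spacing single positive numeric, grid step in millimeters
#'   (default 0.1, i.e. a 14 mm chord for n = 140).
#' @slot center numeric length-2 \code{(row, col)} index (1-based, may be
#'   half-integer) of the corneal apex / grid center.
#' @slot side \code{"OD"} (right) or \code{"OS"} (left).
#' @slot layer \code{"anterior"} or \code{"posterior"}.
#' @slot meta free-form list of source tags (file path, applied transforms,
#'   simulation ground truth, ...).
#'
#' @seealso [ElevationGrid()] for the constructor, [physicalCoords()],
#'   [zoneMask()], [applyFlip()], [applyTransform()].
#' @name ElevationGrid-class
#' @rdname ElevationGrid-class
#' @exportClass ElevationGrid
setClass("ElevationGrid",
  representation(
    values = "matrix",
    spacing = "numeric",
    center = "numeric",
    side = "character",
    layer = "character",
    meta = "list"
  )
)

setValidity("ElevationGrid", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) != ncol(v)) {
    msg <- c(msg, sprintf("values must be square, got %d x %d", nrow(v), ncol(v)))
  }
  if (nrow(v) < 1) msg <- c(msg, "values must have at least one cell")
  if (is.numeric(v) && any(is.infinite(v) | is.nan(v))) {
    msg <- c(msg, "values must be finite or NA (no Inf/NaN)")
  }
  if (length(object@spacing) != 1 || !is.finite(object@spacing) ||
      object@spacing <= 0) {
    msg <- c(msg, "spacing must be a single positive number (mm)")
  }
  if (length(object@center) != 2 || any(!is.finite(object@center))) {
    msg <- c(msg, "center must be two finite (row, col) indices")
  } else if (any(object@center < 0.5 | object@center > nrow(v) + 0.5)) {
    msg <- c(msg, "center must lie within the grid")
  }
  if (!(length(object@side) == 1 && object@side %in% c("OD", "OS"))) {
    msg <- c(msg, "side must be 'OD' or 'OS'")
  }
  if (!(length(object@layer) == 1 &&
        object@layer %in% c("anterior", "posterior"))) {
    msg <- c(msg, "layer must be 'anterior' or 'posterior'")
  }
  if (length(msg)) msg else TRUE
})

#' Zone: a circular analysis region on the cornea
#'
#' A central (or offset) disc of stated diameter over which the VBS index and
#' ring summaries are computed. The clinically standard zones are 4.0 mm and
#' 6.0 mm.
#'
#' @slot diameter single positive numeric, zone diameter in millimeters.
#' @slot center numeric length-2 \code{(x_mm, y_mm)} offset of the zone
#'   center from the grid center, default \code{c(0, 0)}.
#'
#' @seealso [Zone()], [zoneMask()], [vbsReport()]
#' @name Zone-class
#' @rdname Zone-class
#' @exportClass Zone
setClass("Zone",
  representation(diameter = "numeric", center = "numeric")
)

setValidity("Zone", function(object) {
  msg <- character()
  if (length(object@diameter) != 1 || !is.finite(object@diameter) ||
      object@diameter <= 0) {
    msg <- c(msg, "diameter must be a single positive number (mm)")
  }
  if (length(object@center) != 2 || any(!is.finite(object@center))) {
    msg <- c(msg, "center must be a finite (x_mm, y_mm) pair")
  }
  if (length(msg)) msg else TRUE
})

#' RegistrationParams: the flip/shift/rotate/tilt parameter vector
#'
#' The rigid adjustments applied to the moving (left, possibly mirrored) eye
#' before subtraction: an optional mirror flip, in-plane translation
#' \code{(dx, dy)} in mm, an elevation offset \code{dz} in micrometers, a
#' frontal-plane rotation about the grid center in degrees, and a small-angle
#' planar tilt with slopes in micrometers per millimeter.
#'
#' Parameter bounds are not part of the object; they are enforced where the
#' parameters are applied (see [transformBounds()]), so that boundary values
#' are evaluated rather than clipped.
#'
#' @slot flip logical; mirror the moving eye (fellow-eye enantiomorphism).
#' @slot dx,dy numeric, in-plane shift in millimeters.
#' @slot dz numeric, elevation offset in micrometers.
#' @slot rot numeric, frontal-plane rotation in degrees (counterclockwise).
#' @slot tiltX,tiltY numeric, planar tilt slopes in micrometers per
#'   millimeter.
#'
#' @seealso [RegistrationParams()], [applyTransform()], [autoRegister()]
#' @name RegistrationParams-class
#' @rdname RegistrationParams-class
#' @exportClass RegistrationParams
setClass("RegistrationParams",
  representation(
    flip = "logical", dx = "numeric", dy = "numeric", dz = "numeric",
    rot = "numeric", tiltX = "numeric", tiltY = "numeric"
  )
)

setValidity("RegistrationParams", function(object) {
  num <- c(object@dx, object@dy, object@dz, object@rot,
           object@tiltX, object@tiltY)
  msg <- character()
  if (length(object@flip) != 1 || is.na(object@flip)) {
    msg <- c(msg, "flip must be TRUE or FALSE")
  }
  if (length(num) != 6 || any(!is.finite(num))) {
    msg <- c(msg, "all numeric parameters must be single finite values")
  }
  if (length(msg)) msg else TRUE
})

#' DifferenceMap: point-wise interocular elevation differences
#'
#' The signed difference (registered left minus right, micrometers) on the
#' common grid. The validity mask is the conjunction of the two eyes' masks
#' and is encoded as \code{NA} in the signed matrix; the absolute map is
#' derived, see [absoluteDifference()].
#'
#' @slot signed numeric matrix of signed differences in micrometers, \code{NA}
#'   where either eye is missing.
#' @slot spacing grid step in millimeters.
#' @slot center grid center (row, col) index.
#'
#' @seealso [differenceMap()], [vbsReport()], [classifyPattern()]
#' @name DifferenceMap-class
#' @rdname DifferenceMap-class
#' @exportClass DifferenceMap
setClass("DifferenceMap",
  representation(signed = "matrix", spacing = "numeric", center = "numeric")
)

setValidity("DifferenceMap", function(object) {
  msg <- character()
  if (!is.numeric(object@signed) || nrow(object@signed) != ncol(object@signed)) {
    msg <- c(msg, "signed must be a square numeric matrix")
  }
  if (any(is.infinite(object@signed) | is.nan(object@signed))) {
    msg <- c(msg, "signed must be finite or NA")
  }
  if (length(object@spacing) != 1 || !is.finite(object@spacing) ||
      object@spacing <= 0) {
    msg <- c(msg, "spacing must be a single positive number")
  }
  if (length(object@center) != 2 || any(!is.finite(object@center))) {
    msg <- c(msg, "center must be two finite indices")
  }
  if (length(msg)) msg else TRUE
})

#' ZoneReport: VBS and ring summaries for one zone
#'
#' @slot zone the [Zone-class] summarized.
#' @slot vbs mean absolute interocular elevation difference in micrometers
#'   (the VBS index).
#' @slot volume derived volume interpretation in cubic millimeters
#'   (\code{vbs} times the zone area; never used for thresholds).
#' @slot nPoints number of valid lattice points contributing.
#' @slot coverage \code{nPoints} divided by the number of lattice points
#'   inside the zone geometry.
#' @slot rings data.frame of annulus summaries with columns
#'   \code{inner_mm, outer_mm, mean_abs_um, max_abs_um, n_points}; the rings
#'   partition the zone radially.
#'
#' @seealso [vbsReport()], [vbs()], [ringSummary()]
#' @name ZoneReport-class
#' @rdname ZoneReport-class
#' @exportClass ZoneReport
setClass("ZoneReport",
  representation(
    zone = "Zone", vbs = "numeric", volume = "numeric",
    nPoints = "integer", coverage = "numeric", rings = "data.frame"
  )
)

setValidity("ZoneReport", function(object) {
  msg <- character()
  if (!(length(object@vbs) == 1 && is.finite(object@vbs) && object@vbs >= 0)) {
    msg <- c(msg, "vbs must be a single non-negative number")
  }
  if (!(length(object@coverage) == 1 && is.finite(object@coverage) &&
        object@coverage >= 0 && object@coverage <= 1)) {
    msg <- c(msg, "coverage must lie in [0, 1]")
  }
  need <- c("inner_mm", "outer_mm", "mean_abs_um", "max_abs_um", "n_points")
  if (!all(need %in% names(object@rings))) {
    msg <- c(msg, "rings must have columns inner_mm, outer_mm, mean_abs_um, max_abs_um, n_points")
  }
  if (length(msg)) msg else TRUE
})

#' PatternLabel: classification of an interocular difference map
#'
#' Output of the rule-based pattern classifier: one of the canonical
#' interocular symmetry patterns (\code{flat}, \code{tilt}, \code{cone},
#' \code{four_leaf}) or \code{irregular}, with per-label evidence scores
#' (normalized to sum to 1, argmax equal to the label) and the fitted
#' low-order Zernike coefficients in micrometers.
#'
#' @slot label character, one of flat, tilt, cone, four_leaf, irregular.
#' @slot scores named numeric evidence per label, in [0, 1].
#' @slot coefficients named numeric Zernike coefficients (um), OSA indices
#'   \code{Zn.m} up to radial order 4.
#' @slot rms numeric, non-piston fitted RMS in micrometers.
#'
#' @seealso [classifyPattern()]
#' @name PatternLabel-class
#' @rdname PatternLabel-class
#' @exportClass PatternLabel
setClass("PatternLabel",
  representation(
    label = "character", scores = "numeric",
    coefficients = "numeric", rms = "numeric"
  )
)

setValidity("PatternLabel", function(object) {
  labs <- c("flat", "tilt", "cone", "four_leaf", "irregular")
  msg <- character()
  if (!(length(object@label) == 1 && object@label %in% labs)) {
    msg <- c(msg, "label must be one of flat, tilt, cone, four_leaf, irregular")
  }
  if (!all(labs %in% names(object@scores))) {
    msg <- c(msg, "scores must be named for all five labels")
  } else {
    if (sum(object@scores) > 1 + 1e-6) {
      msg <- c(msg, "scores must sum to at most 1 (plus tolerance)")
    }
    if (names(which.max(object@scores)) != object@label) {
      msg <- c(msg, "argmax of scores must equal label")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GroupComparison: Welch comparison of VBS between two cohorts
#'
#' @slot mean,sd,n named length-2 numerics (groups \code{a} and \code{b}).
#' @slot diff mean difference (a minus b) in micrometers.
#' @slot confInt 95 percent confidence interval of the difference
#'   (Welch--Satterthwaite degrees of freedom).
#' @slot statistic,df,pValue the Welch t statistic, degrees of freedom and
#'   two-sided p-value.
#'
#' @seealso [compareGroups()]
#' @name GroupComparison-class
#' @rdname GroupComparison-class
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    mean = "numeric", sd = "numeric", n = "integer",
    diff = "numeric", confInt = "numeric",
    statistic = "numeric", df = "numeric", pValue = "numeric"
  )
)

#' RegistrationFit: result of auto-registration
#'
#' @slot params the optimal [RegistrationParams-class] found.
#' @slot report the [ZoneReport-class] at the optimum on the objective zone.
#' @slot trace data.frame of accepted optimization steps
#'   (\code{iteration, flip, dx_mm, dy_mm, rot_deg, dz_um, tilt_x_um_per_mm,
#'   tilt_y_um_per_mm, vbs_um}); the vbs column is non-increasing.
#' @slot converged logical, FALSE when the iteration budget was exhausted
#'   (best-so-far parameters are still returned).
#'
#' @seealso [autoRegister()]
#' @name RegistrationFit-class
#' @rdname RegistrationFit-class
#' @exportClass RegistrationFit
setClass("RegistrationFit",
  representation(
    params = "RegistrationParams", report = "ZoneReport",
    trace = "data.frame", converged = "logical"
  )
)

#' CorneaSpec: parametric model of one corneal surface
#'
#' A conicoid (biconic via toric add-on) surface: apical radius and
#' asphericity Q define the rotationally symmetric sagitta; elevation is
#' expressed relative to a reference sphere (best-fit by default), in
#' micrometers, as device elevation maps are. Optional components: a toric
#' (astigmatic) elevation term \code{cyl * cos^2(theta - axis) * (r/rmax)^2}
#' and a Gaussian cone bump (keratoconus surrogate).
#'
#' @slot apicalRadius apical radius of curvature in mm (anterior default 7.8).
#' @slot q asphericity (default -0.25, prolate).
#' @slot cylAmp toric elevation amplitude in micrometers at the footprint
#'   edge (0 = no astigmatism).
#' @slot cylAxis toric axis in degrees.
#' @slot cone list, empty for none, else fields \code{amplitude_um},
#'   \code{sigma_mm}, \code{center_x_mm}, \code{center_y_mm}.
#' @slot footprint measured footprint diameter in mm (default 12); points
#'   outside are missing, matching the circular Scheimpflug coverage.
#'
#' @seealso [CorneaSpec()], [renderSurface()]
#' @name CorneaSpec-class
#' @rdname CorneaSpec-class
#' @exportClass CorneaSpec
setClass("CorneaSpec",
  representation(
    apicalRadius = "numeric", q = "numeric",
    cylAmp = "numeric", cylAxis = "numeric",
    cone = "list", footprint = "numeric"
  )
)

setValidity("CorneaSpec", function(object) {
  msg <- character()
  if (!(length(object@apicalRadius) == 1 && is.finite(object@apicalRadius) &&
        object@apicalRadius > 0)) {
    msg <- c(msg, "apicalRadius must be a single positive number (mm)")
  }
  if (!(length(object@footprint) == 1 && is.finite(object@footprint) &&
        object@footprint > 0)) {
    msg <- c(msg, "footprint must be a single positive number (mm)")
  }
  if (!(length(object@cylAmp) == 1 && is.finite(object@cylAmp) &&
        object@cylAmp >= 0)) {
    msg <- c(msg, "cylAmp must be a single non-negative number (um)")
  }
  if (length(object@cone)) {
    need <- c("amplitude_um", "sigma_mm", "center_x_mm", "center_y_mm")
    if (!all(need %in% names(object@cone))) {
      msg <- c(msg, sprintf("cone must have fields %s", paste(need, collapse = ", ")))
    } else {
      if (object@cone$sigma_mm <= 0) msg <- c(msg, "cone sigma_mm must be > 0")
      if (object@cone$amplitude_um < 0) msg <- c(msg, "cone amplitude_um must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PairSpec: recipe for a synthetic fellow-eye pair
#'
#' Defines a simulated acquisition: the right eye (OD) is the base surface
#' with per-field perturbations (\code{delta}) applied; the left eye (OS) is
#' the mirror image of the unperturbed base, observed through an injected
#' acquisition misalignment and per-eye additive Gaussian measurement noise.
#' Optional per-eye smooth irregularity fields model true higher-order
#' interocular asymmetry in normal corneas.
#'
#' @slot base the shared [CorneaSpec-class].
#' @slot delta named list of perturbations applied to the OD copy of
#'   \code{base}: numeric fields are added (\code{apicalRadius}, \code{q},
#'   \code{cylAmp}, \code{cylAxis}); a \code{cone} entry replaces the cone.
#' @slot misalign [RegistrationParams-class] injected into the OS
#'   acquisition (its \code{flip} must be FALSE; the anatomical mirroring is
#'   applied separately).
#' @slot noiseSd per-eye additive Gaussian measurement noise sd in
#'   micrometers (default 0).
#' @slot irrRms per-eye independent smooth irregularity RMS within the
#'   central 4 mm, micrometers (default 0): true interocular asymmetry.
#' @slot sharedIrrRms RMS of a smooth higher-order shape component shared
#'   (mirror-symmetrically) by both eyes, micrometers (default 0); fellow
#'   eyes share such detail, and it is what anchors the registration.
#' @slot seed integer seed fixing all randomness of [makePair()].
#' @slot n,spacing grid size and step (mm).
#' @slot referenceRadius reference sphere radius in mm, or \code{NA} for the
#'   best-fit sphere of the base conicoid (shared by both eyes).
#'
#' @seealso [PairSpec()], [makePair()], [makeCohort()]
#' @name PairSpec-class
#' @rdname PairSpec-class
#' @exportClass PairSpec
setClass("PairSpec",
  representation(
    base = "CorneaSpec", delta = "list", misalign = "RegistrationParams",
    noiseSd = "numeric", irrRms = "numeric", sharedIrrRms = "numeric",
    seed = "integer",
    n = "integer", spacing = "numeric", referenceRadius = "numeric"
  )
)

setValidity("PairSpec", function(object) {
  msg <- character()
  if (object@misalign@flip) {
    msg <- c(msg, "misalign@flip must be FALSE (mirroring is applied separately)")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@irrRms < 0) msg <- c(msg, "irrRms must be >= 0")
  if (object@sharedIrrRms < 0) msg <- c(msg, "sharedIrrRms must be >= 0")
  if (object@n < 8) msg <- c(msg, "n must be at least 8")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' PairAnalysis: full analysis of one fellow-eye pair
#'
#' @slot layer surface analyzed ("anterior" or "posterior").
#' @slot params final [RegistrationParams-class].
#' @slot reports named list of [ZoneReport-class] objects, one per requested
#'   zone diameter (names like "4" and "6").
#' @slot pattern [PatternLabel-class] on the primary zone.
#' @slot diff the registered [DifferenceMap-class].
#' @slot trace optimization trace (empty for manual mode).
#' @slot converged logical.
#'
#' @seealso [analyzePair()]
#' @name PairAnalysis-class
#' @rdname PairAnalysis-class
#' @exportClass PairAnalysis
setClass("PairAnalysis",
  representation(
    layer = "character", params = "RegistrationParams", reports = "list",
    pattern = "PatternLabel", diff = "DifferenceMap",
    trace = "data.frame", converged = "logical"
  )
)
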