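#' @include registration.R
NULL

#' Control settings for the pattern classifier
#'
#' @param flatThreshold RMS (non-piston, fitted) below which a map is
#'   \code{flat}, in micrometers (default 3).
#' @param dominance minimum fraction of non-piston Zernike energy a term
#'   group must carry to decide the label (default 0.5).
#' @param minCoverage minimum in-zone coverage.
#' @return a named list of settings for [classifyPattern()].
#' @export
patternControl <- function(flatThreshold = 3, dominance = 0.5,
                           minCoverage = 0.9) {
  list(flatThreshold = flatThreshold, dominance = dominance,
       minCoverage = minCoverage)
}

#' Rule-based classification of interocular symmetry patterns
#'
#' Classifies a registered signed difference map into one of the canonical
#' interocular symmetry patterns: \code{flat} (high symmetry, normal),
#' \code{tilt} (residual angular misalignment or visual-axis discrepancy),
#' \code{cone} (central bulge asymmetry, keratoconus-like), \code{four_leaf}
#' (quadrant pattern of aniso-astigmatism), or \code{irregular}.
#'
#' The rule operates on the low-order Zernike spectrum of the signed
#' difference over the zone (see [zernikeFit()]). Piston is excluded
#' everywhere, so classification is invariant to adding a constant. With
#' energy fractions of the non-piston spectrum:
#' \itemize{
#'   \item fitted non-piston RMS below \code{flatThreshold} gives \code{flat};
#'   \item otherwise the dominant group decides: tilt terms Z1.-1/Z1.1 give
#'     \code{tilt}; astigmatism terms Z2.-2/Z2.2 give \code{four_leaf};
#'     defocus/spherical terms Z2.0/Z4.0 give \code{cone}, provided the
#'     central deviation of the map agrees in sign with the fitted radial
#'     profile at the center;
#'   \item no group reaching \code{dominance} gives \code{irregular}.
#' }
#' Scores are the energy fractions (plus the higher-order remainder for
#' \code{irregular}), normalized to sum to 1 with the winning label's score
#' made the argmax.
#'
#' @param diff a registered [DifferenceMap-class].
#' @param zone the [Zone-class] analyzed (default 4 mm).
#' @param control see [patternControl()].
#' @return a [PatternLabel-class].
#' @export
classifyPattern <- function(diff, zone = Zone(4), control = patternControl()) {
  coefs <- zernikeFit(diff, zone, minCoverage = control$minCoverage)
  nonPiston <- coefs[-1]
  energy <- nonPiston^2
  total <- sum(energy)
  rms <- sqrt(total)
  labs <- c("flat", "tilt", "cone", "four_leaf", "irregular")
  scores <- stats::setNames(numeric(5), labs)

  if (rms < control$flatThreshold) {
    scores["flat"] <- 1
    return(new("PatternLabel", label = "flat", scores = scores,
               coefficients = coefs, rms = rms))
  }
  fTilt <- sum(energy[c("Z1.-1", "Z1.1")]) / total
  fAstig <- sum(energy[c("Z2.-2", "Z2.2")]) / total
  fCone <- sum(energy[c("Z2.0", "Z4.0")]) / total
  fRest <- max(0, 1 - fTilt - fAstig - fCone)
  fracs <- c(tilt = fTilt, cone = fCone, four_leaf = fAstig)
  label <- names(which.max(fracs))
  if (fracs[label] < control$dominance) {
    label <- "irregular"
  } else if (label == "cone" && !.coneSignConsistent(diff, zone, coefs)) {
    label <- "irregular"
  }
  scores["tilt"] <- fTilt; scores["cone"] <- fCone
  scores["four_leaf"] <- fAstig; scores["irregular"] <- fRest
  if (scores[label] < max(scores)) scores[label] <- max(scores) + 1e-6
  scores <- scores / sum(scores)
  new("PatternLabel", label = label, scores = scores,
      coefficients = coefs, rms = rms)
}

# the central deviation of the map (mean within rho <= 0.25, relative to the
# zone mean) must agree in sign with the fitted piston-free radial profile
# at the center, else the "cone" evidence is spurious
.coneSignConsistent <- function(diff, zone, coefs) {
  r <- .radiusFrom(diff, zone)
  radius <- zone@diameter / 2
  valid <- !is.na(diff@signed)
  inzone <- (r <= radius) & valid
  central <- (r <= 0.25 * radius) & valid
  if (!any(central)) return(TRUE)
  observed <- mean(diff@signed[central]) - mean(diff@signed[inzone])
  predicted <- -sqrt(3) * coefs[["Z2.0"]] + sqrt(5) * coefs[["Z4.0"]]
  observed == 0 || predicted == 0 || sign(observed) == sign(predicted)
}

setMethod("show", "PatternLabel", function(object) {
  cat(sprintf("PatternLabel: %s (non-piston RMS %.2f um)\n",
              object@label, object@rms))
  s <- sort(object@scores, decreasing = TRUE)
  cat("  scores:", paste(sprintf("%s=%.2f", names(s), s), collapse = " "), "\n")
})
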