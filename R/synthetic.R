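#' @include screening.R
NULL

# evaluate expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sagitta of a conicoid surface
#'
#' Axial depth at radial distance \code{r} for a conic of apical radius
#' \code{R} and asphericity \code{Q}:
#' \deqn{z(r) = \frac{r^2}{R\,(1 + \sqrt{1 - (1+Q) r^2 / R^2})}.}
#' \code{Q = 0} gives a sphere; negative Q a prolate (cornea-like) surface.
#'
#' @param r radial distance, mm (vectorized).
#' @param R apical radius of curvature, mm.
#' @param Q asphericity.
#' @return sagitta in mm; NA where the conic is undefined.
#' @export
conicSagitta <- function(r, R, Q = 0) {
  disc <- 1 - (1 + Q) * r^2 / R^2
  out <- rep(NA_real_, length(r))
  ok <- !is.na(disc) & disc >= 0
  out[ok] <- r[ok]^2 / (R * (1 + sqrt(disc[ok])))
  out
}

#' Best-fit (apex-touching) reference sphere radius
#'
#' Radius of the sphere minimizing the area-weighted squared sagitta
#' deviation from the conicoid over the fit diameter, as device elevation
#' maps are referenced to a best-fit sphere.
#'
#' @param spec a [CorneaSpec-class].
#' @param fitDiameter fit zone diameter in mm (default the footprint).
#' @return radius in mm.
#' @export
bestFitSphereRadius <- function(spec, fitDiameter = spec@footprint) {
  rg <- seq(0, fitDiameter / 2, length.out = 201)[-1]
  zc <- conicSagitta(rg, spec@apicalRadius, spec@q)
  obj <- function(R) sum(rg * (zc - conicSagitta(rg, R, 0))^2, na.rm = TRUE)
  stats::optimize(obj, interval = spec@apicalRadius * c(0.5, 2))$minimum
}

#' Construct a CorneaSpec
#'
#' @param apicalRadius apical radius of curvature, mm (anterior corneas
#'   are near 7.8, posterior near 6.5).
#' @param q asphericity (default -0.25).
#' @param cylAmp toric elevation amplitude at the footprint edge, um.
#' @param cylAxis toric axis, degrees.
#' @param cone \code{NULL} for none, or a list with \code{amplitude_um},
#'   \code{sigma_mm}, \code{center_x_mm}, \code{center_y_mm}.
#' @param footprint measured footprint diameter, mm (default 12).
#' @return a [CorneaSpec-class].
#' @export
CorneaSpec <- function(apicalRadius = 7.8, q = -0.25, cylAmp = 0,
                       cylAxis = 0, cone = NULL, footprint = 12) {
  new("CorneaSpec", apicalRadius = apicalRadius, q = q, cylAmp = cylAmp,
      cylAxis = cylAxis, cone = if (is.null(cone)) list() else cone,
      footprint = footprint)
}

#' Render a synthetic corneal elevation grid
#'
#' Elevation in micrometers relative to a reference sphere: conicoid sagitta
#' minus reference-sphere sagitta, plus the toric term
#' \code{cylAmp * cos^2(theta - axis) * (r / rmax)^2} and the Gaussian cone
#' bump if present. Points outside the circular footprint are missing,
#' emulating Scheimpflug coverage (140 x 140 = 19600 cells but only the
#' disc is measured).
#'
#' @param spec a [CorneaSpec-class].
#' @param n grid size (default 140).
#' @param spacing grid step, mm (default 0.1).
#' @param referenceRadius reference sphere radius in mm; \code{NA} (default)
#'   fits the best-fit sphere of the conicoid, see [bestFitSphereRadius()].
#' @param side,layer grid metadata.
#' @return an [ElevationGrid-class].
#' @examples
#' g <- renderSurface(CorneaSpec(), n = 80)
#' @export
renderSurface <- function(spec, n = 140, spacing = 0.1, referenceRadius = NA,
                          side = "OD", layer = "anterior") {
  if (spec@footprint > n * spacing) {
    stop(sprintf("footprint %.1f mm exceeds the grid extent %.1f mm",
                 spec@footprint, n * spacing))
  }
  ctr <- rep((n + 1) / 2, 2)
  xs <- (seq_len(n) - ctr[2]) * spacing
  ys <- (seq_len(n) - ctr[1]) * spacing
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  r <- sqrt(X^2 + Y^2)
  if (is.na(referenceRadius)) referenceRadius <- bestFitSphereRadius(spec)
  elev <- matrix((conicSagitta(as.vector(r), spec@apicalRadius, spec@q) -
                  conicSagitta(as.vector(r), referenceRadius, 0)) * 1000,
                 n, n)
  if (spec@cylAmp > 0) {
    theta <- atan2(Y, X)
    ax <- spec@cylAxis * pi / 180
    elev <- elev + spec@cylAmp * cos(theta - ax)^2 * (r / (spec@footprint / 2))^2
  }
  if (length(spec@cone)) {
    cn <- spec@cone
    d2 <- (X - cn$center_x_mm)^2 + (Y - cn$center_y_mm)^2
    elev <- elev + cn$amplitude_um * exp(-d2 / (2 * cn$sigma_mm^2))
  }
  elev[r > spec@footprint / 2] <- NA_real_
  ElevationGrid(elev, spacing = spacing, center = ctr, side = side,
                layer = layer,
                meta = list(synthetic = TRUE,
                            reference_radius_mm = referenceRadius))
}

# apply a delta list to a CorneaSpec: numeric fields add, cone replaces
.applySpecDelta <- function(spec, delta) {
  out <- spec
  for (f in c("apicalRadius", "q", "cylAxis")) {
    if (!is.null(delta[[f]])) slot(out, f) <- slot(out, f) + delta[[f]]
  }
  if (!is.null(delta$cylAmp)) {
    out@cylAmp <- max(0, out@cylAmp + delta$cylAmp)
  }
  if (!is.null(delta$cone)) {
    out@cone <- if (is.null(delta$cone$amplitude_um)) list() else delta$cone
  }
  validObject(out)
  out
}

# random irregularity field: Gaussian bumps with scales drawn from
# `scales` (mm), centers within r <= 3.5 mm, scaled to a target RMS within
# the central 4 mm; uses the current RNG.
#
# Two flavors are used by the simulator. The mirror-shared component uses
# mid scales (0.4-1.1 mm): coherent height detail both corneas share, which
# is what anchors rigid registration. The per-eye independent component
# uses fine scales (0.15-0.45 mm): a VBS-minimizing registration cannot
# absorb structure that decorrelates within a fraction of the search step,
# so this models the residual (observable) interocular asymmetry directly.
.irrField <- function(n, spacing, rms, scales = c(0.4, 1.1), nBumps = 24) {
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * spacing
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  field <- matrix(0, n, n)
  for (k in seq_len(nBumps)) {
    rad <- sqrt(stats::runif(1)) * 3.5
    ang <- stats::runif(1, 0, 2 * pi)
    cx <- rad * cos(ang); cy <- rad * sin(ang)
    sg <- stats::runif(1, scales[1], scales[2])
    amp <- stats::rnorm(1)
    field <- field + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
  }
  central <- sqrt(X^2 + Y^2) <= 2
  cur <- sqrt(mean(field[central]^2))
  if (cur > 0) field <- field * rms / cur
  field
}

.fineIrrField <- function(n, spacing, rms) {
  .irrField(n, spacing, rms, scales = c(0.15, 0.45), nBumps = 150)
}

#' Construct a PairSpec
#'
#' @param base shared [CorneaSpec-class] (default a typical anterior
#'   cornea).
#' @param delta named list of per-field perturbations applied to the right
#'   eye's copy of \code{base} (see [PairSpec-class]).
#' @param misalign injected acquisition misalignment
#'   ([RegistrationParams-class], flip = FALSE).
#' @param noiseSd per-eye Gaussian measurement noise sd, um (default 0).
#' @param irrRms per-eye independent smooth irregularity RMS within the
#'   central 4 mm, um (default 0): true interocular asymmetry.
#' @param sharedIrrRms RMS of the smooth higher-order component shared
#'   mirror-symmetrically by both eyes, um (default 0).
#' @param seed integer seed (default 1).
#' @param n,spacing grid geometry.
#' @param referenceRadius shared reference sphere radius, or NA for the
#'   best-fit sphere of \code{base}.
#' @return a [PairSpec-class].
#' @export
PairSpec <- function(base = CorneaSpec(), delta = list(),
                     misalign = RegistrationParams(), noiseSd = 0,
                     irrRms = 0, sharedIrrRms = 0, seed = 1L, n = 140L,
                     spacing = 0.1, referenceRadius = NA_real_) {
  new("PairSpec", base = base, delta = delta, misalign = misalign,
      noiseSd = noiseSd, irrRms = irrRms, sharedIrrRms = sharedIrrRms,
      seed = as.integer(seed), n = as.integer(n), spacing = spacing,
      referenceRadius = as.numeric(referenceRadius))
}

#' Simulate a fellow-eye elevation grid pair
#'
#' The right eye (OD) is the base surface with \code{delta} applied; the
#' left eye (OS) is the mirror image of the unperturbed base, observed
#' through the injected misalignment transform; both eyes then receive
#' independent Gaussian measurement noise of sd \code{noiseSd} (so a pair
#' whose only asymmetry is noise has expected aligned VBS
#' \eqn{2\sigma/\sqrt{\pi}}). Per-eye irregularity fields, if requested,
#' model true higher-order asymmetry. Both surfaces share the base's
#' best-fit reference sphere unless \code{referenceRadius} is given.
#'
#' @param spec a [PairSpec-class].
#' @return list with elements \code{od}, \code{os}
#'   ([ElevationGrid-class]) and \code{truth}, a list carrying
#'   \code{injected} (the misalignment), \code{aligning} (the exact
#'   [RegistrationParams-class] that re-register the pair, i.e. the mirror
#'   conjugate inverse of the injected transform, flip = TRUE),
#'   \code{vbs4}/\code{vbs6} (noise-free mirror-registered VBS on the 4 and
#'   6 mm zones) and \code{noiseSd}.
#' @examples
#' p <- makePair(PairSpec(seed = 3L, n = 80L))
#' p$truth$vbs4   # 0 for a perfect twin
#' @export
makePair <- function(spec) {
  validObject(spec)
  refR <- if (is.na(spec@referenceRadius)) bestFitSphereRadius(spec@base)
          else spec@referenceRadius
  odSpec <- .applySpecDelta(spec@base, spec@delta)
  .withSeed(spec@seed, {
    od <- renderSurface(odSpec, n = spec@n, spacing = spec@spacing,
                        referenceRadius = refR, side = "OD")
    osSurf <- renderSurface(spec@base, n = spec@n, spacing = spec@spacing,
                            referenceRadius = refR, side = "OS")
    if (spec@sharedIrrRms > 0) {
      shared <- .irrField(spec@n, spec@spacing, spec@sharedIrrRms)
      od@values <- od@values + shared
      osSurf@values <- osSurf@values + shared
    }
    if (spec@irrRms > 0) {
      od@values <- od@values + .fineIrrField(spec@n, spec@spacing, spec@irrRms)
      osSurf@values <- osSurf@values +
        .fineIrrField(spec@n, spec@spacing, spec@irrRms)
    }
    truth <- list(
      injected = spec@misalign,
      aligning = .invertParams(.mirrorConjugate(spec@misalign)),
      noiseSd = spec@noiseSd,
      reference_radius_mm = refR
    )
    truth$aligning@flip <- TRUE
    gt <- differenceMap(osSurf, od)
    truth$vbs4 <- vbs(vbsReport(gt, Zone(4)))
    truth$vbs6 <- vbs(vbsReport(gt, Zone(6)))
    os <- applyTransform(applyFlip(osSurf), spec@misalign,
                         bounds = transformBounds(shift_mm = Inf,
                                                  rot_deg = Inf,
                                                  tilt_um_per_mm = Inf))
    if (spec@noiseSd > 0) {
      nz <- spec@n
      od@values <- od@values +
        matrix(stats::rnorm(nz^2, 0, spec@noiseSd), nz, nz)
      os@values <- os@values +
        matrix(stats::rnorm(nz^2, 0, spec@noiseSd), nz, nz)
    }
    list(od = od, os = os, truth = truth)
  })
}

# scenario priors for makeCohort; amplitudes in um, lengths in mm
.scenarioPriors <- function(scenario) {
  list(
    baseRadius = c(7.8, 0.1), baseQ = c(-0.25, 0.05),
    baseCyl = c(30, 90), deltaRadiusSd = 0.02, deltaQSd = 0.02,
    deltaCylSd = 4, deltaAxisSd = 8, irrRms = c(5.5, 7.5),
    sharedIrrRms = c(2.5, 4.5),
    shift = 0.4, rot = 4, dz = 10, tilt = 8, noiseSd = 1,
    coneAmp = c(25, 60), coneSigma = c(0.6, 1.0), coneCenter = 0.8,
    withCones = identical(scenario, "separated")
  )
}

#' Simulate a labeled cohort of fellow-eye pairs
#'
#' Draws per-pair anatomy (base conicoid, toricity, interocular deltas,
#' irregularity), acquisition misalignments and noise from the scenario
#' priors, writes each eye's anterior elevation grid in the CSV dialect of
#' [writeElevationCsv()], and writes a manifest pairing the files with
#' diagnosis labels. Fully reproducible from the seed.
#'
#' Scenarios: \code{"separated"} gives the case group a unilateral
#' keratoconus cone (amplitude uniform 15--40 um, confined near the corneal
#' center) on top of the shared normal anatomy; \code{"null"} makes both
#' groups cone-free, so screening performance should be at chance.
#'
#' @param nNormal,nCase group sizes.
#' @param dir output directory (created if needed).
#' @param scenario \code{"separated"} or \code{"null"}.
#' @param seed integer seed.
#' @param n,spacing grid geometry.
#' @return the manifest data.frame (also written to
#'   \code{file.path(dir, "manifest.csv")}), with the per-pair ground truth
#'   attached as attribute \code{"truth"}.
#' @export
makeCohort <- function(nNormal = 30, nCase = 30, dir,
                       scenario = c("separated", "null"), seed = 1,
                       n = 140, spacing = 0.1) {
  scenario <- match.arg(scenario)
  pr <- .scenarioPriors(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- c(rep("normal", nNormal), rep("keratoconus", nCase))
  rows <- list(); truths <- list()
  for (i in seq_along(labels)) {
    pairSeed <- as.integer(seed) * 1000L + i
    draw <- .withSeed(pairSeed, {
      base <- CorneaSpec(
        apicalRadius = stats::rnorm(1, pr$baseRadius[1], pr$baseRadius[2]),
        q = stats::rnorm(1, pr$baseQ[1], pr$baseQ[2]),
        cylAmp = stats::runif(1, pr$baseCyl[1], pr$baseCyl[2]),
        cylAxis = stats::runif(1, 0, 180),
        footprint = min(12, n * spacing))
      delta <- list(
        apicalRadius = stats::rnorm(1, 0, pr$deltaRadiusSd),
        q = stats::rnorm(1, 0, pr$deltaQSd),
        cylAmp = stats::rnorm(1, 0, pr$deltaCylSd),
        cylAxis = stats::rnorm(1, 0, pr$deltaAxisSd))
      if (pr$withCones && labels[i] == "keratoconus") {
        rad <- stats::runif(1, 0, pr$coneCenter)
        ang <- stats::runif(1, 0, 2 * pi)
        delta$cone <- list(
          amplitude_um = stats::runif(1, pr$coneAmp[1], pr$coneAmp[2]),
          sigma_mm = stats::runif(1, pr$coneSigma[1], pr$coneSigma[2]),
          center_x_mm = rad * cos(ang), center_y_mm = rad * sin(ang))
      }
      mis <- RegistrationParams(
        dx = stats::runif(1, -pr$shift, pr$shift),
        dy = stats::runif(1, -pr$shift, pr$shift),
        dz = stats::runif(1, -pr$dz, pr$dz),
        rot = stats::runif(1, -pr$rot, pr$rot),
        tiltX = stats::runif(1, -pr$tilt, pr$tilt),
        tiltY = stats::runif(1, -pr$tilt, pr$tilt))
      irr <- stats::runif(1, pr$irrRms[1], pr$irrRms[2])
      shared <- stats::runif(1, pr$sharedIrrRms[1], pr$sharedIrrRms[2])
      list(base = base, delta = delta, mis = mis, irr = irr, shared = shared)
    })
    pair <- makePair(PairSpec(
      base = draw$base, delta = draw$delta, misalign = draw$mis,
      noiseSd = pr$noiseSd, irrRms = draw$irr, sharedIrrRms = draw$shared,
      seed = pairSeed + 500000L, n = n, spacing = spacing))
    id <- sprintf("pair%03d", i)
    odPath <- file.path(dir, paste0(id, "_od_anterior.csv"))
    osPath <- file.path(dir, paste0(id, "_os_anterior.csv"))
    writeElevationCsv(pair$od, odPath)
    writeElevationCsv(pair$os, osPath)
    rows[[i]] <- data.frame(
      pair_id = id,
      od_anterior_path = basename(odPath), os_anterior_path = basename(osPath),
      od_posterior_path = "", os_posterior_path = "", label = labels[i])
    truths[[id]] <- pair$truth
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  # returned copy carries resolved paths; the CSV stays relative/portable
  for (cc in c("od_anterior_path", "os_anterior_path")) {
    manifest[[cc]] <- file.path(dir, manifest[[cc]])
  }
  attr(manifest, "truth") <- truths
  invisible(manifest)
}

#' Canonical pattern difference maps for classifier validation
#'
#' Generates a signed difference map whose true label is known by
#' construction: \code{flat} is a near-zero field (sub-micrometer plane and
#' defocus), \code{tilt} a plane of 4--9 um/mm in a random direction,
#' \code{cone} a central Gaussian bump (15--35 um, sigma 0.7--1.1 mm,
#' center within 0.4 mm, random sign), and \code{four_leaf} an astigmatic
#' quadrant field \code{A cos(2(theta - axis)) (r/R)^2} with A of 10--25 um.
#' Amplitudes are drawn so each noiseless field is unambiguous under the
#' classifier's energy rules. Optional Gaussian noise is added point-wise.
#'
#' @param pattern one of "flat", "tilt", "cone", "four_leaf".
#' @param seed integer seed.
#' @param noiseSd additive noise sd, um (default 0).
#' @param n,spacing grid geometry.
#' @param zoneDiameter zone used to scale the fields (default 4 mm).
#' @return list with \code{diff} (a [DifferenceMap-class], footprint-masked)
#'   and \code{label}.
#' @export
simulatePatternMap <- function(pattern = c("flat", "tilt", "cone", "four_leaf"),
                               seed = 1, noiseSd = 0, n = 140, spacing = 0.1,
                               zoneDiameter = 4) {
  pattern <- match.arg(pattern)
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * spacing
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  r <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  R <- zoneDiameter / 2
  field <- .withSeed(seed, {
    f <- switch(pattern,
      flat = {
        dir <- stats::runif(1, 0, 2 * pi)
        stats::runif(1, 0, 0.2) * (X * cos(dir) + Y * sin(dir)) +
          stats::runif(1, 0, 0.5) * (r / R)^2
      },
      tilt = {
        dir <- stats::runif(1, 0, 2 * pi)
        stats::runif(1, 4, 9) * (X * cos(dir) + Y * sin(dir))
      },
      cone = {
        A <- stats::runif(1, 15, 35) * sample(c(-1, 1), 1)
        sg <- stats::runif(1, 0.7, 1.1)
        rad <- stats::runif(1, 0, 0.4); ang <- stats::runif(1, 0, 2 * pi)
        A * exp(-((X - rad * cos(ang))^2 + (Y - rad * sin(ang))^2) / (2 * sg^2))
      },
      four_leaf = {
        A <- stats::runif(1, 10, 25) * sample(c(-1, 1), 1)
        ax <- stats::runif(1, 0, pi)
        A * cos(2 * (theta - ax)) * (r / R)^2
      })
    if (noiseSd > 0) f <- f + matrix(stats::rnorm(n^2, 0, noiseSd), n, n)
    f
  })
  field[r > 6] <- NA_real_
  list(diff = new("DifferenceMap", signed = field, spacing = spacing,
                  center = c(ctr, ctr)),
       label = pattern)
}
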