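#' @include synthetic.R
NULL

#' Full symmetry analysis of one fellow-eye pair
#'
#' Registers the left eye onto the right (auto mode minimizes the VBS;
#' manual mode evaluates user-supplied parameters), then reports the VBS and
#' ring summaries on every requested zone and classifies the residual
#' difference pattern on the primary (first) zone.
#'
#' @param od,os right- and left-eye [ElevationGrid-class] objects of the
#'   same surface layer.
#' @param zones numeric zone diameters in mm (default \code{c(4, 6)}); the
#'   first is the registration objective and the pattern zone.
#' @param mode \code{"auto"} (default) or \code{"manual"}.
#' @param params [RegistrationParams-class] for manual mode (default:
#'   mirror flip only, no adjustments).
#' @param control see [registrationControl()].
#' @param patternCtrl see [patternControl()].
#' @return a [PairAnalysis-class].
#' @examples
#' p <- makePair(PairSpec(seed = 11L, n = 80L))
#' a <- analyzePair(p$od, p$os, zones = 4)
#' vbs(a@reports[["4"]])
#' @export
analyzePair <- function(od, os, zones = c(4, 6), mode = c("auto", "manual"),
                        params = RegistrationParams(flip = TRUE),
                        control = registrationControl(),
                        patternCtrl = patternControl()) {
  mode <- match.arg(mode)
  control$zone <- zones[1]
  if (mode == "auto") {
    fit <- autoRegister(os, od, zone = Zone(zones[1]), control = control)
    params <- fit@params
    trace <- fit@trace
    converged <- fit@converged
  } else {
    trace <- data.frame()
    converged <- TRUE
  }
  ev <- evaluateRegistration(os, od, params, zone = Zone(zones[1]),
                             minCoverage = control$minCoverage,
                             bounds = control$bounds)
  reports <- list(ev$report)
  for (z in zones[-1]) {
    reports <- c(reports, list(vbsReport(ev$diff, Zone(z),
                                         minCoverage = control$minCoverage)))
  }
  names(reports) <- as.character(zones)
  pattern <- classifyPattern(ev$diff, Zone(zones[1]), control = patternCtrl)
  new("PairAnalysis", layer = surfaceLayer(od), params = params,
      reports = reports, pattern = pattern, diff = ev$diff,
      trace = trace, converged = converged)
}

#' Register and summarize every pair of a cohort manifest
#'
#' Reads each pair's anterior grids, auto-registers them, and collects the
#' per-pair VBS on the requested zones; the screening workhorse.
#'
#' @param manifest data.frame from [readManifest()] or [makeCohort()].
#' @param zones zone diameters, mm.
#' @param control see [registrationControl()].
#' @param readConfig see [gridReadConfig()].
#' @param verbose print one line per pair with the VBS before (unadjusted
#'   mirror alignment) and after registration.
#' @return data.frame with columns \code{pair_id, label},
#'   \code{vbs_<zone>} per zone, and \code{converged}.
#' @export
analyzeCohort <- function(manifest, zones = c(4, 6),
                          control = registrationControl(),
                          readConfig = gridReadConfig(),
                          verbose = FALSE) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    odCfg <- readConfig; odCfg$side <- "OD"
    osCfg <- readConfig; osCfg$side <- "OS"
    od <- readElevationCsv(manifest$od_anterior_path[i], odCfg)
    os <- readElevationCsv(manifest$os_anterior_path[i], osCfg)
    a <- analyzePair(od, os, zones = zones, mode = "auto", control = control)
    if (verbose) {
      before <- vbs(evaluateRegistration(
        os, od, RegistrationParams(flip = TRUE), Zone(zones[1]),
        minCoverage = control$minCoverage)$report)
      message(sprintf("%s [%s]: VBS %.2f -> %.2f um (%.1f mm zone)",
                      manifest$pair_id[i], manifest$label[i],
                      before, vbs(a@reports[[1]]), zones[1]))
    }
    out <- data.frame(pair_id = manifest$pair_id[i],
                      label = manifest$label[i], converged = a@converged)
    for (z in as.character(zones)) {
      out[[paste0("vbs_", z)]] <- vbs(a@reports[[z]])
    }
    out
  })
  do.call(rbind, rows)
}

setMethod("show", "PairAnalysis", function(object) {
  cat(sprintf("PairAnalysis (%s surface)\n", object@layer))
  show(object@params)
  for (nm in names(object@reports)) {
    cat(sprintf("  %s mm zone: VBS %.3f um\n", nm, vbs(object@reports[[nm]])))
  }
  cat(sprintf("  pattern: %s\n", object@pattern@label))
})
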