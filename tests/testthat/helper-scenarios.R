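# Scenario builders used by the acceptance-level checks (and reusable
# elsewhere). Conditions: realistic normal corneas (0.5-2 D of toric
# elevation, prolate asphericity, mirror-shared higher-order detail), with
# acquisition misalignment and per-eye measurement noise as stated per test.

recoveryPair <- function(seed, noiseSd = 1, sharedIrrRms = 3) {
  .s <- as.integer(seed)
  base <- withr::with_seed(.s, CorneaSpec(
    apicalRadius = stats::rnorm(1, 7.8, 0.1),
    q = stats::rnorm(1, -0.25, 0.05),
    cylAmp = stats::runif(1, 30, 90),
    cylAxis = stats::runif(1, 0, 180)))
  mis <- withr::with_seed(.s + 7L, RegistrationParams(
    dx = stats::runif(1, -0.5, 0.5), dy = stats::runif(1, -0.5, 0.5),
    rot = stats::runif(1, -5, 5), dz = stats::runif(1, -10, 10),
    tiltX = stats::runif(1, -10, 10), tiltY = stats::runif(1, -10, 10)))
  makePair(PairSpec(base = base, misalign = mis, noiseSd = noiseSd,
                    sharedIrrRms = sharedIrrRms, seed = .s + 13L))
}

# median absolute recovery errors of autoRegister against the exact
# aligning ground truth, plus the noise-floor ratios, over `seeds`
recoveryErrors <- function(seeds, noiseSd = 1) {
  rows <- lapply(seeds, function(s) {
    p <- recoveryPair(s, noiseSd = noiseSd)
    fit <- autoRegister(p$os, p$od)
    al <- p$truth$aligning
    fl <- noiseFloorVBS(fit@params, applyFlip(p$os), Zone(4), noiseSd)
    tiltErr <- sqrt((fit@params@tiltX - al@tiltX)^2 +
                    (fit@params@tiltY - al@tiltY)^2)
    tiltMag <- max(sqrt(al@tiltX^2 + al@tiltY^2), 1)
    data.frame(edx = fit@params@dx - al@dx, edy = fit@params@dy - al@dy,
               erot = fit@params@rot - al@rot, tiltRel = tiltErr / tiltMag,
               vbs = vbs(fit@report), floor = fl,
               naive = 2 * noiseSd / sqrt(pi))
  })
  do.call(rbind, rows)
}
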