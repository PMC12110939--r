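# corneaSym

Bilateral corneal elevation symmetry analysis and keratoconus screening in R.

## The problem

Fellow eyes are near-perfect mirror images of each other, while corneal
ectasias such as keratoconus are typically asymmetric between the eyes. The
fellow eye is therefore an ideal patient-specific reference surface: subtract
one cornea from the mirrored other and the residual map exposes abnormality
that unilateral indices miss. `corneaSym` implements this comparison for
dense Scheimpflug tomography exports — square elevation matrices (typically
140 × 140 at 0.1 mm, micrometers relative to a best-fit sphere), one per eye
and corneal surface.

The core quantity is the **VBS index** ("volume between spheres"): after
rigidly registering the mirrored left eye onto the right eye — mirror flip,
in-plane shift `(dx, dy)`, frontal-plane rotation ρ, elevation offset `dz`
and planar tilt `(t_x, t_y)`, chosen to minimize the index itself —

```
VBS = mean over the zone of | E_OS'(x, y) − E_OD(x, y) |      [µm]
E_OS'(x, y) = E_OS(R_{−ρ}(x − dx, y − dy)) + dz + t_x x + t_y y
```

computed over a central corneal zone (4.0 mm and 6.0 mm are standard).
Registration uses a nested optimizer: Nelder–Mead over the geometric
parameters with the offset/tilt plane absorbed exactly by an L1 plane fit at
every step. The registered difference map is additionally classified into
canonical interocular patterns (*flat*, *tilt*, *cone*, *four-leaf*,
*irregular*) via its low-order Zernike spectrum, and cohort-level screening
(Welch group comparison, sensitivity/specificity/PPV threshold sweeps) is
provided, together with a fully controlled synthetic-cornea simulator used
as the validation test bed.

## Worked example

```r
library(corneaSym)

# Simulate a fellow-eye pair: a typical astigmatic cornea, mirror-shared
# higher-order detail, an injected acquisition misalignment, 1 um noise.
spec <- PairSpec(
  base = CorneaSpec(apicalRadius = 7.8, q = -0.25, cylAmp = 60, cylAxis = 30),
  misalign = RegistrationParams(dx = 0.3, dy = -0.2, rot = 3, dz = 8,
                                tiltX = 6, tiltY = -5),
  noiseSd = 1, sharedIrrRms = 3, seed = 42L)
p <- makePair(spec)

# Unadjusted mirror comparison, then auto-registration
before <- evaluateRegistration(p$os, p$od, RegistrationParams(flip = TRUE))
vbs(before$report)
#> [1] 9.084207
a <- analyzePair(p$od, p$os, zones = c(4, 6))
a
#> PairAnalysis (anterior surface)
#> RegistrationParams: flip=TRUE dx=0.282 mm dy=0.203 mm rot=2.967 deg
#>   dz=-10.742 um tilt=(5.679, 5.267) um/mm
#>   4 mm zone: VBS 0.949 um
#>   6 mm zone: VBS 0.973 um
#>   pattern: flat
plotDifferenceMap(a@diff)   # diverging map with 4/6 mm zone circles
```

The VBS drops from 9.1 µm (a level suggesting pathology) to 0.95 µm — the
measurement-noise floor — once the injected head misalignment is corrected,
and the residual pattern is *flat*: the simulated patient has healthy,
mirror-symmetric corneas. The recovered shift and rotation match the
injected misalignment (0.28/0.20 mm vs 0.3/0.2 mm, 2.97° vs 3°; the
correction is expressed in the mirrored left eye's frame, which flips some
signs). A keratoconic pair instead retains a
high central-zone VBS and a *cone* pattern after registration.

Cohort screening end to end:

```r
man <- makeCohort(30, 30, dir = "cohort", scenario = "separated", seed = 1)
res <- analyzeCohort(man, zones = c(4, 6))
compareGroups(res$vbs_4[res$label == "keratoconus"],
              res$vbs_4[res$label == "normal"],
              names = c("keratoconus", "normal"))
screenThresholds(res$vbs_4, res$label, thresholds = c(10.4, 11.3))
```

A command-line wrapper with `analyze`, `simulate` and `screen` subcommands
is installed at `system.file("cli/corneasym", package = "corneaSym")`.

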