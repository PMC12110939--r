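Package: corneaSym
Title: Bilateral Corneal Elevation Symmetry Analysis and Keratoconus Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying interocular symmetry of corneal surface
    elevation from Scheimpflug tomography exports. Fellow-eye 140x140
    elevation grids are registered rigidly (mirror flip, in-plane shift and
    rotation, elevation offset and planar tilt) by iterative minimization of
    the Volume Between Spheres (VBS) index, the mean absolute interocular
    elevation difference within a central corneal zone. Includes ring/zone
    summaries, a Zernike-based rule classifier for canonical asymmetry
    patterns (flat, tilt, cone, four-leaf), cohort-level screening statistics
    (Welch comparison, threshold sensitivity/specificity/PPV sweeps), a
    synthetic biconic cornea simulator for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'elevation-grid.R'
    'io.R'
    'transforms.R'
    'metrics.R'
    'zernike.R'
    'registration.R'
    'pattern.R'
    'screening.R'
    'synthetic.R'
    'analyze.R'
    'plot.R'
    'cli.R'
    'corneaSym-package.R'
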