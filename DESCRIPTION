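Package: pathscape
Title: Two-Dimensional RMSD Projection and Gaussian-Process Landscapes for
    Reaction Path Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing and visualization of saddle-search optimization
    histories (nudged elastic band, string methods). Maps every sampled
    molecular geometry onto permutation- and rotation-invariant RMSD
    distances to the reactant and product references, rotates that plane
    into a reaction-progress / orthogonal-deviation frame, and reconstructs
    a continuous color-mapped energy landscape with a gradient-enhanced
    Gaussian process using the inverse multiquadric kernel, including a
    Nystrom low-rank solver and posterior-variance reliability contours.
    Includes force-constrained one-dimensional energy profiles, a synthetic
    fixture generator lifting analytic two-dimensional landscapes into
    molecular coordinates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    clue,
    ggplot2,
    rlang,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'trajio.R'
    'permrmsd.R'
    'project2d.R'
    'pathgrad.R'
    'kernels.R'
    'gpsurface.R'
    'fixtures.R'
    'landscape.R'
    'cli.R'
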