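Package: braggshift
Title: Bragg-Peak Position Shifts and Dose Asymmetry for Proton Beams in
    Magnetic Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how a uniform magnetic field, such as the
    main field of an MRI scanner in MRI-guided proton therapy, displaces the
    Bragg peak of a scanned proton pencil beam in water. Implements the
    Bragg-Kleeman range-energy power law, a closed-form analytical model for
    the lateral Bragg-peak shift and the penetration-depth retraction together
    with its algebraic inversion for energy selection, a desk-scale transport
    simulator (deterministic pencil-beam and sampled Monte Carlo modes with
    Highland multiple scattering and range straggling) that scores voxelized
    3D dose grids, and analysis routines for peak localization, shift
    measurement, planar Gaussian asymmetry, inscribed/circumscribed isodose
    circle fitting and rotating full-width-half-maximum scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
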