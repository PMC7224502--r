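Package: tesfvm
Title: Finite-Volume Simulation of Transcranial Electric Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the electric field induced by transcranial
    electric stimulation (tES/tDCS) in volume-conductor head models. The
    package builds layered-sphere phantoms and tetrahedral meshes, positions
    scalp electrodes on a triangulated head surface according to the
    international 10-20 system, assigns isotropic or anisotropic (diffusion
    tensor derived, volume-constraint) conductivity tensors per mesh cell,
    and solves the quasi-static potential equation div(sigma grad phi) = 0
    with a cell-centered finite-volume scheme including iterative
    non-orthogonality correction. A Legendre-series analytic solution for
    point electrodes on concentric spheres provides quantitative
    verification, and field-comparison metrics (magnitude percentiles,
    hotspots, relative and angular difference maps, line profiles) support
    cross-solver comparison. Meshes, label images and surfaces are read and
    written in GMSH v2.2, VTU, NIfTI/ANALYZE, STL and OFF formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    oro.nifti,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
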