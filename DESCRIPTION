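Package: clonemap
Title: Clonal Dynamics, Membrane Properties, and Morphometry of
    Multicolor Fate-Mapped Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational analysis of multicolor (Confetti) fate-mapping
    data for microglia. Implements the Monte Carlo concentric-ring
    clonality statistic with label-permutation null bands, DBSCAN-based
    clone detection with clone density, clone size, and Ki-67
    proliferation indices, extraction of membrane properties (membrane
    resistance, capacitance, reversal potential, specific inward and
    outward conductances) and current-type classification from
    voltage-step recordings, and 3D morphometric feature extraction
    (surface area, volume, sphericity, inertia-ellipsoid semi-axes, and
    2D skeleton statistics) from binary cell masks. Includes seeded
    synthetic-data generators (homogeneous and Thomas-type clustered
    multicolor point patterns, conductance-model current traces,
    voxelized cell shapes) with ground truth, so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    minpack.lm,
    tiff,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
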