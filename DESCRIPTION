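Package: confcouple
Title: Conformational Coupling Analysis for Protein Trajectories and
    Thiamin-Enzyme Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing conformational coupling in molecular
    dynamics trajectories of thiamin diphosphate-dependent enzymes and for
    the accompanying biochemical assay calculations.  Provides structure,
    trajectory, selection and alignment input/output; Kabsch superposition
    and essential-dynamics principal component analysis with per-residue
    displacement profiles; aromatic ring-centroid pair distances, their
    correlation with principal components, two-dimensional free-energy
    surfaces with basin detection, and compensation scores; aromatic-cluster
    geometry and multiple-sequence-alignment conservation scans; enzyme
    assay mathematics (extinction coefficients, Michaelis-Menten fitting,
    slope-based catalytic efficiency, initial velocities, densitometry,
    circular dichroism signal normalisation, apparent melting temperatures,
    and fold-change summaries); and synthetic-data generators with analytic
    ground truth so every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
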