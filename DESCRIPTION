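Package: pacedys
Title: In Silico Comparison of Left Bundle Branch and Leadless Right
    Ventricular Pacing on Ventricular Dyssynchrony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates ventricular electrical activation on synthetic
    biventricular tetrahedral meshes equipped with a fascicular
    His-Purkinje conduction system, under intact conduction, proximal
    left bundle branch block, and septal scar substrates, and under left
    bundle branch pacing and leadless right ventricular septal pacing
    protocols. Activation is computed as first arrival on the mesh edge
    graph under transversely isotropic conduction, bidirectionally
    coupled to the Purkinje tree through Purkinje-myocardial junctions.
    Computes the interventricular and intraventricular dyssynchrony
    measures VEU, absolute VEU, LVDI and BIVAT-90, and cohort-level
    summaries and statistical comparisons. Reads and writes openCARP
    text meshes and VTK unstructured grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
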