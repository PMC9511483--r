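Package: molcham
Title: Conformer-Ensemble Profiling of Molecular Chameleonicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physicochemical profiling of flexible (beyond-Rule-of-5)
    molecules from solvent-labeled conformer ensembles. Computes
    per-conformer 3D polar surface area by numerical surface integration,
    radius of gyration, van der Waals volume and geometric intramolecular
    hydrogen-bond (IMHB) detection with configurable distance/angle
    relaxations; summarises ensembles per solvent (min/max/average/median
    statistics and cross-solvent deltas); builds tiled 2D property-density
    maps over (Rgyr, 3D PSA) with mode detection and representative-conformer
    selection; scores chameleonicity from polarity separation, cross-solvent
    conformer congruence, TPSA attainment and IMHB persistence; and
    implements chromatographic lipophilicity/polarity descriptors (BRlogD,
    log kW IAM, Delta log kW IAM, PLRP-S deviation from linearity) from
    retention-time tables. Includes analytic toy-geometry and Gaussian
    property-cloud generators so the whole pipeline is testable without
    external data, plus an adapter to an external distance-geometry
    conformer engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
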