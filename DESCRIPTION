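Package: cardionuc
Title: Sarcomere-Nuclear Strain Coupling and Perinuclear Mechanics in
    Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how contractile strain in beating cardiomyocytes is
    transferred to the nucleus, and how perinuclear microtubule forces shape
    and damage the nucleus. Provides seeded generators for contraction time
    series and nucleus-centred multi-channel images with analytic ground
    truth; strain-coupling metrics (peak strains, systolic and diastolic
    dampening areas, integrated nuclear strain); nuclear morphometrics
    (shape, perinuclear-to-cytoplasmic tubulin enrichment, chromatin
    protrusion scoring, perinuclear foci counting); loess and continuous
    two-segment breakpoint regression of aspect ratio against microtubule
    cage enrichment; and an axisymmetric finite-strain finite-element model
    of the resting cardiomyocyte with active myofibril contractility and
    microtubule-cage compression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    EBImage,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
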