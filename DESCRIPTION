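Package: synstereo
Title: Serial-Section Synaptic Morphometry and Stereology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative 3D morphometry of synaptic boutons from
    serial-section electron-microscopy contour annotations: reconstruction
    based volume and surface estimation, active-zone and postsynaptic-density
    area measures, vesicle-to-membrane perimeter analysis with functional
    pool classification, physical-disector synapse density estimation,
    Cavalieri point-count volume fractions, astrocytic coverage
    classification, and nonparametric descriptive and comparative
    statistics. Ships a calibrated synthetic serial-section generator with
    exact ground truth so every stage of the pipeline can be validated
    without raw micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
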