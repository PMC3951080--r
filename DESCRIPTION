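Package: voxdose
Title: Voxelized Monte Carlo Dosimetry for Solar-Particle-Event Radiobiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale condensed-history Monte Carlo dose engine for
    protons and electrons in voxelized geometries, built to support the
    dosimetry workflow of large-animal solar-particle-event (SPE)
    radiobiology experiments.  Includes Hounsfield-unit to material and
    density conversion for CT-based geometries, programmatic phantom
    construction (solid-water slabs, PMMA enclosure rigs, a digital
    minipig-like body), electron and broad parallel proton beam models,
    SPE proton-spectrum unfolding from measured depth-dose curves by
    non-negative least squares over a pristine Bragg-peak basis, and
    depth-dose, beam-mixing and dose-volume-histogram analysis.  Dose
    grids can be exported as DICOM RT-Dose for visualization software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
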