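Package: periDose
Title: Whole-Body Out-of-Field Dose Equivalent for Image-Guided Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical modelling of the whole-body dose equivalent delivered
    by image-guided external-beam radiotherapy. Computes the out-of-field
    photon stray dose as the sum of patient scatter, collimator scatter and
    head leakage, the peripheral photoneutron dose equivalent from a
    point-source model with radiological-depth attenuation, and the cone-beam
    CT imaging dose, fuses them with an in-field dose grid, derives per-voxel
    mean photon energies with detector energy-response corrections, and
    compares treatment techniques through dose-equivalent volume histograms.
    Includes a synthetic anthropomorphic phantom and plan generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
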