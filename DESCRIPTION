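Package: flyeye
Title: Connectome-Constrained Fly-Eye Networks for Individual Re-Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds trainable retinotopic neural networks whose layer graph is
    constrained by a declarative connectome table of the Drosophila optic lobe
    (photoreceptor, lamina, medulla and lobula cell types connected by locally
    connected filters), together with the image-processing paths used to study
    re-identification of individual flies at retinal resolution: acuity-limited
    Fourier filtering, bottleneck resizing, training-set standardization and a
    non-aspect-preserving random zoom. A procedural generator produces synthetic
    per-individual fly image chips with morphology that persists across
    recording days, so the full across-day re-identification experiment (split
    by day, train, evaluate with macro F1 and sex-collapsed F1) can be run end
    to end without access to video data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    rhdf5,
    yaml,
    jsonlite,
    glmnet,
    stats,
    utils,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
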