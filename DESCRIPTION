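Package: warplmm
Title: Warped Linear Mixed Models for Quantitative Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Linear mixed models that jointly infer a monotone phenotype
    transformation together with the genetic variance components. The
    package estimates narrow-sense (chip) heritability on the latent
    Gaussian scale, predicts phenotypes on the original measurement scale
    through the inverse transformation, performs mixed-model association
    scans on the transformed phenotype, and includes a forward-selection
    procedure that absorbs large-effect loci as extra variance components
    while the transformation is learned. A simulator for additive
    polygenic traits observed through nonlinear transformations is
    provided for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
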