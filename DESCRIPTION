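Package: oktopo
Title: Corneal Topography Grading for Orthokeratology Lens Fits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the post-wear corneal topography of orthokeratology (OK)
    lens patients. Segments the pupil and the treatment zone with U-Net-family
    encoder-decoder networks (U-Net, U-Net++, U-Net3+) trained by a built-in
    Adam/backpropagation engine, computes the clinical indicators decentration
    (Euclidean center distance at 50 px/mm) and the effective defocusing contact
    range (fraction of the pupil boundary in myopic defocus), and assigns one of
    four topography classes from optometrist grading rules. Ships a synthetic
    topography generator with analytically known ground truth so the whole
    pipeline is trainable and testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
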