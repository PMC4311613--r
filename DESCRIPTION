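Package: trisync
Title: Trilinear Decomposition of Spike-Train Synchrony Tensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies pairwise synchrony and oscillatory synchrony between
    multi-electrode spike trains via jitter-corrected cross-correlograms,
    assembles the resulting statistics into a three-way array (electrode
    pair x stimulus x repetition), and decomposes that array with a PARAFAC
    (canonical polyadic) model fitted by alternating least squares.
    Includes component-number selection by a congruence rule, split-half and
    residual-bootstrap validation, an unfolded-PCA bilinear baseline, and a
    synthetic spike-experiment generator with planted trilinear synchrony
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
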