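Package: flowrecon
Title: Self-Supervised Unrolled Reconstruction of Undersampled Phase-Contrast Flow MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-driven unrolled reconstruction of highly undersampled
    multi-velocity-encoded dynamic (4D flow) MRI. Implements the multicoil
    Cartesian SENSE encoding operator, a complex-valued bidirectional
    convolutional recurrent denoiser with closed-form data-consistency and
    weighted-averaging blocks, self-supervised training on partitions of the
    acquired k-space (SSDU), a four-point phase-contrast phantom simulator,
    and velocity decoding with eddy-current background-phase correction and
    quantitative flow error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
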