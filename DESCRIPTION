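Package: genoconnect
Title: Genomic Connectedness and Prediction Accuracy Under Non-Additive Gene Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates livestock-style populations with additive, dominance and
    epistatic trait architectures, builds pedigree and genomic relationship
    kernels (numerator relationship A, additive G, dominance D, Hadamard G#D,
    and Gaussian kernels), estimates variance components by restricted maximum
    likelihood, and quantifies genomic connectedness between management units
    via the coefficient of determination (CD) of unit contrasts alongside
    two-fold cross-validated prediction accuracy. Includes a scenario grid
    that varies the rate of individual exchange between units and compares
    additive against multi-kernel (kernel-averaged) models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
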