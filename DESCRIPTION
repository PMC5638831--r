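Package: wormetab
Title: Chemometric Analysis of 1H NMR Metabolomics for Earthworm
    Ecotoxicology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible analysis chain for 1D 1H NMR metabolomics in
    soil ecotoxicology: spectral import, water-region exclusion, adaptive
    binning, probability quotient normalization, orthogonal signal
    correction followed by partial least squares discriminant analysis
    (OSC-PLS-DA) with repeated two-fold cross-validation and permutation
    testing, statistical total correlation spectroscopy (STOCSY),
    metabolite-level fold-change tables with Benjamini-Hochberg
    correction, pathway over-representation and topology impact analysis,
    and bioaccumulation-factor bookkeeping for metal exposure studies.
    Includes a synthetic spectrum generator with known ground truth so
    every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
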