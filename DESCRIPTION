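Package: shedmap
Title: Mapping Sheddase Cleavage Sites from Semi-Specific Proteomics Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping ectodomain-shedding cleavage sites on membrane
    receptors from multi-protease semi-specific peptide evidence. Provides
    in-silico full and semi-specific protease digestion, classification of
    peptide termini as protease-consistent or non-canonical, aggregation of
    terminus evidence into concordant cleavage-site calls, theoretical b/y
    fragment-ion generation with tolerance-based peak matching and charge
    deconvolution, the spectrum contrast angle with bootstrap stability
    assessment, label-free proteome comparison with down-shifted-normal
    imputation and Benjamini-Hochberg corrected t tests, fluorescence
    shedding-ratio and FRET trace quantification, three-parameter
    concentration-response fitting with the extra-sum-of-squares F test, and
    seeded synthetic-data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
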