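Package: thiostoich
Title: Stoichiometric Mass Balance and Expression-Informed Models of
    Microbial Sulfur Oxidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing sulfur-oxidation pathways of
    acidophilic bacteria (Acidithiobacillus-type metabolism) from
    batch-culture solution chemistry and gene expression. Provides exact
    rational balancing, completion and composition of sulfur reactions
    over a curated library of oxidation, comproportionation and
    disproportionation reactions; by-difference mass balance of the
    unresolved sulfur-oxidation-intermediate ("Other SOI") pool from
    total dissolved sulfur and speciation time series; non-negative
    least-squares inference of reaction extents from observed
    concentration changes; integer normalisation of observed changes into
    net reactions; FPKM expression categorisation and gene-to-reaction
    support scoring; and a batch-culture simulator with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
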