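Package: cancerSig
Title: Integrated SNV, SV and MSI Mutational Signature Profiling and Deciphering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-tumor mutational feature profiles from somatic
    single-nucleotide variant calls (96 trinucleotide-context classes),
    structural-variant calls (4 event classes by 8 log10 size bins) and
    microsatellite-instability locus tables (18 canonical repeat-unit
    classes), merges them into one weighted feature matrix, deciphers
    shared mutational signatures by non-negative matrix factorization
    with bootstrap-stability rank selection, refits per-sample signature
    exposures, and renders per-sample decomposition reports together
    with a cohort-level normalized-weights table.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    vcfR,
    pracma,
    cluster,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
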