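Package: taxafun
Title: Taxa-Function Profiling and Verification for Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking microbial taxonomy to metabolic function in
    shotgun-metagenome surveys. Implements coverage-based verification of
    classifier taxonomic assignments (read re-mapping, breadth of coverage,
    and a confirmed-fraction decision rule for flagging potentially spurious
    genera), taxonomically stratified RPKM pathway profiling for nitrogen
    (KEGG map00910) and phosphonate/phosphinate (KEGG map00440) metabolism,
    permutation-based multivariate statistics (PERMANOVA with exact
    enumeration and Monte-Carlo fallback, PCoA, NMDS, Pearson correlation
    screens), and construction of treatment-genus-process flow tables for
    Sankey-style visualisation. A synthetic-community generator with planted
    ground truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
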