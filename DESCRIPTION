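Package: duplimap
Title: Mapping Duplicate-Gene Hybrid Incompatibilities from Cross Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting two-locus recessive hybrid
    incompatibilities caused by divergently resolved gene duplicates, built
    around the Mimulus hybrid seedling lethality system. Provides a forward
    cross simulator (inbred founders, Haldane meiosis, F1/F2/F3 schemes,
    pooled sequencing counts), a chi-squared screen over a catalog of
    segregation models, bulked segregant analysis with sliding-window
    allele-frequency scans and quantile region calling, recombinant
    fine-mapping with progeny tests and minimal-interval narrowing,
    duplicate-copy placement by diagnostic haplotype association with
    frameshift and premature-stop detection, and post differential
    expression summarisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
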