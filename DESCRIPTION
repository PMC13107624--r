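Package: adatscan
Title: Screening for ADAT2-Dependent Translation from tRNA-Seq, RNA-Seq
    and Ribo-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies genes whose translation depends on ADAT2-mediated
    adenosine-to-inosine (A-to-I) editing at the tRNA wobble position
    (inosine-34). Provides the wobble-pairing model of the eight
    ADAT-substrate anticodon families and their strictly inosine-dependent
    codons, quantification of wobble-position inosine fractions from
    tRNA-seq pileups, codon-usage-bias scoring of coding sequences against
    a proteome background, translation-efficiency (Ribo-seq/RNA-seq)
    concordance filtering, a staged candidate-prioritization funnel, a
    synonymous recoder that removes A-to-I dependence from a coding
    sequence, and a ground-truthed synthetic-data generator that makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
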