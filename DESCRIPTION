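Package: coexdiff
Title: Differential Co-Expression and Differential Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares gene co-expression structure, rather than expression
    level, between two phenotypic conditions. Implements a per-gene
    differential co-expression statistic (DCp) with a permutation null and
    false discovery rate control, link-centric selection of differentially
    co-expressed gene pairs via a limit-fold-change model with sign-reversal
    typing and binomial enrichment (DCe), and a differential regulation
    layer that projects the calls onto a transcription-factor-to-target
    library. Includes the three-comparison study design used in
    pre-/post-treatment case-control studies (individual-effect exclusion
    and key-regulator overlap) and a synthetic-data generator with planted
    correlation shifts and reversals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
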