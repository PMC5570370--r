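Package: stressmir
Title: HSF-1-Regulated miRNA Classification from Factorial Small-RNA-Seq
    Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies microRNAs into heat-shock-dependent and
    heat-shock-independent regulatory classes from small-RNA-seq count data
    collected under a 2x2 knockdown-by-stress design (hsf-1 RNAi crossed
    with heat shock in Caenorhabditis elegans). Provides adapter trimming
    and mismatch-rule read mapping against a mature miRNA reference,
    control-relative fold changes with exact or quasi-likelihood tests and
    Benjamini-Hochberg correction, Venn-style significance partitions and
    regulatory class calls, inverse-correlation integration of predicted
    miRNA targets with mRNA regulation, shared-neighbor network expansion
    with linker detection, hypergeometric over-representation with
    functional-annotation clustering, and a synthetic-data generator with
    planted ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
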