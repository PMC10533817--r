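Package: themis
Title: Multimodal Cell-Free DNA Whole-Methylome Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts four genome-wide feature modalities from fragment-level
    cell-free DNA enzymatic methyl-seq data (methylated fragment ratio, fragment
    size index, size-selected plasma aneuploidy, and fragment 5' end motifs),
    integrates them into an ensemble cancer-detection score (the THEMIS score),
    and classifies the cancer signal origin over tissue-specific open-chromatin
    peak clusters. Ships a fragment-level synthetic cohort simulator so the full
    pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    e1071,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
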