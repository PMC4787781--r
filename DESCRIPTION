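Package: rtsig
Title: Reverse-Transcription Signatures of N1-Methyladenosine in RNA-Seq
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of N1-methyladenosine (m1A) in RNA-Seq alignments via its
    reverse-transcription signature: per-position profiles of coverage, read
    starts, arrest rates and misincorporation patterns; per-adenosine feature
    vectors (arrest rate, mismatch content and composition, context-sensitive
    arrest rate); a random-forest site classifier with stratified
    cross-validation, leave-one-out and leave-feature-out analyses and a kNN
    baseline; sequence-context analyses (ternary mismatch composition,
    hierarchical clustering, a permutation test for +1-base separation,
    Levenshtein mismapping-risk matrices); and a read simulator emulating
    m1A-induced RT arrest, +1-dependent misincorporation, partial occupancy,
    fragmentation and background error, so that the whole pipeline is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    randomForest,
    class,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
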