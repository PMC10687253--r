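Package: gcuaudit
Title: Audit Sequence-Context Bias in Direct RNA m5C Modification Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing per-site 5-methylcytosine (m5C) calls from
    nanopore direct RNA sequencing for sequence-context artifacts. The
    package aggregates per-read modification calls into per-cytosine
    methylated fractions, ranks sites and extracts their sequence-context
    windows, discovers enriched motifs with a ZOOPS
    (zero-or-one-occurrence-per-sequence) EM position-weight-matrix learner
    with mononucleotide-shuffle permutation significance, stratifies
    methylated fractions by the central 3-mer context, and compares GCU
    against non-GCU cytosines (median fold change, two-tailed Welch z test,
    Cohen's d), including paired native versus in-vitro-transcribed (IVT)
    sample comparisons. A seeded synthetic-data generator plants
    context-specific false-call biases and true modification sites over a
    simulated transcriptome so the whole pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Depends: R (>= 4.1)
NeedsCompilation: yes
Config/testthat/edition: 3
RoxygenNote: 7.3.3
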