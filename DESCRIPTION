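Package: rbpscreen
Title: RNA-Binding Protein Candidate Screening and Transcript Stability Analysis
Version: 0.1.0
Authors@R:
    person("Ovarian RBP", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing RNA-binding proteins (RBPs) as candidate
    metastasis suppressors from multiple two-group expression datasets with a
    copy-number deletion filter; for calling an RBP's stabilized target
    transcripts by intersecting RIP-seq binding, steady-state down-regulation,
    and transcription-inhibition destabilization; for estimating transcript
    decay kinetics and half-lives from qPCR and inhibitor time courses; and for
    associating gene and composite-gene expression with immune-marker
    co-expression and survival. A synthetic-data generator with planted ground
    truth stands in for the original sequencing data and drives the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    rtracklayer
Config/testthat/edition: 3
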