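Package: rdrpscreen
Title: Screening Uncharacterized Proteins for RNA Viral RdRp and Endogenous Viral Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to triage "uncharacterized" protein database records into
    RNA-viral RNA-dependent RNA polymerase (RdRp), reverse-transcriptase-like
    (RT) and non-viral classes. Implements a simplified profile hidden Markov
    model (build, Viterbi and forward bit scores), an anchor-driven RdRp/RT
    clade split with paired-profile max-score assignment, a five-channel
    evidence model with a two-of-five classification rule and RT exclusion,
    neighbor-joining placement with patristic-distance OTU assignment and
    support-aware family assignment, endogenous viral element (EVE) signature
    statistics including ORF degradation metrics and a shared-insertion-site
    test, near-miss band selection with term enrichment, and negative-control
    set construction. A synthetic-corpus generator emulates the statistical
    structure of large protein databases so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
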