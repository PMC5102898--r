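Package: fplasmid
Title: Classification of F-Like Conjugative Plasmids from Their Transfer Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to type and classify F-like (IncF/MOB_F12) conjugative
    plasmids from annotated sequence records. Detects MOB_F12 relaxases by
    diagnostic N-terminal motifs plus identity to a reference panel, builds a
    36-gene presence/absence profile of the conjugation (tra) region with
    per-gene conservation and Hamming co-occurrence statistics, infers operon
    architecture from gene order and strand, assigns plasmids to five
    regulatory groups (A-E), and places relaxase domains on a neighbor-joining
    tree with outgroup rooting and monophyly tests. Includes a deterministic
    synthetic-plasmid generator with known ground truth, so the whole pipeline
    can be exercised end to end without database downloads, and a small
    command-line front end for simulate/classify/report runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
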