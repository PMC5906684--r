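Package: znrtools
Title: Comparative Analysis of Zinc-Ribbon and SH3-Fold Beta-Barrel Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for comparative sequence and structure analysis of small
    beta-domains: scanning protein sequences for CPxCG-type zinc-knuckle motifs
    and calling the chelation state (intact, partial or lost) of zinc-ribbon
    derived domains such as the archaeal chromatin proteins Cren7 and Sul7;
    profiling aromatic-cage conservation across chromo-like domain family
    alignments; classifying zinc-ribbon topology types (1A, 1B, 2) from
    C-alpha coordinates; rigid-body superposition with TM-score scoring and a
    deterministic fragment-seeded structural alignment; identity-based
    redundancy clustering; and dual-evidence (E-value and Z-score channel)
    single-linkage consensus trees rendered as Newick. Includes synthetic-data
    generators that emulate each stage's inputs so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    ape,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
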