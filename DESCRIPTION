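Package: clcimpact
Title: Structural and Cohort Analysis of Missense Mutations in Dimeric
    Chloride Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for in-silico analysis of missense mutations on dimeric
    chloride-channel structures in the ClC family. Computes solvent-accessible
    surface area (Shrake-Rupley) and relative accessibility with a buriedness
    rule, maps dimer-interface residues by buried surface area or cross-chain
    distance, detects the ion-conduction pathway through a subunit on a
    clearance-weighted grid, identifies side-chain hydrogen bonds and aromatic
    interactions, and classifies mutation impact by side-chain volume, charge
    and polarity change. Includes cohort-level utilities that parse HGVS-style
    variant tables, count disease alleles with cis-phase awareness, and
    summarise mutation frequencies and novelty, together with deterministic
    generators for synthetic benchmark structures and cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
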