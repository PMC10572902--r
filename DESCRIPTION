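Package: pbflex
Title: Protein Block Analysis of Nanobody Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Structural-alphabet post-processing of conformational ensembles of
    single-domain antibodies (VHH / nanobodies). Encodes backbone conformations
    into the 16-letter Protein Blocks alphabet, computes per-position flexibility
    statistics (Neq, RMSF) and between-system comparison statistics (delta-Neq,
    delta-PB, PB sequence logos), annotates framework and CDR regions, audits
    humanization point mutations against hotspot and camelid-hallmark tables,
    and generates synthetic conformational ensembles with prescribed per-position
    Protein Block statistics so the full pipeline runs without molecular-dynamics
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
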