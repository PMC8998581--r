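Package: leaprofiler
Title: Sequence-Based Characterisation of Late Embryogenesis Abundant Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein sequences into late embryogenesis abundant
    (LEA) families and motif-defined subgroups, computes per-protein
    physicochemical profiles (GRAVY, isoelectric point, molecular weight,
    residue-category composition, hydrophilin status), scans for family
    consensus motifs and dehydrin K/Y/S segments, performs HeliQuest-style
    helical-wheel amphipathicity analysis, scores hydroxyl-radical
    scavenging ability, and summarises desiccation-responsive differential
    expression. Ships a seeded synthetic proteome and DEG generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
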