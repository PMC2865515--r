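Package: protomerscan
Title: Protomer Enumeration and Zwitterion Stability Analysis for Gas-Phase Peptide Ions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide the zwitterionic character of gas-phase peptide
    ions. Enumerates every protonation microstate (protomer) compatible with a
    net charge, scores charge separation with an additive intrinsic
    gas-phase-basicity model, runs a hierarchical conformer-selection and
    energy-ranking protocol over externally supplied energy lists, and
    classifies the stabilizing interactions (salt bridges and three classes of
    hydrogen bonds) in 3-D conformers read from PDB files. Ships definitions
    of bradykinin, angiotensin II and Trp-cage together with intrinsic
    gas-phase basicity, proton affinity and protonation-energy tables, and a
    synthetic-fixture generator for conformers and mock energy landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
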