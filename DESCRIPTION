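Package: ddhelix
Title: Modelling Death-Domain Helical Oligomer Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for template-guided modelling of death-domain (DD)
    helical oligomers such as the myddosome. Provides rigid-body (Kabsch)
    superposition with sequence-guided residue correspondence, screw-axis
    decomposition of the helical lattice, template-threading of a query DD
    sequence, construction of extended layered assemblies (including the
    two-stage octamer extension under a MyD88/IRAK-4 scaffold), steric
    clash detection and side-chain relief, inter-subunit contact and
    interface-offset analysis for the three canonical DD interaction
    faces, a simplified per-residue interface-energy decomposition with
    lowest-four averaging across subunit copies, and an in-silico
    point-mutation scan. A synthetic generator of layered DD helices with
    known ground truth supports fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
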