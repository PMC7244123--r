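Package: pocketevo
Title: Evolutionary Scenarios for Receptor Binding Pockets That Predate Their Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct how the ligand-binding pocket of a membrane
    receptor evolved when the receptor predates its endogenous ligand. From a
    receptor-ligand 3D complex, an in-frame codon alignment of receptor
    orthologs and a phylogeny partitioned into ordered taxonomic groups, the
    package extracts the binding interface, maps it into alignment columns,
    and computes per-branch conservation and selection indexes: percent
    identity of the pocket and of the whole sequence to the mammalian
    reference, within-branch non-synonymous substitution counts, pocket
    restricted dN/dS (omega) from counting-based estimators built on Fitch
    parsimony ancestral reconstruction, and a per-site selection scan. A
    rule-based classifier assigns each receptor to one of three evolutionary
    scenarios (pre-existing conserved pocket, progressive pocket acquisition,
    pocket reshuffling at ligand appearance). A branch- and site-class aware
    codon evolution simulator generates synthetic receptor families under each
    scenario for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
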