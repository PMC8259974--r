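Package: unirenum
Title: Renumber Macromolecular Structure Files to UniProt Numbering
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Replaces author residue numbering in mmCIF and legacy PDB
    structure files (asymmetric units and biological assemblies) with
    numbering derived from the corresponding UniProt sequences, using
    residue-level mappings from the SIFTS resource. Residues and ligands
    without a UniProt number receive collision-free offset numbers, every
    residue-numbered annotation table is updated consistently, the
    sequence-scheme tables are rewritten to preserve the original
    numbering, and a per-chain report summarises what was renumbered.
    Includes a synthetic fixture generator covering pathological
    numbering (signal-peptide offsets, negative or unobserved expression
    tags, insertion codes, chimeric chains, non-polymer ligands) so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
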