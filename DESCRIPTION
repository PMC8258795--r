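Package: plifscreen
Title: Protein-Ligand Interaction Fingerprint Screening for Structure-Based Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects non-covalent protein-ligand interactions (hydrogen bonds,
    hydrophobic contacts, halogen bonds) from PDB-format complexes by geometric
    rules, encodes them as pairwise-feature binary interaction fingerprints,
    ranks a complex library by Tanimoto similarity to a query complex with
    empirical p-values, and filters hits to approved-drug ligands. Candidate
    compounds are characterised by extended-connectivity (Morgan) fingerprint
    similarity and BOILED-Egg blood-brain-barrier classification; homolog
    templates are assessed by global sequence alignment, iterative Kabsch
    superposition, and binding-site residue correspondence. A synthetic-data
    generator plants interaction geometries and fingerprint libraries with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
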