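Package: kinconf
Title: Kinase Conformation Gauging and Interaction Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies protein-kinase structures by the conformational state
    of their major structural motifs (DFG-loop in/out/out-up, alphaC-helix
    in/out, glycine-rich loop extended/folded) using centre-of-mass distance
    and angle descriptors over key Aurora-kinase motif residues, detects the
    major classes of non-covalent protein-ligand interactions (strong and weak
    hydrogen bonds, salt bridges, cation-pi, pi-pi, CH-pi, van der Waals
    contacts), encodes them into a 14-bit structure interaction fingerprint,
    and maps set bits onto binding-site sub-pockets and specificity hot-spots
    to rank compatible inhibitor classes. Includes a PDB reader/writer with
    modified-residue normalization, canonical Aurora-A residue numbering via
    pairwise sequence alignment, a deterministic synthetic toy-kinase
    generator used for closed-loop testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
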