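#!/usr/bin/env Rscript

# Fetches the NETWORK-REQUIRING reproduction inputs used by acceptance
# criteria 5-7 in tests/testthat/test-acceptance.R:
#   * the four representative Aurora-A crystal structures
#     (2W1C, 3E5A, 3UNZ, 2J4Z) from the RCSB PDB,
#   * UniProt sequences O14965 (AURKA_HUMAN), P24941 (CDK2_HUMAN),
#     Q96GD4 (AURKB_HUMAN).
# Files land in inst/extdata/reproduction/; reinstall the package afterwards.
# The 56-entry whole-set reproduction additionally needs a table_s1.tsv
# (columns: pdb_id, dfg, alpha_c, g_loop) and the matching PDB files under
# inst/extdata/reproduction/pdb/ -- assemble those from the published
# supporting information of the original survey; this script cannot
# download them.

dest <- file.path("inst", "extdata", "reproduction")
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

pdb_ids <- c("2W1C", "3E5A", "3UNZ", "2J4Z")
for (id in pdb_ids) {
  f <- file.path(dest, paste0(id, ".pdb"))
  if (!file.exists(f)) {
    utils::download.file(
      sprintf("https://files.rcsb.org/download/%s.pdb", id), f,
      quiet = TRUE
    )
    message("fetched ", f)
  }
}

uniprot <- c("O14965", "P24941", "Q96GD4")
for (acc in uniprot) {
  f <- file.path(dest, paste0(acc, ".fasta"))
  if (!file.exists(f)) {
    utils::download.file(
      sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", acc), f,
      quiet = TRUE
    )
    message("fetched ", f)
  }
}

message("done; reinstall the package so system.file() can see the files")
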