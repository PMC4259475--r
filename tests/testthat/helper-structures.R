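# Small in-code structure builders shared across test files.

# one PDB ATOM/HETATM line with standard column layout
pdb_line <- function(record, serial, name, resname, chain, resnum, x, y, z,
                     occ = 1.00, element = substr(name, 1, 1), altloc = " ") {
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, name, altloc, resname, chain, resnum, x, y, z, occ, 0, element
  )
}

glycine_pdb_text <- function() {
  c(
    pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 1.46, 0, 0, element = "C"),
    pdb_line("ATOM", 3, "C", "GLY", "A", 1, 2.0, 1.4, 0, element = "C"),
    "END"
  )
}

# an atom-tibble row set for a single residue given named coordinates
res_tbl <- function(resname, resnum, coords, chain = "A", hetero = FALSE) {
  nm <- names(coords)
  el <- vapply(nm, function(n) {
    g <- sub("^[0-9]*", "", n)
    if (substr(g, 1, 2) %in% c("SE", "CL", "BR")) substr(g, 1, 2) else substr(g, 1, 1)
  }, character(1))
  xyz <- do.call(rbind, coords)
  tibble::tibble(
    record = if (hetero) "HETATM" else "ATOM",
    serial = seq_along(nm), name = nm, resname = resname, chain = chain,
    resnum = as.integer(resnum), inscode = "",
    x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3]),
    occupancy = 1, element = unname(el), model = 1L,
    modified_from = NA_character_, is_hetero = hetero
  )
}

# benzene HET group centred at `centre` with normal `normal`
benzene_tbl <- function(centre = c(0, 0, 0), normal = c(0, 0, 1),
                        resnum = 901, chain = "L", resname = "BNZ") {
  rc <- kinconf:::.ring_coords(centre, normal, 6, 1.39)
  coords <- lapply(seq_len(6), function(i) rc[i, ])
  names(coords) <- paste0("C", 1:6)
  res_tbl(resname, resnum, coords, chain = chain, hetero = TRUE)
}

# acetate-like carboxylate HET group: CH3-COO(-)
carboxylate_tbl <- function(origin = c(0, 0, 0), resnum = 902, chain = "L") {
  res_tbl("ACY2", resnum, list(
    C1 = origin, # methyl C
    C2 = origin + c(1.5, 0, 0), # carboxyl C
    O1 = origin + c(2.2, 1.05, 0),
    O2 = origin + c(2.2, -1.05, 0)
  ), chain = chain, hetero = TRUE)
}

# pose row (as extract_ligands returns) from a hetero atom tibble
pose_of <- function(lig_tbl) {
  extract_ligands(lig_tbl)[1, ]
}

all_labels <- expand.grid(
  dfg = c("in", "out", "out_up"),
  alpha_c = c("in", "out"),
  g_loop = c("extended", "folded"),
  stringsAsFactors = FALSE
)

# residue maps are expensive (pairwise alignment); cache one per conformation
toy_map_cache <- new.env(parent = emptyenv())
toy_map <- function(dfg = "in", alpha_c = NULL, g_loop = "extended") {
  key <- paste(dfg, alpha_c %||% "def", g_loop)
  if (is.null(toy_map_cache[[key]])) {
    a <- make_toy_kinase(dfg, alpha_c, g_loop)
    toy_map_cache[[key]] <- align_to_reference(chain_sequence(a, "A"))
  }
  toy_map_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
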