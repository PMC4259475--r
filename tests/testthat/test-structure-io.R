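# PDB parsing, writing, modified-residue normalization, ligand extraction.

test_that("minimal glycine PDB parses to one chain, one residue, three atoms", {
  a <- read_pdb(text = glycine_pdb_text())
  expect_equal(nrow(a), 3)
  expect_equal(unique(a$chain), "A")
  expect_equal(unique(a$resnum), 1L)
  expect_equal(a$name, c("N", "CA", "C"))
  expect_equal(a$x, c(0, 1.46, 2.0), tolerance = 1e-9)
  expect_false(any(a$is_hetero))
})

test_that("write + parse round-trips coordinates and residue identity", {
  atoms <- make_toy_kinase("out_up", g_loop = "folded")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(atoms, tf)
  back <- read_pdb(tf)
  expect_equal(nrow(back), nrow(atoms))
  expect_equal(back$resnum, atoms$resnum)
  expect_equal(back$resname, atoms$resname)
  expect_equal(back$name, atoms$name)
  # PDB format carries 0.001 A precision
  expect_equal(back$x, atoms$x, tolerance = 5e-4)
  expect_equal(back$y, atoms$y, tolerance = 5e-4)
  expect_equal(back$z, atoms$z, tolerance = 5e-4)
})

test_that("parser reports malformed records and absent models by name", {
  expect_error(read_pdb(text = "HEADER only"), "no ATOM/HETATM")
  bad <- c(pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0), "ATOM      2  CA")
  expect_error(read_pdb(text = bad), "line 2")
  expect_error(read_pdb(text = glycine_pdb_text(), model = 3), "model 3")
})

test_that("alternate locations keep the highest occupancy, ties prefer A", {
  txt <- c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 5, 0, 0, 0, occ = 0.4, altloc = "A", element = "C"),
    pdb_line("ATOM", 2, "CA", "SER", "A", 5, 9, 9, 9, occ = 0.6, altloc = "B", element = "C"),
    pdb_line("ATOM", 3, "OG", "SER", "A", 5, 1, 0, 0, occ = 0.5, altloc = "A", element = "O"),
    pdb_line("ATOM", 4, "OG", "SER", "A", 5, 8, 8, 8, occ = 0.5, altloc = "B", element = "O")
  )
  a <- read_pdb(text = txt)
  expect_equal(nrow(a), 2)
  expect_equal(a$x[a$name == "CA"], 9) # higher occupancy wins
  expect_equal(a$x[a$name == "OG"], 1) # tie goes to altloc A
})

test_that("phosphothreonine is standardized to THR without phosphate atoms", {
  tpo <- res_tbl("TPO", 288, list(
    N = c(0, 0, 0), CA = c(1.5, 0, 0), C = c(2.2, 1.3, 0), O = c(3.4, 1.4, 0),
    CB = c(1.9, -1.2, 0.8), OG1 = c(1.5, -2.4, 0.2), CG2 = c(3.0, -1.4, 1.4),
    P = c(1.1, -3.8, 0.5), O1P = c(0, -4.3, -0.4), O2P = c(2.4, -4.6, 0.3),
    O3P = c(0.7, -3.9, 1.9)
  ))
  tpo$record <- "HETATM"
  out <- standardize_modified_residues(tpo)
  expect_equal(unique(out$resname), "THR")
  expect_false(any(grepl("P", out$name) & out$element == "P"))
  expect_setequal(out$name, c("N", "CA", "C", "O", "CB", "OG1", "CG2"))
  expect_equal(unique(out$modified_from), "TPO")
  expect_false(any(out$is_hetero))
})

test_that("selenomethionine becomes MET with SE relabelled to SD", {
  mse <- res_tbl("MSE", 10, list(
    N = c(0, 0, 0), CA = c(1.5, 0, 0), C = c(2.2, 1.3, 0), O = c(3.4, 1.4, 0),
    CB = c(1.9, -1.2, 0.8), CG = c(1.6, -2.5, 0.1), SE = c(2.3, -3.9, 0.9),
    CE = c(1.5, -5.3, 0.2)
  ))
  out <- standardize_modified_residues(mse)
  # hand-written expected record
  expected_names <- c("N", "CA", "C", "O", "CB", "CG", "SD", "CE")
  expect_equal(unique(out$resname), "MET")
  expect_setequal(out$name, expected_names)
  expect_equal(out$element[out$name == "SD"], "S")
  expect_equal(out$x[out$name == "SD"], 2.3) # coordinates untouched
})

test_that("standardization is a no-op without modified residues and idempotent", {
  atoms <- make_toy_kinase("in")
  expect_identical(standardize_modified_residues(atoms), atoms)
  tpo <- res_tbl("TPO", 288, list(
    N = c(0, 0, 0), CA = c(1.5, 0, 0), C = c(2.2, 1.3, 0), O = c(3.4, 1.4, 0),
    CB = c(1.9, -1.2, 0.8), OG1 = c(1.5, -2.4, 0.2), CG2 = c(3.0, -1.4, 1.4),
    P = c(1.1, -3.8, 0.5)
  ))
  once <- standardize_modified_residues(tpo)
  expect_identical(standardize_modified_residues(once), once)
})

test_that("ligand extraction types features and conserves atom counts", {
  prot <- make_toy_kinase("in")
  expect_equal(nrow(extract_ligands(prot)), 0) # apo

  benz <- benzene_tbl(centre = c(30, 30, 30))
  poses <- extract_ligands(dplyr::bind_rows(prot, benz))
  expect_equal(nrow(poses), 1)
  expect_equal(poses$n_atoms, 6)
  ar <- poses$features[[1]][poses$features[[1]]$feature == "Ar", ]
  expect_equal(nrow(ar), 1)
  expect_length(ar$atoms[[1]], 6)

  carb <- carboxylate_tbl(origin = c(40, 40, 40))
  poses2 <- extract_ligands(dplyr::bind_rows(prot, benz, carb))
  expect_equal(nrow(poses2), 2)
  expect_equal(sum(poses2$n_atoms), 10) # atom count conserved
  feats <- poses2$features[[which(poses2$resname == "ACY2")]]
  an <- feats[feats$feature == "Anion", ]
  expect_equal(sort(an$atoms[[1]]), c(3L, 4L)) # the two carboxylate oxygens

  # waters and common additives are excluded by default
  wat <- res_tbl("HOH", 999, list(O = c(50, 50, 50)), chain = "W", hetero = TRUE)
  expect_equal(nrow(extract_ligands(dplyr::bind_rows(prot, wat))), 0)
})
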