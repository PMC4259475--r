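# Geometric primitives against brute-force oracles.

test_that("distance and angle match hand values and the oracle battery", {
  expect_equal(pt_distance(c(0, 0, 0), c(3, 0, 0)), 3.0)
  expect_equal(pt_distance(c(1, 2, 3), c(1, 2, 3)), 0.0)
  expect_equal(pt_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(pt_angle(c(-1, 0, 0), c(0, 0, 0), c(5, 0, 0)), 180)
  set.seed(1)
  for (k in 1:100) {
    p <- matrix(stats::rnorm(9, sd = 5), 3)
    expect_equal(pt_distance(p[1, ], p[2, ]), oracle_dist(p[1, ], p[2, ]), tolerance = 1e-9)
    expect_equal(pt_angle(p[1, ], p[2, ], p[3, ]),
      oracle_angle(p[1, ], p[2, ], p[3, ]),
      tolerance = 1e-9
    )
  }
  expect_error(pt_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")
})

test_that("dihedrals match an independent two-normal formulation", {
  set.seed(2)
  for (k in 1:100) {
    p <- matrix(stats::rnorm(12, sd = 4), 4)
    expect_equal(
      pt_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
      oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
      tolerance = 1e-8
    )
  }
})

test_that("residue COM matches the brute-force mass-weighted sum", {
  one <- res_tbl("ALA", 1, list(CB = c(1, 2, 3)))
  expect_equal(residue_com(one), c(1, 2, 3))

  two <- res_tbl("GLY", 2, list(CA = c(0, 0, 0)))
  two2 <- dplyr::bind_rows(two, res_tbl("GLY", 2, list(CA = c(2, 0, 0))))
  expect_equal(residue_com(two2, com_spec("ca", "unit")), c(1, 0, 0))

  arg <- res_tbl("ARG", 3, list(
    N = c(0, 0, 0), CA = c(1.4, 0.2, 0), C = c(2.4, 1.1, 0.4), O = c(3.5, 0.9, 0.1),
    CB = c(1.8, -1.3, 0.6), CG = c(1.5, -2.6, -0.1), CD = c(2.2, -3.8, 0.6),
    NE = c(1.9, -5.1, 0.1), CZ = c(2.5, -6.2, 0.6),
    NH1 = c(3.4, -6.2, 1.6), NH2 = c(2.1, -7.4, 0.2)
  ))
  for (sel in c("sidechain", "heavy", "ca")) {
    for (wt in c("mass", "unit")) {
      expect_equal(
        residue_com(arg, com_spec(sel, wt)),
        oracle_com(arg, sel, wt),
        tolerance = 1e-12
      )
    }
  }
})

test_that("glycine side-chain COM falls back to the alpha carbon", {
  gly <- res_tbl("GLY", 7, list(
    N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.2, 1.3, 0), O = c(3.4, 1.4, 0)
  ))
  expect_equal(residue_com(gly, com_spec("sidechain")), c(1.46, 0, 0))
})

test_that("COM lies in the convex hull of the selected atoms", {
  set.seed(3)
  for (k in 1:25) {
    n <- sample(3:8, 1)
    coords <- lapply(seq_len(n), function(i) stats::rnorm(3, sd = 3))
    names(coords) <- c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")[1:n]
    res <- res_tbl("TYR", 1, coords)
    com <- residue_com(res, com_spec("sidechain", "mass"))
    # inside the bounding box (necessary condition of the hull)
    expect_true(all(com >= apply(do.call(rbind, coords), 2, min) - 1e-9))
    expect_true(all(com <= apply(do.call(rbind, coords), 2, max) + 1e-9))
  }
})

test_that("an ideal beta strand recovers its generating phi/psi within 1 degree", {
  bb <- kinconf:::.build_gloop_backbone(rep(-140, 6), rep(135, 6))
  rows <- lapply(1:6, function(i) {
    res_tbl("ALA", i, list(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ], O = bb$O[i, ]))
  })
  atoms <- dplyr::bind_rows(rows)
  for (i in 2:5) {
    pp <- backbone_dihedrals(atoms, "A", i)
    expect_equal(unname(pp["phi"]), -140, tolerance = 1)
    expect_equal(unname(pp["psi"]), 135, tolerance = 1)
  }
  expect_error(backbone_dihedrals(atoms, "A", 1), "absent")
  noc <- atoms[!(atoms$resnum == 3 & atoms$name == "C"), ]
  expect_error(backbone_dihedrals(noc, "A", 3), "C")
})

test_that("all geometric outputs are rigid-motion invariant", {
  atoms <- make_toy_kinase("out_up")
  res <- atoms[atoms$resnum == 275, ]
  set.seed(4)
  for (k in 1:20) {
    R <- random_rotation()
    tr <- stats::rnorm(3, sd = 20)
    res2 <- transform_atoms(res, R, tr)
    com1 <- residue_com(res)
    com2 <- residue_com(res2)
    expect_equal(com2, c(R %*% com1) + tr, tolerance = 1e-6)
    a2 <- transform_atoms(atoms, R, tr)
    pp1 <- backbone_dihedrals(atoms, "A", 142)
    pp2 <- backbone_dihedrals(a2, "A", 142)
    expect_equal(pp1, pp2, tolerance = 1e-6)
  }
})
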