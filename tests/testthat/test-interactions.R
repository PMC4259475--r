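# Non-covalent interaction detectors.

test_that("a short linear N...O pair is one strong H-bond; 5 A is none", {
  prot <- interaction_protein()
  o <- prot[prot$resnum == 1 & prot$name == "O", ]
  o_xyz <- c(o$x, o$y, o$z)
  dirv <- c(0.2, 0.4, 0.89)
  dirv <- dirv / sqrt(sum(dirv^2))
  near <- res_tbl("LIG", 900, list(
    N1 = o_xyz + 2.5 * dirv, C2 = o_xyz + 3.95 * dirv
  ), chain = "L", hetero = TRUE)
  hb <- detect_hbonds(prot, pose_of(near))
  hb <- hb[hb$kind == "HBOND_STRONG" & hb$resnum == 1 & hb$partner == "N1", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$subtype, "N-H...O")
  expect_equal(hb$distance, 2.5, tolerance = 1e-9)
  expect_gte(hb$angle, 120)

  far <- res_tbl("LIG", 900, list(
    N1 = o_xyz + 5.0 * dirv, C2 = o_xyz + 6.45 * dirv
  ), chain = "L", hetero = TRUE)
  hb2 <- detect_hbonds(prot, pose_of(far))
  expect_equal(nrow(hb2[hb2$resnum == 1 & hb2$partner == "N1", ]), 0)
})

test_that("salt bridges toggle with the alphaC state in the toy kinase", {
  crit <- interaction_criteria()
  a_in <- make_toy_kinase("in", "in")
  sb_in <- detect_salt_bridges(a_in, NULL, crit, map = toy_map("in", "in"))
  expect_true(any(sb_in$resnum == 162 & sb_in$partner == "GLU181"))
  expect_false(any(sb_in$partner == "ARG255"))

  a_out <- make_toy_kinase("in", "out")
  sb_out <- detect_salt_bridges(a_out, NULL, crit, map = toy_map("in", "out"))
  expect_false(any(sb_out$resnum == 162 & sb_out$partner == "GLU181"))
  expect_true(any(sb_out$resnum == 181 & sb_out$partner == "ARG255"))
})

test_that("the K162-F275 protein cation-pi appears in the out-up conformation", {
  cp <- detect_cation_pi(make_toy_kinase("out_up"), NULL,
    map = toy_map("out_up")
  )
  expect_true(any(cp$subtype == "protein-protein" & cp$partner == "PHE275"))
  cp_in <- detect_cation_pi(make_toy_kinase("in"), NULL, map = toy_map("in"))
  expect_false(any(cp_in$subtype == "protein-protein"))
})

test_that("cation-pi needs the cation near the ring axis", {
  prot <- interaction_protein()
  ring_ctr <- c(51.5, -3, 0.5) # PHE ring centre, normal +z
  above <- res_tbl("LIG", 900, list(
    N1 = ring_ctr + c(0, 0, 4.0), C2 = ring_ctr + c(0, 0, 5.45)
  ), chain = "L", hetero = TRUE)
  cp <- detect_cation_pi(prot, pose_of(above))
  expect_true(any(cp$subtype == "ligand-cation" & cp$resnum == 3))

  inplane <- res_tbl("LIG", 900, list(
    N1 = ring_ctr + c(4.0, 0, 0), C2 = ring_ctr + c(5.45, 0, 0)
  ), chain = "L", hetero = TRUE)
  cp2 <- detect_cation_pi(prot, pose_of(inplane))
  expect_false(any(cp2$subtype == "ligand-cation"))
})

test_that("pi stacking distinguishes face and edge arrangements", {
  prot <- interaction_protein()
  ring_ctr <- c(51.5, -3, 0.5)
  face <- benzene_tbl(ring_ctr + c(0, 0, 3.8), c(0, 0, 1), resname = "LIG", resnum = 900)
  pp <- detect_pi_stacking(prot, pose_of(face))
  expect_equal(pp$subtype, "face")

  edge <- benzene_tbl(ring_ctr + c(0, 0, 5.0), c(1, 0, 0), resname = "LIG", resnum = 900)
  pp2 <- detect_pi_stacking(prot, pose_of(edge))
  expect_equal(pp2$subtype, "edge")

  none <- benzene_tbl(ring_ctr + c(0, 0, 8), c(0, 0, 1), resname = "LIG", resnum = 900)
  expect_equal(nrow(detect_pi_stacking(prot, pose_of(none))), 0)
})

test_that("every detector matches the literal brute-force oracle on random fixtures", {
  prot <- interaction_protein()
  for (s in 1:30) {
    lig <- random_interaction_ligand(prot, seed = s)
    got <- detector_interaction_sets(prot, lig)
    want <- oracle_interaction_sets(prot, lig)
    expect_identical(got$strong, want$strong, label = paste("strong seed", s))
    expect_identical(got$weak, want$weak, label = paste("weak seed", s))
    expect_identical(got$salt, want$salt, label = paste("salt seed", s))
    expect_identical(got$catpi, want$catpi, label = paste("catpi seed", s))
    expect_identical(got$pipi, want$pipi, label = paste("pipi seed", s))
    expect_identical(got$chpi_n, want$chpi_n, label = paste("chpi seed", s))
  }
})

test_that("loosening any cutoff never removes a record (monotonicity)", {
  prot <- interaction_protein()
  base <- interaction_criteria()
  loose <- interaction_criteria(
    hbond_strong_dist = 4.2, hbond_weak_dist = 4.5, hbond_angle = 100,
    salt_bridge_dist = 5.5, cation_pi_dist = 7.5, cation_pi_angle = 45,
    pipi_face_dist = 6.5, pipi_face_angle = 45, chpi_dist = 5.5, chpi_elev = 20
  )
  key <- function(tab) paste(tab$kind, tab$resnum, tab$partner, tab$ligand_role)
  for (s in 1:10) {
    lig <- random_interaction_ligand(prot, seed = 100 + s)
    pose <- pose_of(lig)
    for (f in list(detect_hbonds, detect_salt_bridges, detect_cation_pi, detect_ch_pi)) {
      expect_true(
        all(key(f(prot, pose, base)) %in% key(f(prot, pose, loose))),
        label = paste("monotone seed", s)
      )
    }
  }
})

test_that("record geometry values are rigid-motion invariant", {
  prot <- interaction_protein()
  lig <- random_interaction_ligand(prot, seed = 7)
  tab1 <- interaction_table(dplyr::bind_rows(prot, lig),
    pose_of(lig),
    map = tibble::tibble(
      author_number = 1:4, author_aa = c("S", "K", "F", "D"),
      canonical_position = 1:4, anchor = "", motif = ""
    )
  )
  set.seed(8)
  R <- random_rotation()
  tr <- stats::rnorm(3, sd = 15)
  prot2 <- transform_atoms(prot, R, tr)
  lig2 <- transform_atoms(lig, R, tr)
  tab2 <- interaction_table(dplyr::bind_rows(prot2, lig2),
    pose_of(lig2),
    map = tibble::tibble(
      author_number = 1:4, author_aa = c("S", "K", "F", "D"),
      canonical_position = 1:4, anchor = "", motif = ""
    )
  )
  ord <- function(t) t[order(t$kind, t$resnum, t$partner, t$ligand_role), ]
  t1 <- ord(tab1)
  t2 <- ord(tab2)
  expect_equal(t1$kind, t2$kind)
  expect_equal(t1$distance, t2$distance, tolerance = 1e-6)
  expect_equal(t1$angle, t2$angle, tolerance = 1e-6)
})

test_that("the interaction table is the union of the individual detectors", {
  cx <- make_toy_complex(c(4L, 10L, 12L))
  tab <- interaction_table(cx$atoms, cx$pose, cx$map)
  crit <- interaction_criteria()
  parts <- dplyr::bind_rows(
    detect_salt_bridges(cx$atoms, cx$pose, crit, cx$map),
    detect_cation_pi(cx$atoms, cx$pose, crit, cx$map),
    detect_hbonds(cx$atoms, cx$pose, crit),
    detect_pi_stacking(cx$atoms, cx$pose, crit),
    detect_ch_pi(cx$atoms, cx$pose, crit)
  )
  key <- function(t) sort(paste(t$kind, t$resnum, t$partner, t$ligand_role))
  expect_identical(key(tab), key(parts))
  expect_true(all(!is.na(tab$canonical)))
})

test_that("apo structures yield protein-protein records only", {
  a <- make_toy_kinase("out_up")
  tab <- interaction_table(a, NULL, toy_map("out_up"))
  expect_gt(nrow(tab), 0)
  expect_true(all(tab$partner_type == "protein"))
})
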