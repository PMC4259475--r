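# Inter- and intra-motif metric vectors.

test_that("inter-motif metric equals brute-force recomputation from raw coordinates", {
  a <- make_toy_kinase("out_up")
  m <- toy_map("out_up")
  inter <- inter_motif_metric(a, m)

  com_of <- function(canonical) {
    author <- m$author_number[match(canonical, m$canonical_position)]
    oracle_com(a[a$resnum == author & !a$is_hetero, ])
  }
  K <- com_of(162)
  E <- com_of(181)
  GK <- com_of(210)
  GK2 <- com_of(212)
  F275 <- com_of(275)
  expect_equal(inter$inter_r2_gk_e181, oracle_dist(GK, E), tolerance = 1e-9)
  expect_equal(inter$inter_r3_gk_f275, oracle_dist(GK, F275), tolerance = 1e-9)
  expect_equal(inter$inter_r4_k162_f275, oracle_dist(K, F275), tolerance = 1e-9)
  expect_equal(inter$inter_r5_e181_f275, oracle_dist(E, F275), tolerance = 1e-9)
  expect_equal(inter$inter_r6_k162_e181, oracle_dist(K, E), tolerance = 1e-9)
  expect_equal(inter$inter_ang_k_gk2_e, oracle_angle(K, GK2, E), tolerance = 1e-9)
  expect_equal(inter$inter_ang_k_gk2_f, oracle_angle(K, GK2, F275), tolerance = 1e-9)
  expect_equal(inter$inter_ang_e_gk_f, oracle_angle(E, GK, F275), tolerance = 1e-9)
})

test_that("intra-motif metric equals brute-force recomputation", {
  a <- make_toy_kinase("out")
  m <- toy_map("out")
  intra <- intra_motif_metric(a, m)
  com_of <- function(canonical) {
    author <- m$author_number[match(canonical, m$canonical_position)]
    oracle_com(a[a$resnum == author & !a$is_hetero, ])
  }
  D <- com_of(274)
  F275 <- com_of(275)
  G <- com_of(276)
  W <- com_of(277)
  expect_equal(intra$intra_r1_a273_d274, oracle_dist(com_of(273), D), tolerance = 1e-9)
  expect_equal(intra$intra_r2_d274_f275, oracle_dist(D, F275), tolerance = 1e-9)
  expect_equal(intra$intra_r3_f275_g276, oracle_dist(F275, G), tolerance = 1e-9)
  expect_equal(intra$intra_r4_d274_g276, oracle_dist(D, G), tolerance = 1e-9)
  expect_equal(intra$intra_r5_f275_w277, oracle_dist(F275, W), tolerance = 1e-9)
  expect_equal(intra$intra_r6_f275_t288, oracle_dist(F275, com_of(288)), tolerance = 1e-9)
  expect_equal(intra$intra_ang_dfg, oracle_angle(D, F275, G), tolerance = 1e-9)
  expect_equal(intra$intra_ang_fwh, oracle_angle(F275, W, com_of(280)), tolerance = 1e-9)
  expect_equal(intra$intra_ang_fwt, oracle_angle(F275, W, com_of(288)), tolerance = 1e-9)
})

test_that("metric vectors are rigid-motion invariant", {
  a <- make_toy_kinase("in")
  m <- toy_map("in")
  base <- dplyr::bind_cols(inter_motif_metric(a, m), intra_motif_metric(a, m))
  set.seed(5)
  for (k in 1:10) {
    a2 <- transform_atoms(a, random_rotation(), stats::rnorm(3, sd = 30))
    moved <- dplyr::bind_cols(inter_motif_metric(a2, m), intra_motif_metric(a2, m))
    expect_equal(as.numeric(moved), as.numeric(base), tolerance = 1e-6)
  }
})

test_that("the DFG-in archetype keeps a salt-bridge-compatible K162-E181 distance", {
  inter <- inter_motif_metric(make_toy_kinase("in", "in"), toy_map("in", "in"))
  expect_lt(inter$inter_r6_k162_e181, 4.5)
})

test_that("GK-F275 and K162-F275 are larger in non-DFG-in conformations", {
  r_in <- inter_motif_metric(make_toy_kinase("in"), toy_map("in"))
  for (d in c("out", "out_up")) {
    r <- inter_motif_metric(make_toy_kinase(d), toy_map(d))
    expect_gt(r$inter_r3_gk_f275, r_in$inter_r3_gk_f275)
    expect_gt(r$inter_r4_k162_f275, r_in$inter_r4_k162_f275)
  }
})

test_that("missing anchors are reported by name", {
  a <- make_toy_kinase("in")
  m <- toy_map("in")
  noK <- a[a$resnum != 162, ]
  expect_error(inter_motif_metric(noK, m), "K162")
})
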