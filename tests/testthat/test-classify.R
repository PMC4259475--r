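# Conformation classification and calibration.

test_that("classifying a calibration reference recovers its own label", {
  cal <- default_calibration()
  for (d in c("in", "out", "out_up")) {
    a <- make_toy_kinase(d)
    r <- classify_structure(a, map = toy_map(d), cal = cal)
    expect_equal(r$dfg, d)
    expect_gt(r$dfg_margin, 0)
  }
})

test_that("calibration requires one reference per class", {
  a <- make_toy_kinase("in")
  refs <- tibble::tibble(
    atoms = list(a), map = list(toy_map("in")), dfg = "in"
  )
  expect_error(calibrate_conformations(refs), "out")
})

test_that("noisy archetype clouds are recovered at >= 95%", {
  # three clusters of noisy fixtures (sigma = 0.3 A) against the noise-free
  # calibration; seeded simulation oracle
  cal <- default_calibration()
  n <- 30
  hits <- 0
  for (d in c("in", "out", "out_up")) {
    m <- toy_map(d)
    for (s in seq_len(n)) {
      a <- make_toy_kinase(d, noise_sigma = 0.3, seed = 1000 + s)
      r <- classify_dfg(
        inter_motif_metric(a, m), intra_motif_metric(a, m), cal
      )
      hits <- hits + (r$dfg == d)
    }
  }
  expect_gte(hits / (3 * n), 0.95)
})

test_that("alphaC call follows the Lys162-Glu181 salt bridge", {
  cal <- default_calibration()
  a_in <- make_toy_kinase("in", "in")
  m <- toy_map("in", "in")
  inter <- inter_motif_metric(a_in, m)
  expect_equal(classify_alpha_c(a_in, m, inter, cal)$alpha_c, "in")
  # E181 rotated away from K162
  a_out <- make_toy_kinase("in", "out")
  m2 <- toy_map("in", "out")
  inter2 <- inter_motif_metric(a_out, m2)
  expect_equal(classify_alpha_c(a_out, m2, inter2, cal)$alpha_c, "out")
  expect_gt(inter2$inter_r6_k162_e181, cal$alpha_c_boundary)
})

test_that("G-loop call combines dihedral deviation and F144 displacement", {
  cal <- default_calibration()
  ext <- classify_gloop(make_toy_kinase("in", g_loop = "extended"), toy_map("in"), cal)
  fld <- classify_gloop(
    make_toy_kinase("in", g_loop = "folded"),
    toy_map("in", g_loop = "folded"), cal
  )
  expect_equal(ext$g_loop, "extended")
  expect_equal(fld$g_loop, "folded")
  expect_lt(ext$gloop_dev, 5) # ideal beta strand: essentially zero deviation
  expect_gt(fld$gloop_dev, cal$gloop_dev_threshold)
  expect_lt(fld$gloop_f144_dist, ext$gloop_f144_dist)

  # more than half the span missing -> explicit error
  a <- make_toy_kinase("in")
  trimmed <- a[!(a$resnum %in% 139:146), ]
  expect_error(classify_gloop(trimmed, toy_map("in"), cal), "incomplete")
})

test_that("equal centroid distances break ties toward DFG-in with zero margin", {
  cal <- default_calibration()
  cal$centroids["out", ] <- cal$centroids["in", ]
  a <- make_toy_kinase("in")
  m <- toy_map("in")
  r <- classify_dfg(inter_motif_metric(a, m), intra_motif_metric(a, m), cal)
  expect_equal(r$dfg, "in")
  expect_equal(r$dfg_margin, 0)
})

test_that("calibrations round-trip through the key-value text format", {
  cal <- default_calibration()
  tf <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cal, tf)
  back <- read_calibration(tf)
  expect_equal(back$centroids, cal$centroids, tolerance = 1e-9)
  expect_equal(back$center, cal$center, tolerance = 1e-9)
  expect_equal(back$scale, cal$scale, tolerance = 1e-9)
  expect_equal(back$gloop_dev_threshold, cal$gloop_dev_threshold, tolerance = 1e-9)
  a <- make_toy_kinase("out_up")
  m <- toy_map("out_up")
  r1 <- classify_dfg(inter_motif_metric(a, m), intra_motif_metric(a, m), cal)
  r2 <- classify_dfg(inter_motif_metric(a, m), intra_motif_metric(a, m), back)
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("tidy and glance summarise a calibration", {
  cal <- default_calibration()
  td <- tidy(cal)
  expect_true(all(c("feature", "quantity", "value") %in% names(td)))
  expect_equal(nrow(td), 9 * 4)
  gl <- glance(cal)
  expect_equal(gl$n_classes, 3)
  expect_true(is.finite(gl$gloop_dev_threshold))
})
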