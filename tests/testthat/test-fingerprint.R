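# 14-bit fingerprint encoding and comparison.

empty_table <- function() {
  tibble::tibble(
    kind = character(), subtype = character(), chain = character(),
    resnum = integer(), resname = character(), partner = character(),
    partner_type = character(), ligand_role = character(),
    distance = numeric(), angle = numeric(), ligand_id = character(),
    canonical = integer(), anchor = character()
  )
}

record_row <- function(canonical, kind, role, subtype = "x") {
  tibble::tibble(
    kind = kind, subtype = subtype, chain = "A", resnum = canonical,
    resname = "XXX", partner = "N1", partner_type = "ligand",
    ligand_role = role, distance = 3, angle = NA_real_, ligand_id = "L",
    canonical = canonical, anchor = ""
  )
}

test_that("an empty table gives the all-zero fingerprint", {
  fp <- compute_sift(empty_table())
  expect_equal(sift_string(fp), strrep("0", 14))
})

test_that("a single hinge record sets only bit 4", {
  tab <- record_row(213L, "HBOND_STRONG", "HA")
  fp <- compute_sift(tab)
  expect_equal(sift_string(fp), "00010000000000")
  # the same residue with the wrong role sets nothing
  fp2 <- compute_sift(record_row(213L, "HBOND_STRONG", "HD"))
  expect_equal(sift_string(fp2), strrep("0", 14))
  # weak H-bonds never set H-bond bits
  fp3 <- compute_sift(record_row(213L, "HBOND_WEAK", "HA"))
  expect_equal(sift_string(fp3), strrep("0", 14))
})

test_that("an engineered complex realizes bits 4, 10, 14 exactly", {
  cx <- make_toy_complex(c(4L, 10L, 14L))
  tab <- interaction_table(cx$atoms, cx$pose, cx$map)
  fp <- compute_sift(tab)
  expect_equal(which(unclass(fp) == 1L), c(4L, 10L, 14L), ignore_attr = TRUE)
  # audited against the generator's intent list
  for (i in seq_len(nrow(cx$audit))) {
    au <- cx$audit[i, ]
    hit <- tab$canonical == au$canonical & tab$kind == au$kind &
      tab$ligand_role == au$ligand_role & tab$partner_type == "ligand"
    expect_true(any(hit, na.rm = TRUE), label = paste("audit bit", au$bit))
  }
})

test_that("compute_sift is idempotent over duplicated records", {
  tab <- record_row(213L, "HBOND_STRONG", "HA")
  expect_identical(
    compute_sift(dplyr::bind_rows(tab, tab, tab)),
    compute_sift(tab)
  )
})

test_that("tanimoto matches the popcount definition", {
  z <- compute_sift(empty_table())
  b4 <- compute_sift(record_row(213L, "HBOND_STRONG", "HA"))
  b7 <- compute_sift(record_row(181L, "HBOND_STRONG", "HD"))
  expect_equal(tanimoto(b4, b4), 1.0)
  expect_equal(tanimoto(b4, b7), 0.0)
  expect_equal(tanimoto(z, z), 1.0) # both empty
  set.seed(11)
  for (k in 1:50) {
    a <- stats::rbinom(14, 1, 0.4)
    b <- stats::rbinom(14, 1, 0.4)
    want <- if (sum(a | b) == 0) 1 else sum(a & b) / sum(a | b)
    expect_equal(tanimoto(a, b), want)
  }
})

test_that("frequency profiles count set bits as percentages", {
  z <- compute_sift(empty_table())
  b4 <- compute_sift(record_row(213L, "HBOND_STRONG", "HA"))
  prof <- frequency_profile(list(z, z, b4, b4))
  expect_equal(prof$frequency_pct[prof$bit == 4], 50)
  expect_equal(sum(prof$frequency_pct[prof$bit != 4]), 0)
  prof0 <- frequency_profile(list(z))
  expect_true(all(prof0$frequency_pct == 0))
  # hand count over 10 seeded fingerprints
  set.seed(12)
  fps <- lapply(1:10, function(i) {
    structure(stats::rbinom(14, 1, 0.3), class = "kinconf_sift")
  })
  prof10 <- frequency_profile(fps)
  hand <- colSums(do.call(rbind, lapply(fps, unclass))) * 10
  expect_equal(prof10$frequency_pct, unname(hand))
})

test_that("tidy() labels the fingerprint bits", {
  b4 <- compute_sift(record_row(213L, "HBOND_STRONG", "HA"))
  td <- tidy(b4)
  expect_equal(nrow(td), 14)
  expect_equal(td$residue[td$set], "A213")
})
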