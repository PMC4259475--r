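# Random protein-ligand micro-fixtures plus a literal, loop-based oracle for
# every interaction detector. The oracle re-derives donor/acceptor/charge/
# aromatic typing for the FIXED residue/ligand vocabulary used here, so it
# shares no typing tables or geometry code with the package.

# protein scaffold: SER (donor+acceptor), LYS (cation), PHE (ring),
# ASP (anion), far apart; returns atom tibble
interaction_protein <- function() {
  mk_bb <- function(base) {
    list(
      N = base + c(0, 0, 0), CA = base + c(1.46, 0, 0),
      C = base + c(2.2, 1.3, 0), O = base + c(3.3, 1.5, 0.6)
    )
  }
  ser <- res_tbl("SER", 1, c(mk_bb(c(0, 0, 0)), list(
    CB = c(1.8, -1.3, 0.5), OG = c(1.4, -2.6, 0.1)
  )))
  lys <- res_tbl("LYS", 2, c(mk_bb(c(25, 0, 0)), list(
    CB = c(26.8, -1.3, 0.5), CG = c(26.5, -2.7, 0), CD = c(27.3, -3.9, 0.6),
    CE = c(27.0, -5.3, 0.1), NZ = c(27.8, -6.4, 0.8)
  )))
  ring <- kinconf:::.ring_coords(c(51.5, -3, 0.5), c(0, 0, 1), 6, 1.39)
  phe <- res_tbl("PHE", 3, c(mk_bb(c(50, 0, 0)), list(
    CB = c(51.8, -1.3, 0.5),
    CG = ring[1, ], CD1 = ring[2, ], CE1 = ring[3, ],
    CZ = ring[4, ], CE2 = ring[5, ], CD2 = ring[6, ]
  )))
  asp <- res_tbl("ASP", 4, c(mk_bb(c(75, 0, 0)), list(
    CB = c(76.8, -1.3, 0.5), CG = c(76.5, -2.7, 0),
    OD1 = c(75.6, -3.6, 0.3), OD2 = c(77.4, -3.4, -0.8)
  )))
  dplyr::bind_rows(ser, lys, phe, asp)
}

# ligand fragments thrown at random targets: amine (N+C), ether (O+2C),
# benzene, carboxylate; distances uniform in [2, 8] A. Draws where two
# fragments collide (inter-fragment atoms < 2.2 A, which would change the
# geometric feature typing) are rejected and redrawn deterministically.
random_interaction_ligand <- function(prot, seed) {
  for (try in 0:50) {
    lig <- .random_interaction_ligand_once(prot, seed + try * 100000L)
    frag <- c(1, 1, 2, 2, 2, rep(3, 6), rep(4, 4))
    d <- as.matrix(stats::dist(as.matrix(lig[, c("x", "y", "z")])))
    inter <- outer(frag, frag, "!=")
    if (min(d[inter]) >= 2.2) {
      return(lig)
    }
  }
  stop("no collision-free ligand draw found")
}

.random_interaction_ligand_once <- function(prot, seed) {
  set.seed(seed)
  rnd_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  at <- function(resnum, name) {
    r <- prot[prot$resnum == resnum & prot$name == name, ]
    c(r$x, r$y, r$z)
  }
  coords <- list()
  # amine near a random polar/charged target
  tgt <- list(at(1, "O"), at(1, "OG"), at(4, "OD1"))[[sample(3, 1)]]
  d <- rnd_dir()
  coords$N1 <- tgt + stats::runif(1, 2, 8) * d
  coords$C2 <- coords$N1 + 1.45 * d
  # ether acceptor near the SER backbone N-H direction or out in space
  nh <- at(1, "N") + c(-0.7, -0.7, 0) # roughly anti to CA/C
  coords$O3 <- nh + stats::runif(1, 0, 6) * rnd_dir()
  coords$C4 <- coords$O3 + c(1.43, 0, 0)
  coords$C5 <- coords$O3 + c(-0.7, 1.25, 0)
  # benzene near the PHE ring or the LYS NZ
  ctr <- list(c(51.5, -3, 0.5), at(2, "NZ"))[[sample(2, 1)]] +
    stats::runif(1, 3, 8) * rnd_dir()
  rc <- kinconf:::.ring_coords(ctr, rnd_dir(), 6, 1.39)
  for (i in 1:6) coords[[paste0("C", 5 + i)]] <- rc[i, ]
  # carboxylate near the LYS NZ
  base <- at(2, "NZ") + stats::runif(1, 2, 8) * rnd_dir()
  coords$C12 <- base
  coords$C13 <- base + c(1.5, 0, 0)
  coords$O14 <- base + c(2.2, 1.05, 0)
  coords$O15 <- base + c(2.2, -1.05, 0)
  res_tbl("LIG", 900, coords, chain = "L", hetero = TRUE)
}

# ---- literal oracle -------------------------------------------------------

.o_unit <- function(v) v / sqrt(sum(v^2))

oracle_infer_h <- function(d_xyz, all_xyz) {
  d2 <- colSums((t(all_xyz) - d_xyz)^2)
  nb <- which(d2 > 0.25 & d2 < 1.9^2)
  if (!length(nb)) {
    return(NULL)
  }
  s <- c(0, 0, 0)
  for (i in nb) s <- s + .o_unit(all_xyz[i, ] - d_xyz)
  if (sqrt(sum(s^2)) < 1e-6) {
    return(NULL)
  }
  d_xyz - .o_unit(s)
}

# expected record keys per kind for the fixed vocabulary above
oracle_interaction_sets <- function(prot, lig) {
  px <- as.matrix(prot[, c("x", "y", "z")])
  lx <- as.matrix(lig[, c("x", "y", "z")])
  all_prot_el <- prot$element
  gx <- function(tab, i) c(tab$x[i], tab$y[i], tab$z[i])

  # typing (hard-coded for this vocabulary)
  p_don <- which(prot$name == "N" | (prot$resname == "SER" & prot$name == "OG") |
    (prot$resname == "LYS" & prot$name == "NZ"))
  p_acc <- which(prot$name == "O" | (prot$resname == "SER" & prot$name == "OG") |
    (prot$resname == "ASP" & prot$name %in% c("OD1", "OD2")))
  l_don <- which(lig$name == "N1")
  l_acc <- which(lig$name %in% c("O3", "O14", "O15"))
  l_cat <- which(lig$name == "N1")
  l_anion <- which(lig$name %in% c("O14", "O15"))
  l_ring <- match(paste0("C", 6:11), lig$name)
  l_carbons <- which(lig$element == "C")
  phe_ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  p_ring_idx <- which(prot$resname == "PHE" & prot$name %in% phe_ring_names)
  prg <- oracle_ring_geom(px[p_ring_idx, , drop = FALSE])
  lrg <- oracle_ring_geom(lx[l_ring, , drop = FALSE])

  strong <- character()
  weak <- character()
  salt <- character()
  catpi <- character()
  pipi <- character()
  chpi_n <- 0L

  # strong: protein donor -> ligand acceptor
  for (i in p_don) {
    for (j in l_acc) {
      d <- oracle_dist(gx(prot, i), gx(lig, j))
      if (d > 3.5) next
      h <- oracle_infer_h(gx(prot, i), px)
      if (!is.null(h)) {
        if (oracle_angle(gx(prot, i), h, gx(lig, j)) < 120) next
      }
      strong <- c(strong, paste(prot$resnum[i], lig$name[j], "HA"))
    }
  }
  # strong: ligand donor -> protein acceptor
  for (j in l_don) {
    for (i in p_acc) {
      d <- oracle_dist(gx(lig, j), gx(prot, i))
      if (d > 3.5) next
      h <- oracle_infer_h(gx(lig, j), lx)
      if (!is.null(h)) {
        if (oracle_angle(gx(lig, j), h, gx(prot, i)) < 120) next
      }
      strong <- c(strong, paste(prot$resnum[i], lig$name[j], "HD"))
    }
  }
  # weak: ligand ring C -> protein acceptor; protein ring C -> ligand acceptor
  for (j in l_ring) {
    for (i in p_acc) {
      if (oracle_dist(gx(lig, j), gx(prot, i)) <= 3.8) {
        weak <- c(weak, paste(prot$resnum[i], lig$name[j], "HD"))
      }
    }
  }
  for (i in p_ring_idx) {
    for (j in l_acc) {
      if (oracle_dist(gx(prot, i), gx(lig, j)) <= 3.8) {
        weak <- c(weak, paste(prot$resnum[i], lig$name[j], "HA"))
      }
    }
  }
  # salt bridges (group minimum distance)
  nz <- which(prot$resname == "LYS" & prot$name == "NZ")
  if (length(l_anion)) {
    dmin <- min(vapply(l_anion, function(j) oracle_dist(gx(prot, nz), gx(lig, j)), 1))
    if (dmin <= 4.0) salt <- c(salt, "2 +")
  }
  od <- which(prot$resname == "ASP" & prot$name %in% c("OD1", "OD2"))
  if (length(l_cat)) {
    dmin <- min(vapply(od, function(i) oracle_dist(gx(prot, i), gx(lig, l_cat)), 1))
    if (dmin <= 4.0) salt <- c(salt, "4 -")
  }
  # cation-pi
  if (oracle_count_cation_pi(list(gx(prot, nz)), list(lrg)) > 0) {
    catpi <- c(catpi, "2 protein-cation")
  }
  if (oracle_count_cation_pi(list(gx(lig, l_cat)), list(prg)) > 0) {
    catpi <- c(catpi, "3 ligand-cation")
  }
  # pi-pi
  d <- oracle_dist(prg$centroid, lrg$centroid)
  ang <- acos(min(1, abs(sum(prg$normal * lrg$normal)))) * 180 / pi
  if ((d <= 5.5 && ang <= 30) || (d >= 4.5 && d <= 6.5 && ang >= 60 && ang <= 90)) {
    pipi <- c(pipi, "3")
  }
  # CH-pi (count only)
  for (j in l_carbons) {
    dd <- oracle_dist(gx(lig, j), prg$centroid)
    if (dd < 1e-6 || dd > 4.5) next
    v <- .o_unit(gx(lig, j) - prg$centroid)
    elev <- 90 - acos(min(1, abs(sum(v * prg$normal)))) * 180 / pi
    if (elev >= 30) chpi_n <- chpi_n + 1L
  }
  p_c <- which(prot$element == "C")
  for (i in p_c) {
    dd <- oracle_dist(gx(prot, i), lrg$centroid)
    if (dd < 1e-6 || dd > 4.5) next
    v <- .o_unit(gx(prot, i) - lrg$centroid)
    elev <- 90 - acos(min(1, abs(sum(v * lrg$normal)))) * 180 / pi
    if (elev >= 30) chpi_n <- chpi_n + 1L
  }
  list(
    strong = sort(unique(strong)), weak = sort(unique(weak)),
    salt = sort(unique(salt)), catpi = sort(unique(catpi)),
    pipi = sort(unique(pipi)), chpi_n = chpi_n
  )
}

# package detectors reduced to the same keys
detector_interaction_sets <- function(prot, lig, crit = interaction_criteria()) {
  pose <- pose_of(lig)
  hb <- detect_hbonds(prot, pose, crit)
  sb <- detect_salt_bridges(prot, pose, crit)
  cp <- detect_cation_pi(prot, pose, crit)
  pp <- detect_pi_stacking(prot, pose, crit)
  ch <- detect_ch_pi(prot, pose, crit)
  list(
    strong = sort(unique(with(
      hb[hb$kind == "HBOND_STRONG", ],
      paste(resnum, partner, ligand_role)
    ))),
    weak = sort(unique(with(
      hb[hb$kind == "HBOND_WEAK", ],
      paste(resnum, partner, ligand_role)
    ))),
    salt = sort(unique(with(sb, paste(resnum, sub("protein", "", subtype))))),
    catpi = sort(unique(with(cp, paste(resnum, subtype)))),
    pipi = sort(unique(as.character(pp$resnum))),
    chpi_n = nrow(ch)
  )
}
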