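# Non-covalent interaction detection between a protein structure and a ligand
# pose, plus the conserved intra-protein contacts (Lys162-Glu181 and
# Glu181-Arg255 ion pairs, Lys162-Phe275 cation-pi).
#
# All criteria are geometric, work from heavy atoms (donor hydrogens are
# inferred from heavy-atom geometry where possible, otherwise the check falls
# back to distance only and the record is flagged "no-angle"), and are fully
# user-overridable via interaction_criteria().

#' Geometric criteria for interaction detection
#'
#' Defaults follow common structure-interaction-fingerprint practice:
#' strong H-bond donor-acceptor <= 3.5 A with D-H...A >= 120 deg where a
#' hydrogen is inferable; weak (C-H) H-bond <= 3.8 A; salt bridge <= 4.0 A
#' between opposite formal-charge heavy atoms; cation-pi <= 6.0 A within 30
#' deg of the ring normal; pi-pi face <= 5.5 A / <= 30 deg, edge 4.5-6.5 A /
#' 60-90 deg; CH-pi <= 4.5 A with >= 30 deg elevation above the ring plane.
#'
#' @param ... Named overrides of any default listed above.
#' @return An `interaction_criteria` object (named list).
#' @export
interaction_criteria <- function(...) {
  crit <- list(
    hbond_strong_dist = 3.5, hbond_angle = 120, hbond_weak_dist = 3.8,
    salt_bridge_dist = 4.0,
    cation_pi_dist = 6.0, cation_pi_angle = 30,
    pipi_face_dist = 5.5, pipi_face_angle = 30,
    pipi_edge_dist_min = 4.5, pipi_edge_dist_max = 6.5,
    pipi_edge_angle_min = 60, pipi_edge_angle_max = 90,
    chpi_dist = 4.5, chpi_elev = 30,
    vdw_slack = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(crit))
  if (length(bad)) stop("unknown criteria: ", paste(bad, collapse = ", "), call. = FALSE)
  crit[names(over)] <- over
  structure(crit, class = "interaction_criteria")
}

.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47,
  CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, H = 1.20
)

# --- protein-side typing tables -------------------------------------------

.protein_sc_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), ASN = "ND2",
  GLN = "NE2", TRP = "NE1"
)
.protein_sc_acceptors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  MET = "SD"
)
.protein_cations <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.protein_anions <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.protein_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
)

.res_key <- function(a) paste(a$chain, a$resnum, sep = ":")

# atom-level protein donor/acceptor tables
protein_polar_atoms <- function(prot, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  tab <- if (role == "donor") .protein_sc_donors else .protein_sc_acceptors
  sc <- prot[
    prot$resname %in% names(tab) &
      mapply(function(rn, nm) nm %in% tab[[rn]], prot$resname, prot$name),
  ]
  bb <- if (role == "donor") {
    prot[prot$name == "N" & prot$resname != "PRO", ]
  } else {
    prot[prot$name %in% c("O", "OXT"), ]
  }
  dplyr::bind_rows(bb, sc)
}

# rings of aromatic residues with all ring atoms present
protein_ring_list <- function(prot) {
  arom <- prot[prot$resname %in% names(.protein_rings), ]
  if (nrow(arom) == 0) {
    return(list())
  }
  out <- list()
  for (key in unique(.res_key(arom))) {
    res <- arom[.res_key(arom) == key, ]
    need <- .protein_rings[[res$resname[1]]]
    if (!all(need %in% res$name)) next
    idx <- match(need, res$name)
    xyz <- as.matrix(res[idx, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2, ctr))
    out[[length(out) + 1]] <- list(
      chain = res$chain[1], resnum = res$resnum[1], resname = res$resname[1],
      centroid = ctr, normal = sv$v[, 3],
      carbons = as.matrix(res[idx, c("x", "y", "z")])[substr(need, 1, 1) == "C", , drop = FALSE]
    )
  }
  out
}

# inferred donor-hydrogen position from heavy-atom geometry: H sits opposite
# the resultant of the donor's covalent neighbours. NULL when no neighbour is
# found (then the caller uses the distance-only criterion).
infer_donor_h <- function(donor_xyz, context_xyz, context_el) {
  d2 <- colSums((t(context_xyz) - donor_xyz)^2)
  nb <- which(d2 > 0.25 & d2 < 1.9^2 & context_el != "H")
  if (!length(nb)) {
    return(NULL)
  }
  dirs <- vapply(nb, function(i) .unit(context_xyz[i, ] - donor_xyz), numeric(3))
  res <- -rowSums(dirs)
  if (sqrt(sum(res^2)) < 1e-6) {
    return(NULL)
  }
  donor_xyz + 1.0 * .unit(res)
}

.empty_records <- function() {
  tibble::tibble(
    kind = character(), subtype = character(), chain = character(),
    resnum = integer(), resname = character(),
    partner = character(), partner_type = character(),
    ligand_role = character(), distance = numeric(), angle = numeric(),
    ligand_id = character()
  )
}

.record <- function(kind, subtype, res_row, partner, partner_type,
                    ligand_role, distance, angle, ligand_id) {
  tibble::tibble(
    kind = kind, subtype = subtype,
    chain = res_row$chain, resnum = as.integer(res_row$resnum),
    resname = res_row$resname,
    partner = partner, partner_type = partner_type,
    ligand_role = ligand_role,
    distance = distance, angle = angle, ligand_id = ligand_id
  )
}

.pose_parts <- function(pose) {
  if (is.data.frame(pose)) {
    stopifnot(nrow(pose) == 1)
    pose <- as.list(pose)
    pose$atoms <- pose$atoms[[1]]
    pose$features <- pose$features[[1]]
  }
  la <- pose$atoms
  fx <- pose$features
  feat_idx <- function(f) {
    rows <- fx[fx$feature == f, ]
    if (nrow(rows) == 0) {
      return(integer(0))
    }
    sort(unique(unlist(rows$atoms)))
  }
  rings <- fx[fx$feature == "Ar", ]$atoms
  list(
    atoms = la,
    id = pose$ligand_id %||% paste(la$chain[1], la$resnum[1], la$resname[1], sep = ":"),
    hd = feat_idx("HD"), ha = feat_idx("HA"),
    cation = feat_idx("Cation"), anion = feat_idx("Anion"),
    hydro = feat_idx("Hydrophobe"),
    rings = rings
  )
}

.lig_xyz <- function(la, i) c(la$x[i], la$y[i], la$z[i])

.lig_ring_geom <- function(la, idx) {
  xyz <- as.matrix(la[idx, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3], xyz = xyz)
}

#' Detect hydrogen bonds between protein and ligand
#'
#' Strong H-bonds pair an N/O donor with an N/O acceptor at <= 3.5 A and,
#' where a donor hydrogen can be inferred from heavy-atom geometry,
#' D-H...A >= 120 deg (otherwise the record carries the "no-angle" flag in
#' its subtype). Weak H-bonds pair an aromatic/sp2 C-H donor with an N/O
#' acceptor at <= 3.8 A.
#'
#' @param atoms Atom tibble.
#' @param pose One ligand pose (row of [extract_ligands()]).
#' @param crit An [interaction_criteria()].
#' @return Tibble of interaction records.
#' @export
detect_hbonds <- function(atoms, pose, crit = interaction_criteria()) {
  prot <- protein_atoms(atoms)
  lp <- .pose_parts(pose)
  la <- lp$atoms
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  lig_xyz <- as.matrix(la[, c("x", "y", "z")])
  out <- list()
  push <- function(r) out[[length(out) + 1]] <<- r

  strong_pair <- function(d_xyz, a_xyz, ctx_xyz, ctx_el) {
    dist <- pt_distance(d_xyz, a_xyz)
    if (dist > crit$hbond_strong_dist) {
      return(NULL)
    }
    h <- infer_donor_h(d_xyz, ctx_xyz, ctx_el)
    if (is.null(h)) {
      return(list(distance = dist, angle = NA_real_, noang = TRUE))
    }
    ang <- pt_angle(d_xyz, h, a_xyz)
    if (ang < crit$hbond_angle) {
      return(NULL)
    }
    list(distance = dist, angle = ang, noang = FALSE)
  }

  # protein donor -> ligand acceptor
  pdon <- protein_polar_atoms(prot, "donor")
  for (i in seq_len(nrow(pdon))) {
    d_xyz <- c(pdon$x[i], pdon$y[i], pdon$z[i])
    for (j in lp$ha) {
      a_xyz <- .lig_xyz(la, j)
      hit <- strong_pair(d_xyz, a_xyz, prot_xyz, prot$element)
      if (is.null(hit)) next
      sub <- paste0(pdon$element[i], "-H...", la$element[j])
      if (hit$noang) sub <- paste0(sub, " (no-angle)")
      push(.record(
        "HBOND_STRONG", sub, pdon[i, ], la$name[j], "ligand", "HA",
        hit$distance, hit$angle, lp$id
      ))
    }
  }
  # ligand donor -> protein acceptor
  pacc <- protein_polar_atoms(prot, "acceptor")
  for (j in lp$hd) {
    d_xyz <- .lig_xyz(la, j)
    for (i in seq_len(nrow(pacc))) {
      a_xyz <- c(pacc$x[i], pacc$y[i], pacc$z[i])
      hit <- strong_pair(d_xyz, a_xyz, lig_xyz, la$element)
      if (is.null(hit)) next
      sub <- paste0(la$element[j], "-H...", pacc$element[i])
      if (hit$noang) sub <- paste0(sub, " (no-angle)")
      push(.record(
        "HBOND_STRONG", sub, pacc[i, ], la$name[j], "ligand", "HD",
        hit$distance, hit$angle, lp$id
      ))
    }
  }
  # weak: ligand aromatic-ring C-H donor -> protein acceptor
  lig_ring_c <- unique(unlist(lp$rings))
  lig_ring_c <- lig_ring_c[toupper(la$element[lig_ring_c]) == "C"]
  for (j in lig_ring_c) {
    d_xyz <- .lig_xyz(la, j)
    for (i in seq_len(nrow(pacc))) {
      dist <- pt_distance(d_xyz, c(pacc$x[i], pacc$y[i], pacc$z[i]))
      if (dist <= crit$hbond_weak_dist) {
        push(.record(
          "HBOND_WEAK", paste0("C-H...", pacc$element[i]),
          pacc[i, ], la$name[j], "ligand", "HD", dist, NA_real_, lp$id
        ))
      }
    }
  }
  # weak: protein aromatic C-H donor -> ligand acceptor
  for (ring in protein_ring_list(prot)) {
    for (k in seq_len(nrow(ring$carbons))) {
      for (j in lp$ha) {
        dist <- pt_distance(ring$carbons[k, ], .lig_xyz(la, j))
        if (dist <= crit$hbond_weak_dist) {
          push(.record(
            "HBOND_WEAK", paste0("C-H...", la$element[j]),
            tibble::tibble(
              chain = ring$chain, resnum = ring$resnum, resname = ring$resname
            ),
            la$name[j], "ligand", "HA", dist, NA_real_, lp$id
          ))
        }
      }
    }
  }
  if (!length(out)) {
    return(.empty_records())
  }
  dplyr::distinct(
    dplyr::bind_rows(out),
    .data$kind, .data$resnum, .data$chain, .data$partner, .data$ligand_role,
    .keep_all = TRUE
  )
}

# canonical intra-protein pairs scanned by the protein-protein detectors
.protein_pairs_salt <- list(c(162, 181), c(181, 255))
.protein_pair_catpi <- c(162, 275)

.charged_group_atoms <- function(prot, resnum_author) {
  res <- prot[prot$resnum == resnum_author, , drop = FALSE]
  if (nrow(res) == 0) {
    return(NULL)
  }
  rn <- res$resname[1]
  nm <- c(.protein_cations[[rn]], .protein_anions[[rn]])
  res <- res[res$name %in% nm, , drop = FALSE]
  if (nrow(res) == 0) {
    return(NULL)
  }
  list(res = res, charge = if (rn %in% names(.protein_cations)) "+" else "-")
}

#' Detect salt bridges
#'
#' Protein-ligand: minimum heavy-atom distance between a charged protein
#' group (Lys/Arg vs Asp/Glu) and an opposite-charge ligand feature
#' <= 4.0 A. Protein-protein: only the conserved pairs K162-E181 and
#' E181-R255 are scanned (requires `map`).
#'
#' @param atoms Atom tibble.
#' @param pose Ligand pose or `NULL` for protein-only analysis.
#' @param crit An [interaction_criteria()].
#' @param map Optional `residue_map` enabling the conserved protein pairs.
#' @return Tibble of interaction records.
#' @export
detect_salt_bridges <- function(atoms, pose = NULL, crit = interaction_criteria(),
                                map = NULL) {
  prot <- protein_atoms(atoms)
  out <- list()
  push <- function(r) out[[length(out) + 1]] <<- r

  group_min_dist <- function(xyz_a, xyz_b) {
    min(apply(xyz_a, 1, function(p) {
      min(sqrt(colSums((t(xyz_b) - p)^2)))
    }))
  }

  if (!is.null(pose)) {
    lp <- .pose_parts(pose)
    la <- lp$atoms
    for (rn in unique(prot$resnum[prot$resname %in% c(
      names(.protein_cations), names(.protein_anions)
    )])) {
      grp <- .charged_group_atoms(prot, rn)
      if (is.null(grp)) next
      lig_idx <- if (grp$charge == "+") lp$anion else lp$cation
      if (!length(lig_idx)) next
      d <- group_min_dist(
        as.matrix(grp$res[, c("x", "y", "z")]),
        as.matrix(la[lig_idx, c("x", "y", "z")])
      )
      if (d <= crit$salt_bridge_dist) {
        push(.record(
          "SALT_BRIDGE", paste0("protein", grp$charge),
          grp$res[1, ], paste(la$name[lig_idx], collapse = ","),
          "ligand", if (grp$charge == "+") "Anion" else "Cation",
          d, NA_real_, lp$id
        ))
      }
    }
  }
  if (!is.null(map)) {
    for (pair in .protein_pairs_salt) {
      a1 <- canonical_to_author(map, pair[1])
      a2 <- canonical_to_author(map, pair[2])
      if (is.na(a1) || is.na(a2)) next
      g1 <- .charged_group_atoms(prot, a1)
      g2 <- .charged_group_atoms(prot, a2)
      if (is.null(g1) || is.null(g2) || g1$charge == g2$charge) next
      d <- group_min_dist(
        as.matrix(g1$res[, c("x", "y", "z")]),
        as.matrix(g2$res[, c("x", "y", "z")])
      )
      if (d <= crit$salt_bridge_dist) {
        push(.record(
          "SALT_BRIDGE", "protein-protein", g1$res[1, ],
          paste0(g2$res$resname[1], a2), "protein", NA_character_,
          d, NA_real_, NA_character_
        ))
      }
    }
  }
  if (!length(out)) .empty_records() else dplyr::bind_rows(out)
}

.catpi_geom <- function(cation_xyz, ring) {
  d <- pt_distance(cation_xyz, ring$centroid)
  v <- .unit(cation_xyz - ring$centroid)
  ang <- acos(min(1, abs(sum(v * ring$normal)))) * 180 / pi
  list(distance = d, angle = ang)
}

#' Detect cation-pi interactions
#'
#' Cation charge centre to aromatic ring centroid <= 6.0 A with the centroid
#' to cation vector within 30 deg of the ring normal. Scans protein cations
#' against ligand rings, ligand cations against protein rings, and the
#' conserved protein-protein pair K162-F275 when `map` is given.
#'
#' @inheritParams detect_salt_bridges
#' @export
detect_cation_pi <- function(atoms, pose = NULL, crit = interaction_criteria(),
                             map = NULL) {
  prot <- protein_atoms(atoms)
  prings <- protein_ring_list(prot)
  out <- list()
  push <- function(r) out[[length(out) + 1]] <<- r

  if (!is.null(pose)) {
    lp <- .pose_parts(pose)
    la <- lp$atoms
    # protein cation vs ligand ring
    pcat <- prot[
      prot$resname %in% names(.protein_cations) &
        mapply(function(rn, nm) nm %in% .protein_cations[[rn]], prot$resname, prot$name),
    ]
    for (i in seq_len(nrow(pcat))) {
      for (ridx in lp$rings) {
        rg <- .lig_ring_geom(la, ridx)
        g <- .catpi_geom(c(pcat$x[i], pcat$y[i], pcat$z[i]), rg)
        if (g$distance <= crit$cation_pi_dist && g$angle <= crit$cation_pi_angle) {
          push(.record(
            "CATION_PI", "protein-cation", pcat[i, ],
            paste(la$name[ridx], collapse = ","), "ligand", "Ar",
            g$distance, g$angle, lp$id
          ))
        }
      }
    }
    # ligand cation vs protein ring
    for (j in lp$cation) {
      for (ring in prings) {
        g <- .catpi_geom(.lig_xyz(la, j), ring)
        if (g$distance <= crit$cation_pi_dist && g$angle <= crit$cation_pi_angle) {
          push(.record(
            "CATION_PI", "ligand-cation",
            tibble::tibble(
              chain = ring$chain, resnum = ring$resnum, resname = ring$resname
            ),
            la$name[j], "ligand", "Cation", g$distance, g$angle, lp$id
          ))
        }
      }
    }
  }
  if (!is.null(map)) {
    a_cat <- canonical_to_author(map, .protein_pair_catpi[1])
    a_ring <- canonical_to_author(map, .protein_pair_catpi[2])
    if (!is.na(a_cat) && !is.na(a_ring)) {
      cat_res <- prot[prot$resnum == a_cat & prot$name %in% unlist(.protein_cations), ]
      ring <- purrr::detect(prings, function(r) r$resnum == a_ring)
      if (nrow(cat_res) > 0 && !is.null(ring)) {
        g <- .catpi_geom(c(cat_res$x[1], cat_res$y[1], cat_res$z[1]), ring)
        if (g$distance <= crit$cation_pi_dist && g$angle <= crit$cation_pi_angle) {
          push(.record(
            "CATION_PI", "protein-protein", cat_res[1, ],
            paste0(ring$resname, a_ring), "protein", NA_character_,
            g$distance, g$angle, NA_character_
          ))
        }
      }
    }
  }
  if (!length(out)) .empty_records() else dplyr::bind_rows(out)
}

#' Detect pi-pi stacking
#'
#' Face stacking: ring-centroid distance <= 5.5 A with interplanar angle
#' <= 30 deg. Edge (T-shaped): 4.5-6.5 A with 60-90 deg.
#'
#' @inheritParams detect_hbonds
#' @export
detect_pi_stacking <- function(atoms, pose, crit = interaction_criteria()) {
  prot <- protein_atoms(atoms)
  lp <- .pose_parts(pose)
  la <- lp$atoms
  out <- list()
  for (ring in protein_ring_list(prot)) {
    for (ridx in lp$rings) {
      rg <- .lig_ring_geom(la, ridx)
      d <- pt_distance(ring$centroid, rg$centroid)
      ang <- acos(min(1, abs(sum(ring$normal * rg$normal)))) * 180 / pi
      lab <- NULL
      if (d <= crit$pipi_face_dist && ang <= crit$pipi_face_angle) {
        lab <- "face"
      } else if (d >= crit$pipi_edge_dist_min && d <= crit$pipi_edge_dist_max &&
        ang >= crit$pipi_edge_angle_min && ang <= crit$pipi_edge_angle_max) {
        lab <- "edge"
      }
      if (!is.null(lab)) {
        out[[length(out) + 1]] <- .record(
          "PI_PI", lab,
          tibble::tibble(
            chain = ring$chain, resnum = ring$resnum, resname = ring$resname
          ),
          paste(la$name[ridx], collapse = ","), "ligand", "Ar",
          d, ang, lp$id
        )
      }
    }
  }
  if (!length(out)) .empty_records() else dplyr::bind_rows(out)
}

#' Detect CH-pi interactions
#'
#' A carbon within 4.5 A of a ring centroid and elevated >= 30 deg above the
#' ring plane. Scans ligand carbons against protein rings and protein
#' aromatic carbons against ligand rings.
#'
#' @inheritParams detect_hbonds
#' @export
detect_ch_pi <- function(atoms, pose, crit = interaction_criteria()) {
  prot <- protein_atoms(atoms)
  lp <- .pose_parts(pose)
  la <- lp$atoms
  out <- list()
  elev <- function(p, ring) {
    d <- pt_distance(p, ring$centroid)
    if (d < 1e-6) {
      return(list(distance = d, elev = 90))
    }
    v <- .unit(p - ring$centroid)
    ang <- acos(min(1, abs(sum(v * ring$normal)))) * 180 / pi
    list(distance = d, elev = 90 - ang)
  }
  lig_c <- which(toupper(la$element) == "C")
  for (ring in protein_ring_list(prot)) {
    for (j in lig_c) {
      g <- elev(.lig_xyz(la, j), ring)
      if (g$distance <= crit$chpi_dist && g$elev >= crit$chpi_elev) {
        out[[length(out) + 1]] <- .record(
          "CH_PI", "ligand-CH",
          tibble::tibble(
            chain = ring$chain, resnum = ring$resnum, resname = ring$resname
          ),
          la$name[j], "ligand", "Hydrophobe", g$distance, g$elev, lp$id
        )
      }
    }
  }
  for (ridx in lp$rings) {
    rg <- .lig_ring_geom(la, ridx)
    ring <- list(centroid = rg$centroid, normal = rg$normal)
    pc <- prot[toupper(prot$element) == "C", ]
    for (i in seq_len(nrow(pc))) {
      g <- elev(c(pc$x[i], pc$y[i], pc$z[i]), ring)
      if (g$distance <= crit$chpi_dist && g$elev >= crit$chpi_elev) {
        out[[length(out) + 1]] <- .record(
          "CH_PI", "protein-CH", pc[i, ],
          paste(la$name[ridx], collapse = ","), "ligand", "Ar",
          g$distance, g$elev, lp$id
        )
      }
    }
  }
  if (!length(out)) .empty_records() else dplyr::bind_rows(out)
}

#' Detect van der Waals contacts
#'
#' Heavy-atom pairs closer than the sum of their van der Waals radii plus
#' 0.5 A. Recorded for completeness; never enters the fingerprint.
#'
#' @inheritParams detect_hbonds
#' @export
detect_vdw <- function(atoms, pose, crit = interaction_criteria()) {
  prot <- protein_atoms(atoms)
  lp <- .pose_parts(pose)
  la <- lp$atoms
  out <- list()
  rp <- .vdw_radii[toupper(prot$element)]
  rp[is.na(rp)] <- 1.7
  rl <- .vdw_radii[toupper(la$element)]
  rl[is.na(rl)] <- 1.7
  for (j in seq_len(nrow(la))) {
    p <- .lig_xyz(la, j)
    d <- sqrt((prot$x - p[1])^2 + (prot$y - p[2])^2 + (prot$z - p[3])^2)
    hits <- which(d <= rp + rl[j] + crit$vdw_slack)
    for (i in hits) {
      out[[length(out) + 1]] <- .record(
        "VDW", paste0(prot$element[i], "|", la$element[j]),
        prot[i, ], la$name[j], "ligand", NA_character_,
        d[i], NA_real_, lp$id
      )
    }
  }
  if (!length(out)) .empty_records() else dplyr::bind_rows(out)
}

#' Full interaction table for one structure (and optional ligand pose)
#'
#' Union of all detectors, labelled with canonical positions and anchor names
#' via the residue map and sorted by canonical position. With `pose = NULL`
#' only the conserved protein-protein contacts are scanned.
#'
#' @param atoms Atom tibble.
#' @param pose Ligand pose or `NULL`.
#' @param map A `residue_map`.
#' @param crit An [interaction_criteria()].
#' @param include_vdw Include van der Waals contact records (default FALSE).
#' @return Tibble of records with `canonical` and `anchor` columns.
#' @export
interaction_table <- function(atoms, pose = NULL, map,
                              crit = interaction_criteria(),
                              include_vdw = FALSE) {
  recs <- list(
    detect_salt_bridges(atoms, pose, crit, map),
    detect_cation_pi(atoms, pose, crit, map)
  )
  if (!is.null(pose)) {
    recs <- c(recs, list(
      detect_hbonds(atoms, pose, crit),
      detect_pi_stacking(atoms, pose, crit),
      detect_ch_pi(atoms, pose, crit)
    ))
    if (include_vdw) recs <- c(recs, list(detect_vdw(atoms, pose, crit)))
  }
  tab <- dplyr::bind_rows(recs)
  if (nrow(tab) == 0) {
    tab <- .empty_records()
  }
  idx <- match(tab$resnum, map$author_number)
  tab$canonical <- map$canonical_position[idx]
  tab$anchor <- map$anchor[idx]
  dplyr::arrange(tab, .data$canonical, .data$kind)
}

#' Serialize an interaction table with its criteria header
#'
#' @param table Record tibble from [interaction_table()].
#' @param crit The criteria used.
#' @param file Path or `NULL`.
#' @return Lines, invisibly.
#' @export
write_interaction_table <- function(table, crit = interaction_criteria(), file = NULL) {
  hdr <- c(
    "# kinconf interaction table",
    paste0("# criteria: ", paste(names(crit), unlist(crit), sep = "=", collapse = " "))
  )
  cols <- c(
    "kind", "subtype", "chain", "resnum", "resname", "canonical", "anchor",
    "partner", "partner_type", "ligand_role", "distance", "angle"
  )
  cols <- intersect(cols, names(table))
  body <- c(
    paste(cols, collapse = "\t"),
    vapply(seq_len(nrow(table)), function(i) {
      paste(vapply(cols, function(cc) {
        v <- table[[cc]][i]
        if (is.numeric(v)) format(round(v, 3)) else as.character(v %||% "")
      }, character(1)), collapse = "\t")
    }, character(1))
  )
  ln <- c(hdr, body)
  if (!is.null(file)) writeLines(ln, file)
  invisible(ln)
}
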