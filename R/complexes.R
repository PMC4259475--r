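# Synthetic protein-ligand complexes realizing a requested fingerprint.
#
# For every requested bit the generator places a small ligand fragment at
# mid-window geometry relative to the target residue: amine-like donors
# (N + trailing C) 2.9 A from the acceptor atom, ether-like acceptors
# (O + two C) 3.0 A along the residue's inferred donor-H direction, benzene
# probes 3.8 A along a ring normal (pi-pi) or 4.5 A along a free direction
# from the cation (cation-pi). Fragment directions are chosen by a clearance
# search so that no unintended bit-relevant geometry is created; the audit
# list of intended records is returned for oracle comparison.

# 200 candidate directions on a Fibonacci sphere
.dir_candidates <- local({
  n <- 200
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
})

.min_dist_to <- function(p, xyz) {
  if (nrow(xyz) == 0) {
    return(Inf)
  }
  min(sqrt(colSums((t(xyz) - p)^2)))
}

# choose the direction whose fragment points stay farthest from `avoid`
# while honouring hard keep-out constraints (each a list(xyz, min))
.pick_direction <- function(origin, offsets, avoid_xyz, keepouts = list()) {
  best <- NULL
  best_score <- -Inf
  for (k in seq_len(nrow(.dir_candidates))) {
    d <- .dir_candidates[k, ]
    pts <- t(vapply(offsets, function(o) origin + o * d, numeric(3)))
    ok <- all(vapply(keepouts, function(ko) {
      all(apply(pts, 1, function(p) .min_dist_to(p, ko$xyz) >= ko$min))
    }, logical(1)))
    if (!ok) next
    sc <- min(apply(pts, 1, function(p) .min_dist_to(p, avoid_xyz)))
    if (sc > best_score) {
      best_score <- sc
      best <- d
    }
  }
  if (is.null(best)) {
    stop("toy complex: no clash-free direction found", call. = FALSE)
  }
  best
}

.res_atoms_of <- function(prot, resnum) {
  prot[prot$resnum == resnum, , drop = FALSE]
}

.named_xyz <- function(res, name) {
  i <- match(name, res$name)
  c(res$x[i], res$y[i], res$z[i])
}

#' Generate a synthetic kinase-ligand complex realizing a fingerprint
#'
#' Builds a toy kinase ([make_toy_kinase()]) plus a single HET group ("LIG")
#' whose fragments realize exactly the requested fingerprint bits (1-14, as
#' in [sift_bit_table()]).
#'
#' @param bits Integer vector of requested bits (subset of 1:14).
#' @param dfg,alpha_c,g_loop Conformation of the protein (defaults: DFG
#'   out-up with its canonical alphaC-out pairing, extended G-loop).
#' @param seed Integer seed (reserved for noisy variants).
#' @param noise_sigma Gaussian coordinate noise on the protein, Angstrom.
#' @return List: `atoms` (protein + ligand), `pose` (row of
#'   [extract_ligands()]), `map` (residue map), `audit` (tibble of intended
#'   records: `bit`, `canonical`, `kind`, `ligand_role`).
#' @export
make_toy_complex <- function(bits = integer(), dfg = "out_up", alpha_c = NULL,
                             g_loop = "extended", noise_sigma = 0, seed = 1L) {
  bits <- sort(unique(as.integer(bits)))
  stopifnot(all(bits %in% 1:14))
  prot <- make_toy_kinase(dfg, alpha_c, g_loop, noise_sigma = noise_sigma, seed = seed)
  map <- align_to_reference(chain_sequence(prot, "A"))
  bt <- sift_bit_table()
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  prings <- protein_ring_list(prot)
  pring_centroids <- do.call(rbind, lapply(prings, function(r) r$centroid))
  pcations <- prot[
    prot$resname %in% names(.protein_cations) &
      mapply(function(rn, nm) nm %in% .protein_cations[[rn]], prot$resname, prot$name),
  ]
  pcation_xyz <- as.matrix(pcations[, c("x", "y", "z")])
  ppolar <- dplyr::bind_rows(
    protein_polar_atoms(prot, "donor"), protein_polar_atoms(prot, "acceptor")
  )
  ppolar_xyz <- as.matrix(ppolar[, c("x", "y", "z")])

  lig <- list() # rows: name, element, x, y, z
  lig_xyz <- function() {
    if (!length(lig)) {
      return(matrix(numeric(0), ncol = 3))
    }
    do.call(rbind, lapply(lig, function(a) a$xyz))
  }
  n_at <- 0L
  add_atom <- function(element, xyz) {
    n_at <<- n_at + 1L
    lig[[n_at]] <<- list(name = paste0(element, n_at), element = element, xyz = xyz)
  }

  author_of <- function(canonical) {
    a <- canonical_to_author(map, canonical)
    stopifnot(!is.na(a))
    a
  }
  # Keep-out sets. Donor/acceptor fragments only need to stay clear of polar
  # protein atoms of OTHER residues (3.6 A, just beyond the 3.5 A strong-bond
  # cutoff) and of already-placed ligand atoms: an amine N near a protein
  # ring or cation cannot set any bit. Ligand rings must additionally stay
  # clear of non-target protein ring centroids (6.6 A, beyond the pi-pi edge
  # window) and of non-target protein cations (6.2 A, beyond the cation-pi
  # cutoff), or they would set pi-pi / cation-pi bits never requested.
  keep_polar <- function(exclude_resnum) {
    sel <- ppolar$resnum != exclude_resnum
    list(xyz = ppolar_xyz[sel, , drop = FALSE], min = 3.6)
  }
  keep_lig <- function() list(xyz = lig_xyz(), min = 3.0)
  # Angle-aware feasibility for a candidate ligand ring: reject placements
  # that could register pi-pi with a non-target protein ring (distance AND
  # interplanar-angle windows, with safety margins over the detector's
  # criteria) or cation-pi with a non-target protein cation.
  ring_ok <- function(centre, normal, exclude_ring = -1L, exclude_cation = -1L) {
    for (r in prings) {
      if (r$resnum == exclude_ring) next
      d <- pt_distance(centre, r$centroid)
      if (d > 7.0) next
      ang <- acos(min(1, abs(sum(.unit(normal) * r$normal)))) * 180 / pi
      if ((d <= 5.8 && ang <= 35) ||
        (d >= 4.2 && d <= 6.8 && ang >= 55 && ang <= 95)) {
        return(FALSE)
      }
    }
    for (i in seq_len(nrow(pcations))) {
      if (pcations$resnum[i] == exclude_cation) next
      p <- pcation_xyz[i, ]
      d <- pt_distance(centre, p)
      if (d > 6.3) next
      ang <- acos(min(1, abs(sum(.unit(p - centre) * .unit(normal))))) * 180 / pi
      if (ang <= 33) {
        return(FALSE)
      }
    }
    TRUE
  }

  place_donor_fragment <- function(acceptor_xyz, resnum_author) {
    d <- .pick_direction(
      acceptor_xyz,
      offsets = c(2.9, 4.35),
      avoid_xyz = rbind(prot_xyz, lig_xyz()),
      keepouts = list(keep_polar(resnum_author), keep_lig())
    )
    add_atom("N", acceptor_xyz + 2.9 * d)
    add_atom("C", acceptor_xyz + 4.35 * d)
  }
  place_acceptor_fragment <- function(donor_xyz, h_dir, resnum_author) {
    o <- donor_xyz + 3.0 * .unit(h_dir)
    add_atom("O", o)
    # two ether carbons, chosen clash-free, pointing onward from the donor
    base <- .unit(o - donor_xyz)
    e1 <- .unit(base + 0.9 * .perp_of(base))
    e2 <- .unit(base - 0.9 * .perp_of(base))
    add_atom("C", o + 1.43 * e1)
    add_atom("C", o + 1.43 * e2)
  }
  place_benzene <- function(centre, normal) {
    rc <- .ring_coords(centre, normal, 6, 1.39)
    for (k in 1:6) add_atom("C", rc[k, ])
  }

  ring_of <- function(resnum_author) {
    purrr::detect(prings, function(r) r$resnum == resnum_author)
  }
  donor_h_dir <- function(res, donor_name) {
    dx <- .named_xyz(res, donor_name)
    h <- infer_donor_h(dx, prot_xyz, prot$element)
    stopifnot(!is.null(h))
    list(donor = dx, dir = h - dx)
  }

  audit <- list()
  note <- function(bit, canonical, kind, role) {
    audit[[length(audit) + 1]] <<- tibble::tibble(
      bit = bit, canonical = canonical, kind = kind, ligand_role = role
    )
  }

  for (b in bits) {
    canonical <- bt$canonical[b]
    au <- author_of(canonical)
    res <- .res_atoms_of(protein_atoms(prot), au)
    if (b %in% c(1L, 2L, 5L, 6L)) { # ligand donor -> backbone carbonyl O
      place_donor_fragment(.named_xyz(res, "O"), au)
      note(b, canonical, "HBOND_STRONG", "HD")
    } else if (b == 7L) { # ligand donor -> E181 side-chain carboxylate
      place_donor_fragment(.named_xyz(res, "OE1"), au)
      note(b, canonical, "HBOND_STRONG", "HD")
    } else if (b == 8L) { # ligand donor -> D274 side-chain carboxylate
      place_donor_fragment(.named_xyz(res, "OD1"), au)
      note(b, canonical, "HBOND_STRONG", "HD")
    } else if (b %in% c(3L, 4L)) { # hinge backbone N-H -> ligand acceptor
      dh <- donor_h_dir(res, "N")
      place_acceptor_fragment(dh$donor, dh$dir, au)
      note(b, canonical, "HBOND_STRONG", "HA")
    } else if (b == 9L) { # H280 ring N-H -> ligand acceptor
      dh <- donor_h_dir(res, "NE2")
      place_acceptor_fragment(dh$donor, dh$dir, au)
      note(b, canonical, "HBOND_STRONG", "HA")
    } else if (b == 10L) { # K162 cation-pi with ligand aromatic
      nz <- .named_xyz(res, "NZ")
      other_prot <- prot_xyz[prot$resnum != au, , drop = FALSE]
      best <- NULL
      best_sc <- -Inf
      for (k in seq_len(nrow(.dir_candidates))) {
        dd <- .dir_candidates[k, ]
        ctr <- nz + 4.5 * dd
        rc <- .ring_coords(ctr, dd, 6, 1.39)
        clear <- min(apply(rc, 1, .min_dist_to, xyz = rbind(other_prot, lig_xyz())))
        if (clear < 2.5 || !ring_ok(ctr, dd, exclude_cation = au)) next
        if (clear > best_sc) {
          best_sc <- clear
          best <- list(ctr = ctr, normal = dd)
        }
      }
      if (is.null(best)) {
        stop("toy complex: no clash-free ring placement for bit ", b, call. = FALSE)
      }
      place_benzene(best$ctr, best$normal)
      note(b, canonical, "CATION_PI", "Ar")
    } else { # 11-14: face pi-pi onto the residue ring
      ring <- ring_of(au)
      stopifnot(!is.null(ring))
      other_prot <- prot_xyz[prot$resnum != au, , drop = FALSE]
      best <- NULL
      best_sc <- -Inf
      for (side in c(1, -1)) {
        ctr <- ring$centroid + side * 3.8 * ring$normal
        rc <- .ring_coords(ctr, ring$normal, 6, 1.39)
        clear <- min(apply(rc, 1, .min_dist_to, xyz = rbind(other_prot, lig_xyz())))
        if (clear < 2.5 || !ring_ok(ctr, ring$normal, exclude_ring = au)) next
        if (clear > best_sc) {
          best_sc <- clear
          best <- list(ctr = ctr, normal = ring$normal)
        }
      }
      if (is.null(best)) {
        stop("toy complex: no clash-free ring placement for bit ", b, call. = FALSE)
      }
      place_benzene(best$ctr, best$normal)
      note(b, canonical, "PI_PI", "Ar")
    }
  }

  if (n_at > 0) {
    lx <- lig_xyz()
    lig_tbl <- tibble::tibble(
      record = "HETATM",
      serial = max(prot$serial) + seq_len(n_at),
      name = vapply(lig, `[[`, character(1), "name"),
      resname = "LIG",
      chain = "L",
      resnum = 900L,
      inscode = "",
      x = lx[, 1], y = lx[, 2], z = lx[, 3],
      occupancy = 1,
      element = vapply(lig, `[[`, character(1), "element"),
      model = 1L,
      modified_from = NA_character_,
      is_hetero = TRUE
    )
    atoms <- dplyr::bind_rows(prot, lig_tbl)
  } else {
    atoms <- prot
  }
  poses <- extract_ligands(atoms)
  list(
    atoms = atoms,
    pose = if (nrow(poses)) poses[1, ] else NULL,
    map = map,
    audit = if (length(audit)) {
      dplyr::bind_rows(audit)
    } else {
      tibble::tibble(
        bit = integer(), canonical = integer(),
        kind = character(), ligand_role = character()
      )
    }
  )
}
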