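# Deterministic synthetic toy-kinase generator.
#
# The generator builds a minimal "kinase" out of the motif segments that the
# conformational metrics and the fingerprint need: G-loop (136-148), beta3
# strand with the catalytic lysine (158-166), alphaC helix segment (173-189),
# hinge (205-222), catalytic loop with the HRD arginine (250-260) and the
# DFG/activation segment (268-292). Author numbering equals canonical
# numbering; the sequence is the bundled reference profile restricted to those
# spans, so alignment recovers the identity mapping.
#
# Geometry is deliberately non-physical but geometrically valid: the G-loop
# backbone is grown from ideal internal coordinates (N-CA 1.46, CA-C 1.53,
# C-N 1.33 Angstrom) with prescribed phi/psi; all other residues stand alone
# with a local ideal backbone; anchor side chains are placed as compact
# clusters (aromatic residues as true planar rings) centred on designed
# points that realize each conformation class:
#   * DFG-in: Phe275 under the gatekeeper, Asp274 toward the pocket,
#     Lys162-Glu181 salt bridge intact;
#   * DFG-out: the DFG motif swapped toward the C-lobe, Asp274 and Phe275 on
#     opposite sides;
#   * DFG-out(up): Phe275 lifted between the two salt-bridge formers and
#     adjacent to Glu181, Asp274 rotated toward the polar alphaC face;
#   * alphaC-out: Glu181 rotated away from Lys162 and engaged by Arg255;
#   * folded G-loop: non-beta phi/psi in 140-145 and Phe144 displaced into
#     the ATP-site region.

.toy_segments <- list(
  gloop = 136:148,
  beta3 = 158:166,
  alphac = 173:189,
  hinge = 205:222,
  catloop = 250:260,
  aloop = 268:292
)

# pocket centre used to orient backbones and choose clash-free directions
.toy_pocket_centre <- c(5, 5, 1)

# class-independent side-chain design targets (and ring normals where the
# residue is an aromatic interaction site)
.toy_targets_common <- list(
  K162 = list(resnum = 162, target = c(0, 0, 0)),
  L210 = list(resnum = 210, target = c(5, 9, 0)),
  E211 = list(resnum = 211, target = c(8.2, 10.5, -1)),
  Y212 = list(resnum = 212, target = c(11, 11.5, 0), normal = c(0, 0, 1)),
  A213 = list(resnum = 213, target = c(14, 12.5, 1)),
  P214 = list(resnum = 214, target = c(17, 13.5, 1.5)),
  L215 = list(resnum = 215, target = c(20, 14.5, 1)),
  T217 = list(resnum = 217, target = c(26, 16.5, -0.5)),
  R220 = list(resnum = 220, target = c(35, 18.5, -2)),
  A273 = list(resnum = 273, target = c(2, -3, 1)),
  # ring normals of neighbouring aromatics are kept ~50 deg apart so that a
  # probe stacked face-on onto one ring can never satisfy the face or edge
  # pi-pi window against the other
  W277 = list(resnum = 277, target = c(-2, -7, 6), normal = c(-0.46, -0.79, 0.33)),
  H280 = list(resnum = 280, target = c(-8, -13, 8), normal = c(-0.80, -0.10, 0.60)),
  T288 = list(resnum = 288, target = c(-13, -18, 10))
)

# class-dependent targets
.toy_targets_dfg <- list(
  "in" = list(
    D274 = list(resnum = 274, target = c(4, -4, 3), orient = c(0.76, 0.45, -0.45)),
    F275 = list(resnum = 275, target = c(2.5, 3.5, 2), normal = c(0, 0, 1)),
    G276 = list(resnum = 276, ca = c(1.5, -5.5, 4.5))
  ),
  out = list(
    D274 = list(resnum = 274, target = c(-1, -4.5, 3), orient = c(-0.89, -0.45, 0.06)),
    F275 = list(resnum = 275, target = c(2, -8, -4), normal = c(0.21, -0.85, -0.43)),
    G276 = list(resnum = 276, ca = c(1.5, -6, -1.5))
  ),
  out_up = list(
    # shifted off the alphaC face far enough that a ligand donor can
    # approach the carboxylate, which points away from Glu181/Gly276
    D274 = list(resnum = 274, target = c(-4, -6.5, -2), orient = c(0.4, -0.9, 0.2)),
    # ring normal points at Lys162 so the protein cation-pi contact exists
    F275 = list(resnum = 275, target = c(-4.5, -1, 2.5), normal = c(0.859, 0.191, -0.477)),
    G276 = list(resnum = 276, ca = c(-2, -3.5, 0.5))
  )
)

.toy_targets_alphac <- list(
  "in" = list(
    E181 = list(resnum = 181, target = c(-3.5, 0, 0), orient = c(1, 0, 0)),
    R255 = list(resnum = 255, target = c(-8, -8, -6), orient = c(0, 1, 0)),
    Q177 = list(resnum = 177, target = c(-2.5, 2.5, -2)),
    Q185 = list(resnum = 185, target = c(-5.5, -2.5, 2))
  ),
  out = list(
    E181 = list(resnum = 181, target = c(-6, -2, -3), orient = c(-0.63, -0.5, -0.45)),
    R255 = list(resnum = 255, target = c(-8.5, -4, -4.8), orient = c(0.63, 0.5, 0.45)),
    Q177 = list(resnum = 177, target = c(-5, 1, -5)),
    Q185 = list(resnum = 185, target = c(-9.5, -7, 1))
  )
)

.toy_targets_gloop <- list(
  extended = list(
    F144 = list(resnum = 144, target = c(6, 18, 7), normal = c(0, 0.35, 0.94))
  ),
  folded = list(
    F144 = list(resnum = 144, target = c(3.5, 7, 3), normal = c(-0.3, -0.85, -0.43))
  )
)

# segment CA interpolation lines for FILLER residues (anchors override their
# own CA); the lines are parked outside the interaction shell so that filler
# backbones never crowd the designed side-chain clusters
.toy_segment_lines <- list(
  beta3 = list(from = c(3, -9, -8), to = c(11, -3, -8)),
  alphac = list(from = c(-14, 6, -9), to = c(-22, -2, -9)),
  hinge = list(from = c(-4, 5.5, 5.0), to = c(39, 19.5, 2.1)),
  catloop = list(from = c(-19, -13, -9), to = c(-11, -9, -9)),
  aloop = list(from = c(16, 2, -10), to = c(-8, -20, -10))
)

.unit <- function(v) v / sqrt(sum(v^2))

.perp_of <- function(v) {
  # any unit vector perpendicular to v
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(c(
    v[2] * a[3] - v[3] * a[2],
    v[3] * a[1] - v[1] * a[3],
    v[1] * a[2] - v[2] * a[1]
  ))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# side-chain heavy atoms per residue type
.sidechain_atoms <- list(
  ALA = "CB", ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"), ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"), GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"), GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"), MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"), SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.element_of_atom <- function(name) {
  g <- sub("^[0-9]*", "", name)
  two <- substr(g, 1, 2)
  if (two %in% c("SE", "CL", "BR")) two else substr(g, 1, 1)
}

# hexagonal / pentagonal planar ring centred on `centre` with given normal
.ring_coords <- function(centre, normal, n_atoms, radius) {
  n <- .unit(normal)
  e1 <- .perp_of(n)
  e2 <- .cross3(n, e1)
  ang <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
  t(vapply(ang, function(a) centre + radius * (cos(a) * e1 + sin(a) * e2), numeric(3)))
}

# even circle of k points about `centre` perpendicular to `axis`
# (centroid of the circle equals `centre` for any k >= 2)
.circle_coords <- function(centre, axis, k, radius = 0.55) {
  if (k == 0) {
    return(matrix(numeric(0), ncol = 3))
  }
  if (k == 1) {
    return(matrix(centre, ncol = 3))
  }
  .ring_coords(centre, axis, k, radius)
}

# Build the side-chain atom rows for one designed residue.
# `target` is the design point (ring centroid for aromatics, functional-group
# site for charged residues); `orient` points toward the interaction partner.
.place_sidechain <- function(resname, target, orient = c(0, 0, 1), normal = NULL) {
  atoms <- .sidechain_atoms[[resname]]
  if (length(atoms) == 0) {
    return(NULL)
  }
  v <- .unit(orient)
  w <- .perp_of(v)
  coords <- NULL
  if (resname %in% c("PHE", "TYR")) {
    ring <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    rc <- .ring_coords(target, normal %||% v, 6, 1.39)
    rownames(rc) <- ring
    extra <- list(CB = target + 2.25 * .unit(rc["CG", ] - target))
    if (resname == "TYR") extra$OH <- target + 2.75 * .unit(rc["CZ", ] - target)
    coords <- rbind(rc, do.call(rbind, extra))
  } else if (resname == "HIS") {
    ring <- c("CG", "ND1", "CE1", "NE2", "CD2")
    rc <- .ring_coords(target, normal %||% v, 5, 1.17)
    rownames(rc) <- ring
    coords <- rbind(rc, CB = target + 2.0 * .unit(rc["CG", ] - target))
  } else if (resname == "TRP") {
    ring6 <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
    rc <- .ring_coords(target, normal %||% v, 6, 1.39)
    rownames(rc) <- ring6
    mid <- (rc["CD2", ] + rc["CE2", ]) / 2
    out <- .unit(mid - target)
    five <- rbind(
      CG = rc["CD2", ] + 1.45 * out,
      NE1 = rc["CE2", ] + 1.45 * out,
      CD1 = mid + 2.3 * out
    )
    coords <- rbind(rc, five, CB = five["CG", ] + 1.5 * out)
  } else if (resname %in% c("ASP", "GLU")) {
    # carboxylate oxygens straddle the orientation axis at the design point
    tail <- setdiff(atoms, c("OE1", "OE2", "OD1", "OD2", "CG", "CD"))
    cx <- if (resname == "ASP") "CG" else "CD"
    ox <- if (resname == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
    coords <- rbind(
      matrix(target - 0.4 * v, ncol = 3, dimnames = list(cx)),
      matrix(target + 0.6 * v + 1.1 * w, ncol = 3, dimnames = list(ox[1])),
      matrix(target + 0.6 * v - 1.1 * w, ncol = 3, dimnames = list(ox[2])),
      {
        m <- .circle_coords(target - 1.2 * v, v, length(tail))
        rownames(m) <- tail
        m
      }
    )
  } else if (resname == "LYS") {
    coords <- rbind(
      matrix(target + 0.5 * v, ncol = 3, dimnames = list("NZ")),
      {
        m <- .circle_coords(target - 0.5 * v, v, 4)
        rownames(m) <- c("CB", "CG", "CD", "CE")
        m
      }
    )
  } else if (resname == "ARG") {
    coords <- rbind(
      matrix(target, ncol = 3, dimnames = list("CZ")),
      matrix(target + 0.5 * v + 1.0 * w, ncol = 3, dimnames = list("NH1")),
      matrix(target + 0.5 * v - 1.0 * w, ncol = 3, dimnames = list("NH2")),
      matrix(target - 1.1 * v, ncol = 3, dimnames = list("NE")),
      {
        m <- .circle_coords(target - 2.0 * v, v, 3)
        rownames(m) <- c("CB", "CG", "CD")
        m
      }
    )
  } else if (resname %in% c("SER", "THR")) {
    og <- if (resname == "SER") "OG" else "OG1"
    rest <- setdiff(atoms, og)
    coords <- rbind(
      matrix(target + 0.4 * v, ncol = 3, dimnames = list(og)),
      {
        m <- .circle_coords(target - 0.4 * v, v, length(rest))
        rownames(m) <- rest
        m
      }
    )
  } else if (resname %in% c("ASN", "GLN")) {
    ox <- if (resname == "ASN") "OD1" else "OE1"
    nx <- if (resname == "ASN") "ND2" else "NE2"
    rest <- setdiff(atoms, c(ox, nx))
    coords <- rbind(
      matrix(target + 0.5 * v + 0.9 * w, ncol = 3, dimnames = list(ox)),
      matrix(target + 0.5 * v - 0.9 * w, ncol = 3, dimnames = list(nx)),
      {
        m <- .circle_coords(target - 0.7 * v, v, length(rest))
        rownames(m) <- rest
        m
      }
    )
  } else {
    m <- .circle_coords(target, v, length(atoms), radius = 0.6)
    rownames(m) <- atoms
    coords <- m
  }
  coords
}

# local ideal backbone around a CA given chain direction u and "out" w
.local_backbone <- function(ca, u, w) {
  u <- .unit(u)
  w <- .unit(w - sum(w * u) * u)
  n <- ca + 0.4 * u + 1.40 * w
  cc <- ca + 1.53 * u
  o <- cc + 1.23 * w
  rbind(N = n, CA = ca, C = cc, O = o)
}

# grow a peptide backbone by NeRF from prescribed phi/psi (degrees)
.nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  bc <- .unit(c - b)
  nrm <- .unit(.cross3(b - a, bc))
  m2 <- .cross3(nrm, bc)
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * nrm
}

.build_gloop_backbone <- function(phi, psi) {
  nres <- length(phi)
  N <- matrix(NA_real_, nres, 3)
  CA <- matrix(NA_real_, nres, 3)
  C <- matrix(NA_real_, nres, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.46, 0, 0)
  C[1, ] <- CA[1, ] + 1.53 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  for (i in 2:nres) {
    N[i, ] <- .nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.33, 116.2, psi[i - 1])
    CA[i, ] <- .nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], 1.46, 121.7, 180)
    C[i, ] <- .nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.53, 111.0, phi[i])
  }
  O <- matrix(NA_real_, nres, 3)
  for (i in seq_len(nres)) {
    ref <- if (i < nres) N[i + 1, ] else CA[i, ]
    d <- .cross3(C[i, ] - CA[i, ], ref - CA[i, ])
    if (sqrt(sum(d^2)) < 1e-6) d <- c(0, 0, 1)
    O[i, ] <- C[i, ] + 1.23 * .unit(d)
  }
  list(N = N, CA = CA, C = C, O = O)
}

.toy_profile_aa <- function() {
  prof <- reference_profile()
  stats::setNames(prof$aa, prof$position)
}

.aa1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# assemble one residue's atom rows into the read_pdb() tibble schema
.res_rows <- function(resnum, resname, coords, hetero = FALSE, chain = "A") {
  nm <- rownames(coords)
  tibble::tibble(
    record = if (hetero) "HETATM" else "ATOM",
    serial = NA_integer_,
    name = nm,
    resname = resname,
    chain = chain,
    resnum = as.integer(resnum),
    inscode = "",
    x = unname(coords[, 1]), y = unname(coords[, 2]), z = unname(coords[, 3]),
    occupancy = 1,
    element = vapply(nm, .element_of_atom, character(1)),
    model = 1L,
    modified_from = NA_character_,
    is_hetero = hetero
  )
}

#' Generate a synthetic toy kinase in a prescribed conformation
#'
#' Builds a minimal kinase structure whose motif geometry realizes the
#' requested DFG-loop, alphaC-helix and G-loop labels, such that the
#' conformational metrics recover the generating labels (exactly at
#' `noise_sigma = 0`, with high probability at 0.3 Angstrom). Deterministic
#' for a fixed seed.
#'
#' @param dfg `"in"`, `"out"` or `"out_up"`.
#' @param alpha_c `"in"`, `"out"`, or `NULL` for the canonical pairing
#'   (in for DFG-in, out otherwise).
#' @param g_loop `"extended"` or `"folded"`.
#' @param noise_sigma Standard deviation of i.i.d. Gaussian coordinate noise
#'   in Angstrom (default 0).
#' @param seed Integer seed for the noise.
#' @return Atom tibble in the [read_pdb()] schema (chain "A").
#' @export
make_toy_kinase <- function(dfg = c("in", "out", "out_up"),
                            alpha_c = NULL,
                            g_loop = c("extended", "folded"),
                            noise_sigma = 0, seed = 1L) {
  dfg <- match.arg(dfg)
  g_loop <- match.arg(g_loop)
  if (is.null(alpha_c)) alpha_c <- if (dfg == "in") "in" else "out"
  alpha_c <- match.arg(alpha_c, c("in", "out"))
  stopifnot(noise_sigma >= 0)
  aa <- .toy_profile_aa()
  pc <- .toy_pocket_centre

  designs <- c(
    .toy_targets_common,
    .toy_targets_dfg[[dfg]],
    .toy_targets_alphac[[alpha_c]],
    .toy_targets_gloop[[g_loop]]
  )
  design_of <- stats::setNames(
    designs,
    vapply(designs, function(d) as.character(d$resnum), character(1))
  )
  # orientation of functional groups: K162 points at its partner
  k_partner <- if (dfg == "in" && alpha_c == "in") {
    .toy_targets_alphac[["in"]]$E181$target
  } else {
    .toy_targets_dfg[[dfg]]$F275$target
  }
  design_of[["162"]]$orient <- k_partner - design_of[["162"]]$target
  # E181 carboxylate points at K162 (in) or R255 (out)
  e_partner <- if (alpha_c == "in") c(0, 0, 0) else design_of[["255"]]$target
  design_of[["181"]]$orient <- e_partner - design_of[["181"]]$target
  design_of[["255"]]$orient <- design_of[["181"]]$target - design_of[["255"]]$target

  res_list <- list()
  add_res <- function(rows) res_list[[length(res_list) + 1]] <<- rows

  # --- G-loop: connected backbone with prescribed dihedrals ---
  gl <- .toy_segments$gloop
  phi <- rep(-140, length(gl))
  psi <- rep(135, length(gl))
  if (g_loop == "folded") {
    fold <- gl >= 140 & gl <= 145
    phi[fold] <- -60
    psi[fold] <- -40
  }
  bb <- .build_gloop_backbone(phi, psi)
  i144 <- match(144, gl)
  offset <- c(6, 16, 4) - bb$CA[i144, ]
  for (i in seq_along(gl)) {
    rn <- gl[i]
    r3 <- .aa1to3[[aa[[as.character(rn)]]]]
    coords <- rbind(
      N = bb$N[i, ] + offset, CA = bb$CA[i, ] + offset,
      C = bb$C[i, ] + offset, O = bb$O[i, ] + offset
    )
    if (rn == 144) {
      d <- design_of[["144"]]
      sc <- .place_sidechain("PHE", d$target,
        orient = d$normal, normal = d$normal
      )
      coords <- rbind(coords, sc)
    } else if (r3 != "GLY") {
      coords <- rbind(coords, CB = bb$CA[i, ] + offset + c(0, 0, 1.5))
    }
    add_res(.res_rows(rn, r3, coords))
  }

  # --- standalone segments ---
  for (seg in setdiff(names(.toy_segments), "gloop")) {
    rng <- .toy_segments[[seg]]
    line <- .toy_segment_lines[[seg]]
    u_seg <- .unit(line$to - line$from)
    for (i in seq_along(rng)) {
      rn <- rng[i]
      r3 <- .aa1to3[[aa[[as.character(rn)]]]]
      d <- design_of[[as.character(rn)]]
      frac <- (i - 1) / max(1, length(rng) - 1)
      ca <- if (!is.null(d$ca)) {
        d$ca
      } else if (!is.null(d$target)) {
        d$target + 1.8 * c(0, 0, 1)
      } else {
        line$from + frac * (line$to - line$from)
      }
      w <- .unit(pc - ca)
      coords <- .local_backbone(ca, u_seg, w)
      if (!is.null(d$target) && r3 != "GLY") {
        sc <- .place_sidechain(r3, d$target,
          orient = d$orient %||% c(0, 0, 1), normal = d$normal
        )
        coords <- rbind(coords, sc)
      } else if (r3 != "GLY" && is.null(d$ca)) {
        coords <- rbind(coords, CB = ca + c(0, 0, 1.5))
      }
      add_res(.res_rows(rn, r3, coords))
    }
  }

  atoms <- dplyr::bind_rows(res_list)
  atoms <- atoms[order(atoms$resnum), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, noise_sigma)
    atoms$y <- atoms$y + stats::rnorm(n, 0, noise_sigma)
    atoms$z <- atoms$z + stats::rnorm(n, 0, noise_sigma)
  }
  attr(atoms, "fixture_labels") <- list(dfg = dfg, alpha_c = alpha_c, g_loop = g_loop)
  atoms
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
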