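# Geometric primitives: centres of mass, distances, angles, backbone dihedrals.
# All coordinates are in Angstrom, all angles in degrees.

# Monoisotopic-ish atomic masses for the elements that occur in protein heavy
# atoms and typical organic ligands. Unknown elements fall back to 12.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904,
  I = 126.904, B = 10.81
)

atomic_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
#' @examples
#' pt_distance(c(0, 0, 0), c(3, 0, 0))
pt_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Angle at a vertex
#'
#' Angle, in degrees, between the vectors `v -> a` and `v -> b`.
#'
#' @param a,v,b Numeric 3-vectors; `v` is the vertex.
#' @return Angle in degrees, in \[0, 180\].
#' @export
#' @examples
#' pt_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
pt_angle <- function(a, v, b) {
  u <- a - v
  w <- b - v
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (nu < 1e-9 || nw < 1e-9) {
    stop("angle undefined: zero-length arm at vertex", call. = FALSE)
  }
  cosang <- sum(u * w) / (nu * nw)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Torsion (dihedral) angle over four points
#'
#' IUPAC sign convention; result in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Dihedral angle in degrees.
#' @export
pt_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(c(
    n1[2] * n2[3] - n1[3] * n2[2],
    n1[3] * n2[1] - n1[1] * n2[3],
    n1[1] * n2[2] - n1[2] * n2[1]
  ) * b2) / m1
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Backbone atom names never part of a side chain.
.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Centre-of-mass specification
#'
#' Controls which atoms of a residue enter the centre-of-mass and how they are
#' weighted. The default (side-chain heavy atoms, mass weighting) is the
#' measure that discriminates kinase conformations best; glycine, which has no
#' side chain, falls back to its alpha carbon.
#'
#' @param selection One of `"sidechain"`, `"heavy"` (all heavy atoms) or
#'   `"ca"` (alpha carbon only).
#' @param weighting `"mass"` or `"unit"`.
#' @return An object of class `com_spec`.
#' @export
com_spec <- function(selection = c("sidechain", "heavy", "ca"),
                     weighting = c("mass", "unit")) {
  structure(
    list(
      selection = match.arg(selection),
      weighting = match.arg(weighting)
    ),
    class = "com_spec"
  )
}

#' Centre of mass of one residue
#'
#' @param res Atom tibble for a single residue (see [read_pdb()]).
#' @param spec A [com_spec()].
#' @return Numeric 3-vector.
#' @export
residue_com <- function(res, spec = com_spec()) {
  stopifnot(inherits(spec, "com_spec"), nrow(res) > 0)
  res <- res[toupper(res$element) != "H", , drop = FALSE]
  sel <- switch(spec$selection,
    sidechain = res[!(res$name %in% .backbone_names), , drop = FALSE],
    heavy = res,
    ca = res[res$name == "CA", , drop = FALSE]
  )
  # Gly (and any residue stripped to backbone) falls back to the alpha carbon
  if (spec$selection == "sidechain" && nrow(sel) == 0) {
    sel <- res[res$name == "CA", , drop = FALSE]
  }
  if (nrow(sel) == 0) {
    stop("residue_com: empty atom selection for residue ",
      unique(res$resname)[1], " ", unique(res$resnum)[1],
      call. = FALSE
    )
  }
  w <- if (spec$weighting == "mass") atomic_mass(sel$element) else rep(1, nrow(sel))
  c(
    sum(w * sel$x), sum(w * sel$y), sum(w * sel$z)
  ) / sum(w)
}

# Coordinates of one named atom in a residue tibble; error if absent.
atom_xyz <- function(res, name) {
  i <- which(res$name == name)
  if (length(i) == 0) {
    stop("missing backbone atom ", name, " in residue ",
      unique(res$resname)[1], " ", unique(res$resnum)[1],
      call. = FALSE
    )
  }
  c(res$x[i[1]], res$y[i[1]], res$z[i[1]])
}

#' Backbone phi/psi dihedrals of one residue
#'
#' Standard IUPAC phi (C\[i-1\]-N-CA-C) and psi (N-CA-C-N\[i+1\]) angles.
#' Requires the flanking residues to be present in `atoms` (consecutive
#' author numbering within the chain).
#'
#' @param atoms Atom tibble.
#' @param chain Chain identifier.
#' @param resnum Author residue number of the central residue.
#' @return Named numeric vector `c(phi = , psi = )` in degrees.
#' @export
backbone_dihedrals <- function(atoms, chain, resnum) {
  get_res <- function(n) {
    r <- atoms[!atoms$is_hetero & atoms$chain == chain & atoms$resnum == n, , drop = FALSE]
    if (nrow(r) == 0) {
      stop("backbone_dihedrals: residue ", n, " absent in chain ", chain,
        call. = FALSE
      )
    }
    r
  }
  rm1 <- get_res(resnum - 1)
  r0 <- get_res(resnum)
  rp1 <- get_res(resnum + 1)
  phi <- pt_dihedral(
    atom_xyz(rm1, "C"), atom_xyz(r0, "N"), atom_xyz(r0, "CA"), atom_xyz(r0, "C")
  )
  psi <- pt_dihedral(
    atom_xyz(r0, "N"), atom_xyz(r0, "CA"), atom_xyz(r0, "C"), atom_xyz(rp1, "N")
  )
  c(phi = phi, psi = psi)
}

# Smallest absolute difference between two angles on the circle, degrees.
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# --- small rigid-motion helpers (used by the fixture generator and tests) ---

# Rotation matrix from unit axis and angle in degrees (Rodrigues).
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(
    0, -a[3], a[2],
    a[3], 0, -a[1],
    -a[2], a[1], 0
  ), nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid-body transform to all atom coordinates
#'
#' @param atoms Atom tibble.
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric 3-vector.
#' @return Atom tibble with transformed coordinates.
#' @export
transform_atoms <- function(atoms, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- t(rotation %*% t(as.matrix(atoms[, c("x", "y", "z")])))
  atoms$x <- xyz[, 1] + translation[1]
  atoms$y <- xyz[, 2] + translation[2]
  atoms$z <- xyz[, 3] + translation[3]
  atoms
}
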