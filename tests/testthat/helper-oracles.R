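# Independent brute-force oracles. These deliberately re-derive every
# quantity with the most literal formulation possible (explicit loops,
# textbook formulas) so they share no code path with the package internals.

oracle_dist <- function(a, b) {
  s <- 0
  for (k in 1:3) s <- s + (a[k] - b[k])^2
  sqrt(s)
}

oracle_angle <- function(a, v, b) {
  u <- a - v
  w <- b - v
  acos(max(-1, min(1, sum(u * w) / (sqrt(sum(u^2)) * sqrt(sum(w^2)))))) * 180 / pi
}

oracle_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- oracle_cross(b1, b2)
  n2 <- oracle_cross(b2, b3)
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (sum(oracle_cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# mass table duplicated on purpose (subset sufficient for fixtures)
oracle_mass <- function(el) {
  switch(toupper(el),
    C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    SE = 78.971, H = 1.008, 12.011
  )
}

oracle_com <- function(res, selection = "sidechain", weighting = "mass") {
  bb <- c("N", "CA", "C", "O", "OXT")
  rows <- switch(selection,
    sidechain = which(!(res$name %in% bb)),
    heavy = seq_len(nrow(res)),
    ca = which(res$name == "CA")
  )
  if (selection == "sidechain" && length(rows) == 0) rows <- which(res$name == "CA")
  num <- c(0, 0, 0)
  den <- 0
  for (i in rows) {
    w <- if (weighting == "mass") oracle_mass(res$element[i]) else 1
    num <- num + w * c(res$x[i], res$y[i], res$z[i])
    den <- den + w
  }
  num / den
}

# ring centroid/normal by least squares, independent of svd order convention
oracle_ring_geom <- function(xyz) {
  ctr <- colMeans(xyz)
  m <- sweep(xyz, 2, ctr)
  ev <- eigen(t(m) %*% m)
  list(centroid = ctr, normal = ev$vectors[, 3])
}

# --- exhaustive interaction oracle -----------------------------------------
# Re-derives every detector by scanning all relevant pairs with explicit
# loops; criteria values are written out literally.

oracle_protein_ring_defs <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
)

oracle_xyz <- function(tab, i) c(tab$x[i], tab$y[i], tab$z[i])

# strong H-bond oracle between explicit donor/acceptor atom sets; the caller
# supplies the inferred-H positions (or NA for distance-only donors)
oracle_count_pipi <- function(prot, pose_atoms, pose_rings) {
  hits <- 0
  arom <- prot[prot$resname %in% names(oracle_protein_ring_defs), ]
  for (key in unique(paste(arom$chain, arom$resnum))) {
    res <- arom[paste(arom$chain, arom$resnum) == key, ]
    need <- oracle_protein_ring_defs[[res$resname[1]]]
    if (!all(need %in% res$name)) next
    pg <- oracle_ring_geom(as.matrix(res[match(need, res$name), c("x", "y", "z")]))
    for (ridx in pose_rings) {
      lg <- oracle_ring_geom(as.matrix(pose_atoms[ridx, c("x", "y", "z")]))
      d <- oracle_dist(pg$centroid, lg$centroid)
      ang <- acos(min(1, abs(sum(pg$normal * lg$normal)))) * 180 / pi
      if ((d <= 5.5 && ang <= 30) || (d >= 4.5 && d <= 6.5 && ang >= 60 && ang <= 90)) {
        hits <- hits + 1
      }
    }
  }
  hits
}

oracle_count_cation_pi <- function(cation_xyz_list, ring_geoms) {
  hits <- 0
  for (cx in cation_xyz_list) {
    for (rg in ring_geoms) {
      d <- oracle_dist(cx, rg$centroid)
      if (d > 6.0) next
      v <- (cx - rg$centroid) / d
      ang <- acos(min(1, abs(sum(v * rg$normal)))) * 180 / pi
      if (ang <= 30) hits <- hits + 1
    }
  }
  hits
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  kinconf:::rotation_matrix(axis, stats::runif(1, 0, 360))
}
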