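# Ligand extraction and pharmacophore-style feature typing.
#
# Features are assigned from heavy-atom geometry alone (crystal structures
# rarely carry hydrogens): bonds are inferred from interatomic distances,
# aromatic rings from planar 5/6-cycles, charged groups from carboxylate /
# amine / guanidinium patterns. The rules are deliberately simple and are
# documented in the methods vignette; they are not a cheminformatics engine.

.covalent_radii <- c(
  C = 0.77, N = 0.70, O = 0.66, S = 1.04, P = 1.10, F = 0.64,
  CL = 0.99, BR = 1.14, I = 1.33, SE = 1.17, B = 0.84, H = 0.31
)

# Bond inference: pairs closer than sum of covalent radii + 0.45 A.
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) {
    return(matrix(integer(0), ncol = 2))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- .covalent_radii[toupper(atoms$element)]
  r[is.na(r)] <- 0.77
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") + 0.45
  idx <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  idx[d[idx] > 0.4, , drop = FALSE] # guard against duplicated atoms
}

# All simple cycles of length 5 or 6 that are planar (RMS out-of-plane
# deviation < 0.15 A) and contain only C/N/O/S. Returns list of index vectors.
find_planar_rings <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (n < 5 || nrow(bonds) == 0) {
    return(list())
  }
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]
    j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  rings <- list()
  seen <- character()
  # DFS for cycles up to length 6 starting at each atom
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < 6 && nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  ok_el <- toupper(atoms$element) %in% c("C", "N", "O", "S")
  keep <- vapply(rings, function(rg) {
    if (!all(ok_el[rg])) {
      return(FALSE)
    }
    xyz <- as.matrix(atoms[rg, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2, ctr))
    # smallest singular value measures out-of-plane spread
    sqrt(sv$d[3]^2 / nrow(xyz)) < 0.15
  }, logical(1))
  rings[keep]
}

ring_geometry <- function(atoms, ring) {
  xyz <- as.matrix(atoms[ring, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

# Feature typing of one ligand's atoms. Returns a tibble:
# feature in {HD, HA, Ar, Cation, Anion, Hydrophobe}, atom indices (list-col).
type_ligand_features <- function(lig) {
  bonds <- infer_bonds(lig)
  nb <- vector("list", nrow(lig))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]
    j <- bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  deg <- lengths(nb)
  el <- toupper(lig$element)
  rings <- find_planar_rings(lig, bonds)
  in_ring <- rep(FALSE, nrow(lig))
  for (rg in rings) in_ring[rg] <- TRUE

  feats <- list()
  add <- function(feature, idx) {
    if (length(idx)) {
      feats[[length(feats) + 1]] <<- tibble::tibble(
        feature = feature, atoms = list(as.integer(idx))
      )
    }
  }
  # carboxylate: C bonded to two terminal oxygens -> both O are anionic
  anion_o <- integer()
  for (i in which(el == "C")) {
    os <- nb[[i]][el[nb[[i]]] == "O" & deg[nb[[i]]] == 1]
    if (length(os) >= 2) anion_o <- c(anion_o, os)
  }
  # phosphate/sulfate terminal oxygens
  for (i in which(el %in% c("P", "S"))) {
    os <- nb[[i]][el[nb[[i]]] == "O" & deg[nb[[i]]] == 1]
    if (length(os) >= 2) anion_o <- c(anion_o, os)
  }
  anion_o <- unique(anion_o)
  if (length(anion_o)) add("Anion", anion_o)

  # amine/guanidinium nitrogens: N with <= 1 heavy neighbour, or N in a
  # C(N)(N)N guanidinium pattern -> cationic, H-bond donor
  cation_n <- which(el == "N" & deg <= 1 & !in_ring)
  for (i in which(el == "C" & !in_ring)) {
    ns <- nb[[i]][el[nb[[i]]] == "N"]
    if (length(ns) >= 3) cation_n <- c(cation_n, ns)
  }
  cation_n <- unique(cation_n)
  if (length(cation_n)) add("Cation", cation_n)

  # donors: any N with spare valence (deg < 3), hydroxyl-like O (terminal O
  # not classed as anion)
  don <- unique(c(
    which(el == "N" & deg < 3),
    setdiff(which(el == "O" & deg <= 1), anion_o)
  ))
  # a terminal O on a C that also carries another terminal O is carboxylate
  if (length(don)) add("HD", don)

  # acceptors: all N and O except cationic N
  acc <- setdiff(which(el %in% c("N", "O")), cation_n)
  if (length(acc)) add("HA", acc)

  # aromatic rings (one feature per ring)
  for (rg in rings) add("Ar", rg)

  # hydrophobes: carbons without N/O neighbours
  hyd <- which(el == "C" & vapply(
    seq_along(nb),
    function(i) !any(el[nb[[i]]] %in% c("N", "O")), logical(1)
  ))
  if (length(hyd)) add("Hydrophobe", hyd)

  if (!length(feats)) {
    return(tibble::tibble(feature = character(), atoms = list()))
  }
  dplyr::bind_rows(feats)
}

#' Extract ligand poses from a structure
#'
#' One pose per HET residue (identified by chain/number/name) whose code is
#' not excluded. Each pose carries its atom table and typed pharmacophore
#' features (H-bond donors HD, acceptors HA, aromatic rings Ar, charged
#' groups Cation/Anion, hydrophobic carbons).
#'
#' @param atoms Atom tibble from [read_pdb()].
#' @param exclude HET codes to skip (default waters/ions/additives).
#' @return Tibble with one row per pose: `ligand_id`, `resname`, `chain`,
#'   `resnum`, `n_atoms`, `atoms` (list of atom tibbles), `features`
#'   (list of feature tibbles).
#' @export
extract_ligands <- function(atoms, exclude = default_het_exclude) {
  lig <- ligand_atoms(atoms, exclude)
  if (nrow(lig) == 0) {
    return(tibble::tibble(
      ligand_id = character(), resname = character(), chain = character(),
      resnum = integer(), n_atoms = integer(), atoms = list(), features = list()
    ))
  }
  key <- paste(lig$chain, lig$resnum, lig$resname, sep = ":")
  groups <- split(seq_len(nrow(lig)), key)
  out <- purrr::map(names(groups), function(k) {
    g <- lig[groups[[k]], , drop = FALSE]
    tibble::tibble(
      ligand_id = k,
      resname = g$resname[1],
      chain = g$chain[1],
      resnum = g$resnum[1],
      n_atoms = nrow(g),
      atoms = list(g),
      features = list(type_ligand_features(g))
    )
  })
  dplyr::bind_rows(out)
}
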