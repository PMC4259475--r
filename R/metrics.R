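# Inter- and intra-motif conformational metrics.
#
# Both metrics are vectors of pairwise side-chain centre-of-mass distances and
# angles over key motif residues. The inter-motif metric spans the catalytic
# lysine (K162), the alphaC glutamate (E181), the gatekeeper (GK, canonical
# 210) and the DFG phenylalanine (F275); the intra-motif metric measures the
# spread of the DFG motif and the adjoining activation loop (A273..G276,
# W277, H280, T288).

# side-chain COM of the residue mapped to a canonical anchor position
anchor_com <- function(atoms, map, canonical, spec = com_spec(), label = NULL) {
  author <- canonical_to_author(map, canonical)
  lab <- label %||% as.character(canonical)
  if (is.na(author)) {
    stop("missing anchor: canonical position ", lab, " not aligned", call. = FALSE)
  }
  res <- atoms[!atoms$is_hetero & atoms$resnum == author, , drop = FALSE]
  if (nrow(res) == 0) {
    stop("missing anchor: residue ", author, " (", lab, ") has no atoms", call. = FALSE)
  }
  residue_com(res, spec)
}

#' Inter-motif conformational metric
#'
#' Distances r2(GK..E181), r3(GK..F275), r4(K162..F275), r5(E181..F275,
#' diagnostic), r6(K162..E181) and angles K-(GK+2)-E, K-(GK+2)-F, E-(GK)-F
#' between side-chain centres of mass. All distances in Angstrom, angles in
#' degrees.
#'
#' @param atoms Atom tibble.
#' @param map A `residue_map`.
#' @param spec A [com_spec()].
#' @return One-row tibble with eight `inter_*` columns.
#' @export
inter_motif_metric <- function(atoms, map, spec = com_spec()) {
  K <- anchor_com(atoms, map, 162, spec, "K162")
  E <- anchor_com(atoms, map, 181, spec, "E181")
  GK <- anchor_com(atoms, map, 210, spec, "GK")
  GK2 <- anchor_com(atoms, map, 212, spec, "GK+2")
  F275 <- anchor_com(atoms, map, 275, spec, "F275")
  tibble::tibble(
    inter_r2_gk_e181 = pt_distance(GK, E),
    inter_r3_gk_f275 = pt_distance(GK, F275),
    inter_r4_k162_f275 = pt_distance(K, F275),
    inter_r5_e181_f275 = pt_distance(E, F275),
    inter_r6_k162_e181 = pt_distance(K, E),
    inter_ang_k_gk2_e = pt_angle(K, GK2, E),
    inter_ang_k_gk2_f = pt_angle(K, GK2, F275),
    inter_ang_e_gk_f = pt_angle(E, GK, F275)
  )
}

#' Intra-motif (DFG / activation-loop) conformational metric
#'
#' Distances r1(A273..D274), r2(D274..F275), r3(F275..G276), r4(D274..G276),
#' r5(F275..W277), r6(F275..T288) and angles DFG (vertex F275),
#' FWH and FWT (vertex W277) between side-chain centres of mass
#' (glycine falls back to its alpha carbon).
#'
#' @inheritParams inter_motif_metric
#' @return One-row tibble with nine `intra_*` columns.
#' @export
intra_motif_metric <- function(atoms, map, spec = com_spec()) {
  A <- anchor_com(atoms, map, 273, spec, "A273")
  D <- anchor_com(atoms, map, 274, spec, "D274")
  F275 <- anchor_com(atoms, map, 275, spec, "F275")
  G <- anchor_com(atoms, map, 276, spec, "G276")
  W <- anchor_com(atoms, map, 277, spec, "W277")
  H <- anchor_com(atoms, map, 280, spec, "H280")
  T288 <- anchor_com(atoms, map, 288, spec, "T288")
  tibble::tibble(
    intra_r1_a273_d274 = pt_distance(A, D),
    intra_r2_d274_f275 = pt_distance(D, F275),
    intra_r3_f275_g276 = pt_distance(F275, G),
    intra_r4_d274_g276 = pt_distance(D, G),
    intra_r5_f275_w277 = pt_distance(F275, W),
    intra_r6_f275_t288 = pt_distance(F275, T288),
    intra_ang_dfg = pt_angle(D, F275, G),
    intra_ang_fwh = pt_angle(F275, W, H),
    intra_ang_fwt = pt_angle(F275, W, T288)
  )
}

# discriminative parameter subsets (fixed)
.discriminative_inter <- c(
  "inter_r2_gk_e181", "inter_r3_gk_f275", "inter_r4_k162_f275",
  "inter_r6_k162_e181", "inter_ang_e_gk_f"
)
.discriminative_intra <- c(
  "intra_r5_f275_w277", "intra_r6_f275_t288", "intra_ang_dfg", "intra_ang_fwh"
)
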