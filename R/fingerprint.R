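# 14-bit structure interaction fingerprint.
#
# Each bit encodes one residue-specific interaction between the kinase
# binding site and the ligand. HD/HA name the LIGAND pharmacophore role
# (donor/acceptor); the residue side is fixed by the bit definition. Bit 4 is
# the hinge amide donating to a ligand acceptor (the "HD" printed in the
# source table is corrected to the ligand-acceptor role, consistent with the
# hinge chemistry); bit 11 is the DFG phenylalanine in canonical numbering
# (F275). Only strong H-bonds set the H-bond bits.

#' The 14-bit fingerprint definition
#'
#' @return Tibble: `bit`, `canonical`, `residue`, `kind`, `ligand_role`,
#'   `label`.
#' @export
sift_bit_table <- function() {
  tibble::tribble(
    ~bit, ~canonical, ~residue, ~kind, ~ligand_role, ~label,
    1L, 210L, "L210", "HBOND_STRONG", "HD", "GK L210 H-bond (ligand donor)",
    2L, 211L, "E211", "HBOND_STRONG", "HD", "GK+1 E211 H-bond (ligand donor)",
    3L, 212L, "Y212", "HBOND_STRONG", "HA", "GK+2 Y212 H-bond (ligand acceptor)",
    4L, 213L, "A213", "HBOND_STRONG", "HA", "GK+3 A213 hinge H-bond (ligand acceptor)",
    5L, 216L, "G216", "HBOND_STRONG", "HD", "GK+6 G216 H-bond (ligand donor)",
    6L, 273L, "A273", "HBOND_STRONG", "HD", "A273 H-bond (ligand donor)",
    7L, 181L, "E181", "HBOND_STRONG", "HD", "alphaC E181 H-bond (ligand donor)",
    8L, 274L, "D274", "HBOND_STRONG", "HD", "D274 side-chain H-bond (ligand donor)",
    9L, 280L, "H280", "HBOND_STRONG", "HA", "H280 H-bond (ligand acceptor)",
    10L, 162L, "K162", "CATION_PI", "Ar", "K162 cation-pi (ligand aromatic)",
    11L, 275L, "F275", "PI_PI", "Ar", "DFG F275 pi-pi",
    12L, 277L, "W277", "PI_PI", "Ar", "A-loop W277 pi-pi",
    13L, 280L, "H280", "PI_PI", "Ar", "A-loop H280 pi-pi",
    14L, 144L, "F144", "PI_PI", "Ar", "G-loop F144 pi-pi"
  )
}

#' Compute the 14-bit interaction fingerprint
#'
#' Bit b is set iff at least one record of the interaction table matches bit
#' b's canonical residue, interaction kind and ligand feature role. Records
#' that match no bit are ignored; duplicates are idempotent.
#'
#' @param table Record tibble from [interaction_table()] (must carry
#'   `canonical` labels).
#' @return A `kinconf_sift` object (named 0/1 integer vector of length 14).
#' @export
compute_sift <- function(table) {
  stopifnot("canonical" %in% names(table))
  bt <- sift_bit_table()
  bits <- integer(14)
  lig <- table[table$partner_type %in% "ligand", , drop = FALSE]
  for (i in seq_len(nrow(bt))) {
    hit <- lig$canonical %in% bt$canonical[i] &
      lig$kind == bt$kind[i] &
      (lig$ligand_role %in% bt$ligand_role[i])
    if (bt$kind[i] == "CATION_PI") {
      hit <- hit & lig$subtype == "protein-cation"
    }
    bits[i] <- as.integer(any(hit, na.rm = TRUE))
  }
  names(bits) <- bt$residue
  structure(bits, class = "kinconf_sift")
}

#' @export
print.kinconf_sift <- function(x, ...) {
  cat("SIFt:", sift_string(x), "\n")
  set <- which(unclass(x) == 1L)
  if (length(set)) {
    bt <- sift_bit_table()
    for (i in set) cat(sprintf("  bit %2d  %s\n", i, bt$label[i]))
  }
  invisible(x)
}

#' Fingerprint as a 14-character 0/1 string
#' @param fp A `kinconf_sift`.
#' @return Character scalar.
#' @export
sift_string <- function(fp) paste(unclass(fp), collapse = "")

#' Fingerprint as a labelled tibble
#' @param x A `kinconf_sift`.
#' @param ... Unused.
#' @return Tibble: `bit`, `residue`, `label`, `set`.
#' @method tidy kinconf_sift
#' @export
tidy.kinconf_sift <- function(x, ...) {
  bt <- sift_bit_table()
  bt$set <- unclass(x) == 1L
  bt[, c("bit", "residue", "label", "set")]
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of set bits; 1 when both fingerprints are empty.
#'
#' @param a,b `kinconf_sift` objects (or 0/1 vectors of length 14).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(unclass(a))
  b <- as.integer(unclass(b))
  stopifnot(length(a) == 14, length(b) == 14)
  u <- sum(a | b)
  if (u == 0) {
    return(1.0)
  }
  sum(a & b) / u
}

#' Per-bit frequency profile over a set of fingerprints
#'
#' @param fps List of `kinconf_sift` objects.
#' @return A `kinconf_sift_profile` tibble: `bit`, `residue`, `label`,
#'   `frequency_pct`.
#' @export
frequency_profile <- function(fps) {
  stopifnot(length(fps) > 0)
  m <- do.call(rbind, lapply(fps, function(f) as.integer(unclass(f))))
  bt <- sift_bit_table()
  out <- tibble::tibble(
    bit = bt$bit, residue = bt$residue, label = bt$label,
    frequency_pct = 100 * colMeans(m)
  )
  class(out) <- c("kinconf_sift_profile", class(out))
  out
}

#' Bar chart of an interaction frequency profile
#'
#' @param object A `kinconf_sift_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinconf_sift_profile
#' @export
autoplot.kinconf_sift_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = stats::reorder(paste0(.data$bit, ": ", .data$residue), .data$bit),
      y = .data$frequency_pct
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "fingerprint bit", y = "frequency (%)",
      title = "Interaction frequency profile"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
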