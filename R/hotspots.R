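# Binding-site sub-pockets and specificity hot-spots.
#
# The kinase active site is partitioned into six sub-pockets: adenine (AP),
# back (BP, also called HPI), ribose (RP), phosphate (PP), solvent (SP) and
# hydrophobic allosteric (HPII). Seven hot-spots group the fingerprint bits
# by sub-pocket and interaction chemistry; each inhibitor class (type I,
# I1/2, II, III) requires a conformation and covers a characteristic hot-spot
# set. The hot-spot membership is RECONSTRUCTED (the source figure is only
# pictorial) and shipped as an editable TSV, as is the class table.

.read_mapping <- function(name, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", name, package = "kinconf", mustWork = TRUE)
  }
  tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
}

#' Hot-spot / sub-pocket mapping table
#'
#' @param path Optional override TSV (columns `hotspot`, `pocket`, `bits`,
#'   `interactions`, `features`).
#' @return Tibble with `bits` parsed into an integer list-column.
#' @export
hotspot_table <- function(path = NULL) {
  tab <- .read_mapping("hotspots_reconstructed.tsv", path)
  tab$hotspot <- as.integer(tab$hotspot)
  tab$bits <- lapply(strsplit(tab$bits, ","), as.integer)
  tab
}

#' Inhibitor class profiles
#'
#' One row per inhibitor class: required DFG/alphaC/A-loop conformation,
#' sub-pockets explored, hot-spots targeted, interaction chemistry and
#' pharmacophore features.
#'
#' @param path Optional override TSV.
#' @return Tibble with `hotspots` and `dfg` parsed into list-columns.
#' @export
class_profile_table <- function(path = NULL) {
  tab <- .read_mapping("class_profiles.tsv", path)
  tab$hotspots <- lapply(strsplit(tab$hotspots, ","), as.integer)
  tab$dfg <- strsplit(tab$dfg, ",")
  tab
}

#' Map set fingerprint bits onto binding-site sub-pockets
#'
#' @param fp A `kinconf_sift`.
#' @param hotspots A [hotspot_table()].
#' @return Tibble: `pocket`, `n_bits_set`, `bits_set` (list-column); pockets
#'   with no set bits are omitted.
#' @export
assign_subpockets <- function(fp, hotspots = hotspot_table()) {
  set_bits <- which(unclass(fp) == 1L)
  long <- tidyr::unnest(hotspots[, c("hotspot", "pocket", "bits")], "bits")
  hit <- long[long$bits %in% set_bits, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(tibble::tibble(
      pocket = character(), n_bits_set = integer(), bits_set = list()
    ))
  }
  hit |>
    dplyr::group_by(.data$pocket) |>
    dplyr::summarise(
      n_bits_set = dplyr::n_distinct(.data$bits),
      bits_set = list(sort(unique(.data$bits)))
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_bits_set))
}

#' Rank inhibitor classes compatible with a conformation and fingerprint
#'
#' Score = fraction of the class's required hot-spots covered by the set
#' bits, zeroed when the structure's conformation conflicts with the class
#' requirement (e.g. type II requires a non-DFG-in, alphaC-out conformation).
#'
#' @param call One-row tibble with `dfg` and `alpha_c` columns (e.g. from
#'   [classify_structure()]), or a list with those elements.
#' @param fp A `kinconf_sift`.
#' @param classes A [class_profile_table()].
#' @param hotspots A [hotspot_table()].
#' @return Tibble ranked by score: `class`, `score`, `conformation_ok`,
#'   `hotspots_required`, `hotspots_covered`.
#' @export
suggest_class <- function(call, fp, classes = class_profile_table(),
                          hotspots = hotspot_table()) {
  set_bits <- which(unclass(fp) == 1L)
  covered_hs <- hotspots$hotspot[vapply(
    hotspots$bits, function(b) any(b %in% set_bits), logical(1)
  )]
  out <- purrr::pmap(classes, function(class, dfg, alpha_c, hotspots, ...) {
    ok <- (call$dfg %in% dfg) && (call$alpha_c == alpha_c)
    cov <- intersect(hotspots, covered_hs)
    tibble::tibble(
      class = class,
      score = if (ok) length(cov) / length(hotspots) else 0,
      conformation_ok = ok,
      hotspots_required = list(hotspots),
      hotspots_covered = list(cov)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$score), .data$class)
}
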