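# Canonical residue numbering: map any kinase chain onto canonical Aurora-A
# positions by pairwise sequence alignment, so motif residues (catalytic
# Lys162, alphaC Glu181, gatekeeper Leu210, DFG 274-276, activation loop
# 277-288, glycine-rich loop 136-148) can be addressed uniformly.
#
# The bundled reference profile is a SYNTHETIC stand-in: the anchor positions
# and their residue identities follow the published Aurora-A roster, but the
# filler sequence between anchors is pseudo-random (the true UniProt O14965
# sequence cannot be redistributed here). Substitute a real reference via the
# `profile` argument for work on real structures.

#' Bundled reference profile (synthetic Aurora-A stand-in)
#'
#' Positions are canonical Aurora-A numbers (1-based UniProt convention);
#' anchor residues (K162, E181, gatekeeper L210, hinge offsets GK+1..GK+10,
#' DFG 274-276, A-loop W277/V279/H280/T288, G-loop 136-148 including F144,
#' HRD H254/R255, Q177/Q185, R180) carry their published identities, filler
#' positions are synthetic. Motif spans: G-loop 136-148, alphaC 173-189,
#' hinge 210-217, DFG 274-276, A-loop 277-288 (the DFG motif is conventionally
#' the first triad of the activation segment; spans otherwise do not overlap).
#'
#' @param path Optional path to a profile TSV with columns
#'   `position`, `aa`, `motif`, `anchor`.
#' @return A `reference_profile` object: tibble plus `seq` attribute.
#' @export
reference_profile <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aurka_profile_synthetic.tsv",
      package = "kinconf", mustWork = TRUE
    )
  }
  tab <- utils::read.delim(path, colClasses = c(
    position = "integer", aa = "character",
    motif = "character", anchor = "character"
  ))
  tab$motif[is.na(tab$motif)] <- ""
  tab$anchor[is.na(tab$anchor)] <- ""
  prof <- tibble::as_tibble(tab)
  structure(prof,
    seq = paste(prof$aa, collapse = ""),
    class = c("reference_profile", class(prof))
  )
}

.blosum62_align <- function(a, b, type) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = type
  )
}

#' Map a chain onto canonical reference numbering
#'
#' Ends-free Needleman-Wunsch alignment (BLOSUM62, gap 11/1) of the chain
#' sequence against the reference profile. Residues aligned to a profile
#' position receive that canonical number; anchors are carried over only
#' where the anchor column is actually aligned (never guessed).
#'
#' @param seq Amino-acid string of the chain (or list from
#'   [chain_sequence()], in which case author numbers are taken from it).
#' @param profile A [reference_profile()].
#' @param resnum Author residue numbers matching `seq` (default 1..n).
#' @return A `residue_map` tibble: `author_number`, `author_aa`,
#'   `canonical_position`, `anchor`, `motif`; attributes `coverage` and
#'   `identity`.
#' @export
align_to_reference <- function(seq, profile = reference_profile(), resnum = NULL) {
  if (is.list(seq) && !is.null(seq$seq)) {
    resnum <- seq$resnum
    seq <- seq$seq
  }
  stopifnot(is.character(seq), nchar(seq) >= 50)
  if (is.null(resnum)) resnum <- seq_len(nchar(seq))
  stopifnot(length(resnum) == nchar(seq))
  refseq <- attr(profile, "seq")
  aln <- .blosum62_align(refseq, seq, type = "overlap")
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  # pattern()/subject() return only the aligned range, so seed the absolute
  # indices from the range starts
  ip <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  is <- Biostrings::start(Biostrings::subject(aln)) - 1L
  rows <- vector("list", length(pa))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ip <- ip + 1L
    if (sa[k] != "-") is <- is + 1L
    if (pa[k] != "-" && sa[k] != "-") {
      rows[[k]] <- c(ip, is)
    }
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0) {
    stop("not a recognizable kinase domain: nothing aligned", call. = FALSE)
  }
  coverage <- nrow(rows) / nrow(profile)
  if (coverage < 0.3) {
    stop(sprintf(
      "not a recognizable kinase domain: coverage %.2f < 0.3", coverage
    ), call. = FALSE)
  }
  map <- tibble::tibble(
    author_number = resnum[rows[, 2]],
    author_aa = strsplit(seq, "")[[1]][rows[, 2]],
    canonical_position = profile$position[rows[, 1]],
    anchor = profile$anchor[rows[, 1]],
    motif = profile$motif[rows[, 1]]
  )
  ident <- mean(map$author_aa == profile$aa[rows[, 1]])
  structure(map,
    coverage = coverage, identity = ident,
    class = c("residue_map", class(map))
  )
}

#' Alignment coverage of a residue map
#' @param map A `residue_map`.
#' @return Fraction of reference positions aligned.
#' @export
map_coverage <- function(map) attr(map, "coverage")

# Author residue number for a canonical position (NA if unaligned).
canonical_to_author <- function(map, canonical) {
  i <- match(canonical, map$canonical_position)
  map$author_number[i]
}

#' Locate the gatekeeper residue
#'
#' @param map A `residue_map` from [align_to_reference()].
#' @return List with `author_number` and `aa` of the residue aligned to the
#'   canonical gatekeeper position (210).
#' @export
locate_gatekeeper <- function(map) {
  i <- which(map$anchor == "GK")
  if (length(i) == 0) {
    stop("gatekeeper anchor not aligned in this chain", call. = FALSE)
  }
  list(author_number = map$author_number[i[1]], aa = map$author_aa[i[1]])
}

#' Pairwise percent sequence identity
#'
#' Smith-Waterman local alignment with BLOSUM62, gap open 11 / extension 1
#' (blast-p defaults); identity = identical pairs / alignment length
#' (including gaps), times 100, rounded to the nearest integer.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @return Integer percent identity in \[0, 100\].
#' @export
#' @examples
#' pairwise_identity("AAAA", "AATA") # 75
pairwise_identity <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  aln <- .blosum62_align(seq_a, seq_b, type = "local")
  round(Biostrings::pid(aln, type = "PID1"))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Serialize a residue map as a tab-separated table
#'
#' @param map A `residue_map`.
#' @param file Output path; when `NULL`, lines are returned invisibly.
#' @param chain Chain label written in the first column.
#' @return The lines, invisibly.
#' @export
write_residue_map <- function(map, file = NULL, chain = "A") {
  hdr <- "chain\tauthor_number\tcanonical_position\tanchor_label"
  ln <- c(hdr, sprintf(
    "%s\t%d\t%d\t%s", chain, map$author_number, map$canonical_position, map$anchor
  ))
  if (!is.null(file)) writeLines(ln, file)
  invisible(ln)
}
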