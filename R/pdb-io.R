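# PDB-format structure I/O.
#
# No installed R package parses PDB files in this stack, so the fixed-column
# reader/writer lives here. Only ATOM/HETATM/MODEL/ENDMDL/TER records are
# interpreted; everything else is ignored. Coordinates are preserved to the
# 0.001-Angstrom precision of the format.

#' Default HET-code exclusion list
#'
#' Water plus common crystallographic ions and cryo additives, excluded from
#' ligand extraction by default: the analyses this package supports concern
#' inhibitor co-crystals only.
#' @export
default_het_exclude <- c(
  "HOH", "DOD", "WAT", "NA", "CL", "K", "MG", "CA", "ZN", "MN", "BR", "IOD",
  "SO4", "PO4", "GOL", "EDO", "PEG", "PG4", "ACT", "DMS", "FMT", "MPD", "TRS"
)

.standard_aa3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Modified-residue normalization table
#'
#' Maps common chemically modified residue codes to their parent standard
#' residue. Covers phosphothreonine (TPO), selenomethionine (MSE),
#' phosphotyrosine (PTR) and S,S-(2-hydroxyethyl)thiocysteine (CME); extend by
#' passing additional named entries.
#'
#' @param extra Named character vector of additional `MODIFIED = "PARENT"`
#'   pairs.
#' @return Named character vector mapping modified 3-letter codes to parents.
#' @export
modified_residue_table <- function(extra = character()) {
  tab <- c(TPO = "THR", MSE = "MET", PTR = "TYR", CME = "CYS")
  if (length(extra)) {
    stopifnot(!is.null(names(extra)), all(extra %in% .standard_aa3))
    tab[names(extra)] <- unname(extra)
  }
  tab
}

# Atoms of the modified residue that do not belong to the parent residue and
# are dropped on standardization (phosphate groups, thioethanol adduct).
.modified_extra_atoms <- list(
  TPO = c("P", "O1P", "O2P", "O3P", "OP1", "OP2", "OP3"),
  PTR = c("P", "O1P", "O2P", "O3P", "OP1", "OP2", "OP3"),
  CME = c("SD", "CE", "CZ", "OH"),
  MSE = character()
)

.trim <- function(x) sub("^\\s+", "", sub("\\s+$", "", x))

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records of one model into a tidy atom table. Alternate
#' locations are reduced to the highest-occupancy conformer (ties go to
#' altloc "A"). The element is taken from columns 77-78 when present,
#' otherwise inferred from the atom name.
#'
#' @param file Path to a PDB file, or a character vector of PDB lines via
#'   `text`.
#' @param text Optional character scalar/vector of PDB-format text.
#' @param model Model number to read (default 1 = first model present).
#' @return A tibble with one row per atom: `record`, `serial`, `name`,
#'   `altloc`, `resname`, `chain`, `resnum`, `inscode`, `x`, `y`, `z`,
#'   `occupancy`, `element`, `is_hetero`, `model`, `modified_from`.
#' @export
read_pdb <- function(file = NULL, text = NULL, model = 1L) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- readLines(file, warn = FALSE)
  } else if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  rec <- substr(text, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  if (!any(is_atom)) {
    stop("no ATOM/HETATM records found", call. = FALSE)
  }
  # model bookkeeping: atoms before any MODEL record belong to model 1
  model_no <- cumsum(is_model)
  if (any(is_model)) {
    model_ids <- suppressWarnings(as.integer(substr(text[is_model], 11, 14)))
    model_of_line <- rep(NA_integer_, length(text))
    model_of_line[model_no > 0] <- model_ids[model_no[model_no > 0]]
    model_of_line[model_no == 0] <- model_ids[1]
  } else {
    model_of_line <- rep(1L, length(text))
  }
  keep <- is_atom & model_of_line == model
  if (!any(keep)) {
    stop("model ", model, " not present in input", call. = FALSE)
  }
  ln <- text[keep]
  lineno <- which(keep)
  short <- nchar(ln) < 54
  if (any(short)) {
    stop("malformed ATOM/HETATM record at line ", lineno[which(short)[1]],
      ": fewer than 54 columns",
      call. = FALSE
    )
  }
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    bad <- which(is.na(v) & .trim(substr(ln, from, to)) != "")
    blank <- which(.trim(substr(ln, from, to)) == "")
    if (length(bad)) {
      stop("malformed ", what, " field at line ", lineno[bad[1]], call. = FALSE)
    }
    if (what %in% c("x", "y", "z") && length(blank)) {
      stop("malformed ", what, " field at line ", lineno[blank[1]], call. = FALSE)
    }
    v
  }
  element <- .trim(substr(ln, 77, 78))
  name <- .trim(substr(ln, 13, 16))
  noel <- element == "" | is.na(element)
  if (any(noel)) {
    # infer from atom name: leading digits stripped, first letter(s)
    guess <- sub("^[0-9]*", "", name[noel])
    two <- substr(guess, 1, 2)
    one <- substr(guess, 1, 1)
    element[noel] <- ifelse(two %in% c("SE", "CL", "BR", "FE", "ZN", "MG"), two, one)
  }
  atoms <- tibble::tibble(
    record = .trim(substr(ln, 1, 6)),
    serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name = name,
    altloc = substr(ln, 17, 17),
    resname = .trim(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resnum = as.integer(num(23, 26, "residue number")),
    inscode = .trim(substr(ln, 27, 27)),
    x = num(31, 38, "x"),
    y = num(39, 46, "y"),
    z = num(47, 54, "z"),
    occupancy = ifelse(nchar(ln) >= 60, num(55, 60, "occupancy"), 1),
    element = toupper(element),
    model = model,
    modified_from = NA_character_
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$is_hetero <- atoms$record == "HETATM" & !(atoms$resname %in% .standard_aa3)
  # alt-loc reduction: per (chain, resnum, inscode, name) keep highest
  # occupancy; ties resolved in favour of altloc "A" (then alphabetical)
  if (any(atoms$altloc != " ")) {
    atoms <- atoms |>
      dplyr::group_by(.data$chain, .data$resnum, .data$inscode, .data$resname, .data$name) |>
      dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$serial)
  }
  atoms$altloc <- NULL
  atoms
}

#' Write an atom table as PDB-format text
#'
#' @param atoms Atom tibble as returned by [read_pdb()].
#' @param file Optional path; when `NULL` the lines are returned invisibly.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(atoms, file = NULL) {
  fmt_name <- function(n, el) {
    # standard PDB alignment: element right-justified in cols 13-14
    ifelse(nchar(n) >= 4, substr(n, 1, 4),
      ifelse(nchar(el) == 2, formatC(n, width = -4), paste0(" ", formatC(n, width = -3)))
    )
  }
  ln <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$record == "HETATM", "HETATM", "ATOM"),
    seq_len(nrow(atoms)),
    fmt_name(atoms$name, atoms$element), " ",
    atoms$resname, atoms$chain, atoms$resnum,
    ifelse(atoms$inscode == "", " ", atoms$inscode),
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
    formatC(atoms$element, width = 2)
  )
  ln <- c(ln, "END")
  if (!is.null(file)) writeLines(ln, file)
  invisible(ln)
}

#' Normalize modified residues to their parent residue
#'
#' Renames TPO/MSE/PTR/CME (and user extensions) to the parent standard
#' residue, drops atoms that do not belong to the parent (phosphates, adduct
#' atoms), relabels MSE selenium SE to SD, and keeps the original code in the
#' `modified_from` column. Unknown non-standard protein residue codes are left
#' unchanged with a warning. Idempotent.
#'
#' @param atoms Atom tibble.
#' @param table Mapping from [modified_residue_table()].
#' @return Atom tibble.
#' @export
standardize_modified_residues <- function(atoms, table = modified_residue_table()) {
  hit <- atoms$resname %in% names(table) & atoms$record == "HETATM" |
    atoms$resname %in% names(table)
  if (!any(hit)) {
    return(atoms)
  }
  for (code in intersect(unique(atoms$resname[hit]), names(table))) {
    sel <- atoms$resname == code
    drop <- sel & atoms$name %in% (.modified_extra_atoms[[code]] %||% character())
    atoms <- atoms[!drop, , drop = FALSE]
    sel <- atoms$resname == code
    if (code == "MSE") {
      atoms$name[sel & atoms$name == "SE"] <- "SD"
      atoms$element[sel & atoms$element == "SE"] <- "S"
    }
    atoms$modified_from[sel] <- code
    atoms$resname[sel] <- table[[code]]
    atoms$record[sel] <- "ATOM"
    atoms$is_hetero[sel] <- FALSE
  }
  atoms
}

#' Protein / ligand views of an atom table
#'
#' @param atoms Atom tibble.
#' @param exclude HET codes ignored by `ligand_atoms` (waters, ions,
#'   additives by default).
#' @return Atom tibble subset.
#' @export
protein_atoms <- function(atoms) {
  atoms[!atoms$is_hetero, , drop = FALSE]
}

#' @rdname protein_atoms
#' @export
ligand_atoms <- function(atoms, exclude = default_het_exclude) {
  atoms[atoms$is_hetero & !(atoms$resname %in% exclude), , drop = FALSE]
}

#' One-letter sequence of a protein chain
#'
#' @param atoms Atom tibble.
#' @param chain Chain id.
#' @return List with `seq` (string) and `resnum` (author numbers, same order).
#' @export
chain_sequence <- function(atoms, chain) {
  aa1 <- c(
    ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V"
  )
  p <- protein_atoms(atoms)
  p <- p[p$chain == chain, , drop = FALSE]
  res <- dplyr::distinct(p, .data$resnum, .data$resname)
  res <- res[order(res$resnum), , drop = FALSE]
  letters1 <- aa1[res$resname]
  keep <- !is.na(letters1)
  list(
    seq = paste(letters1[keep], collapse = ""),
    resnum = res$resnum[keep]
  )
}
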