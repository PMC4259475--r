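# Conformation classification.
#
# The DFG call is a nearest-centroid classifier in the z-scored discriminative
# parameter subspace (inter: r2, r3, r4, r6, E-(GK)-F; intra: r5, r6, DFG,
# FWH angles); the alphaC call is a salt-bridge gauge on r6(K162..E181); the
# G-loop call combines the mean circular phi/psi deviation of the loop span
# from the beta-sheet reference (phi = -140, psi = 135) with the displacement
# of the F144 side chain toward the ATP-site centroid. Centroids and
# thresholds come from a calibration built from labelled reference
# structures; the shipped default is calibrated on the noise-free synthetic
# archetypes.

.dfg_levels <- c("in", "out", "out_up")
.gloop_span <- 139:147
.gloop_phi_ref <- -140
.gloop_psi_ref <- 135
.atp_centroid_anchors <- c(210, 213, 162, 274)

#' Calibrate the conformation classifiers from labelled references
#'
#' @param references Tibble (or data.frame) with list-columns `atoms` and
#'   `map` and character columns `dfg` (in/out/out_up; required for every
#'   row) and optionally `g_loop` (extended/folded). DFG centroids need at
#'   least one reference per class; the G-loop thresholds need at least one
#'   extended and one folded reference (otherwise they stay `NA` and
#'   [classify_gloop()] refuses to run).
#' @param alpha_c_boundary Salt-bridge boundary on r6(K162..E181) between
#'   side-chain centres of mass, Angstrom (default 6.0).
#' @param spec A [com_spec()].
#' @param provenance Free-text note stored with the calibration.
#' @return A `kinconf_calibration` object.
#' @export
calibrate_conformations <- function(references,
                                    alpha_c_boundary = 6.0,
                                    spec = com_spec(),
                                    provenance = "user") {
  stopifnot(all(c("atoms", "map", "dfg") %in% names(references)))
  missing_cls <- setdiff(.dfg_levels, references$dfg)
  if (length(missing_cls)) {
    stop(
      "calibration needs at least one reference per DFG class; missing: ",
      paste(missing_cls, collapse = ", "),
      call. = FALSE
    )
  }
  feats <- purrr::map2(references$atoms, references$map, function(a, m) {
    dplyr::bind_cols(
      inter_motif_metric(a, m, spec),
      intra_motif_metric(a, m, spec)
    )
  })
  feats <- dplyr::bind_rows(feats)
  keep <- c(.discriminative_inter, .discriminative_intra)
  X <- as.matrix(feats[, keep])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-6] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  centroids <- do.call(rbind, lapply(.dfg_levels, function(cl) {
    colMeans(Z[references$dfg == cl, , drop = FALSE])
  }))
  rownames(centroids) <- .dfg_levels

  gdev_thr <- NA_real_
  f144_thr <- NA_real_
  if ("g_loop" %in% names(references) && all(c("extended", "folded") %in% references$g_loop)) {
    gl <- purrr::pmap(
      list(references$atoms, references$map, references$g_loop),
      function(a, m, lab) {
        g <- gloop_geometry(a, m, spec)
        tibble::tibble(label = lab, dev = g$dev, f144 = g$f144_dist)
      }
    ) |> dplyr::bind_rows()
    by_lab <- gl |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(dev = mean(.data$dev), f144 = mean(.data$f144))
    ext <- by_lab[by_lab$label == "extended", ]
    fld <- by_lab[by_lab$label == "folded", ]
    gdev_thr <- (ext$dev + fld$dev) / 2
    f144_thr <- (ext$f144 + fld$f144) / 2
  }

  structure(
    list(
      features = keep,
      center = center,
      scale = scale,
      centroids = centroids,
      alpha_c_boundary = alpha_c_boundary,
      gloop_dev_threshold = gdev_thr,
      gloop_f144_threshold = f144_thr,
      com_spec = spec,
      provenance = provenance,
      version = "1"
    ),
    class = "kinconf_calibration"
  )
}

#' @export
print.kinconf_calibration <- function(x, ...) {
  cat("<kinconf_calibration v", x$version, "> (", x$provenance, ")\n", sep = "")
  cat("  DFG centroids over", length(x$features), "z-scored parameters\n")
  cat("  alphaC boundary r6 =", x$alpha_c_boundary, "A\n")
  cat(
    "  G-loop thresholds: dev >", round(x$gloop_dev_threshold, 1),
    "deg & F144 dist <", round(x$gloop_f144_threshold, 1), "A\n"
  )
  invisible(x)
}

#' @method tidy kinconf_calibration
#' @export
tidy.kinconf_calibration <- function(x, ...) {
  tibble::tibble(
    feature = rep(x$features, times = 1 + nrow(x$centroids)),
    quantity = rep(c("center", rownames(x$centroids)), each = length(x$features)),
    value = c(x$center, as.vector(t(x$centroids)))
  )
}

#' @method glance kinconf_calibration
#' @export
glance.kinconf_calibration <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    n_classes = nrow(x$centroids),
    alpha_c_boundary = x$alpha_c_boundary,
    gloop_dev_threshold = x$gloop_dev_threshold,
    gloop_f144_threshold = x$gloop_f144_threshold,
    provenance = x$provenance
  )
}

# package-local cache for the default calibration
.kinconf_cache <- new.env(parent = emptyenv())

#' Default calibration from the synthetic archetypes
#'
#' Nearest-centroid calibration built from the noise-free toy-kinase
#' archetypes (one per DFG class at its canonical alphaC pairing, plus a
#' folded-G-loop archetype). Replace with [calibrate_conformations()] on real
#' labelled structures for work outside the synthetic world.
#'
#' @return A `kinconf_calibration`.
#' @export
default_calibration <- function() {
  if (!is.null(.kinconf_cache$default_cal)) {
    return(.kinconf_cache$default_cal)
  }
  prof <- reference_profile()
  build <- function(dfg, alpha_c, g_loop) {
    a <- make_toy_kinase(dfg, alpha_c, g_loop)
    m <- align_to_reference(chain_sequence(a, "A"), prof)
    list(atoms = a, map = m)
  }
  refs <- list(
    c(build("in", "in", "extended"), dfg = "in", g_loop = "extended"),
    c(build("out", "out", "extended"), dfg = "out", g_loop = "extended"),
    c(build("out_up", "out", "extended"), dfg = "out_up", g_loop = "extended"),
    c(build("in", "in", "folded"), dfg = "in", g_loop = "folded")
  )
  refs <- tibble::tibble(
    atoms = purrr::map(refs, "atoms"),
    map = purrr::map(refs, "map"),
    dfg = purrr::map_chr(refs, "dfg"),
    g_loop = purrr::map_chr(refs, "g_loop")
  )
  cal <- calibrate_conformations(refs, provenance = "synthetic archetypes")
  .kinconf_cache$default_cal <- cal
  cal
}

#' Classify the DFG-loop conformation
#'
#' Nearest-centroid label in the joint discriminative subspace; the margin is
#' the distance gap between the best and second-best centroid. Ties prefer
#' "in" (the most populous class) with margin 0.
#'
#' @param inter,intra Metric rows from [inter_motif_metric()] /
#'   [intra_motif_metric()].
#' @param cal A `kinconf_calibration`.
#' @return One-row tibble: `dfg`, `dfg_margin`, per-class distances.
#' @export
classify_dfg <- function(inter, intra, cal = default_calibration()) {
  x <- c(as.matrix(dplyr::bind_cols(inter, intra)[, cal$features])[1, ])
  z <- (x - cal$center) / cal$scale
  d <- sqrt(rowSums(sweep(cal$centroids, 2, z)^2))
  ord <- order(d, match(names(d), .dfg_levels))
  best <- names(d)[ord[1]]
  margin <- d[ord[2]] - d[ord[1]]
  if (margin < 1e-12) {
    best <- .dfg_levels[min(match(names(d)[d - min(d) < 1e-12], .dfg_levels))]
    margin <- 0
  }
  tibble::tibble(
    dfg = best, dfg_margin = unname(margin),
    dfg_dist_in = unname(d["in"]), dfg_dist_out = unname(d["out"]),
    dfg_dist_out_up = unname(d["out_up"])
  )
}

#' Classify the alphaC-helix conformation
#'
#' "out" when the Lys162-Glu181 side-chain COM distance r6 exceeds the
#' calibrated salt-bridge boundary (default 6.0 Angstrom). Helix i/i+4
#' geometry (Q177/Q185 alpha-carbon spacing around E181) is reported as a
#' diagnostic but is not decisive.
#'
#' @param atoms Atom tibble.
#' @param map Residue map.
#' @param inter Row from [inter_motif_metric()].
#' @param cal A `kinconf_calibration`.
#' @return One-row tibble: `alpha_c`, `alpha_c_margin`, `helix_i_ip4`,
#'   `helix_i_im4` (NA when the glutamine anchors are absent).
#' @export
classify_alpha_c <- function(atoms, map, inter, cal = default_calibration()) {
  r6 <- inter$inter_r6_k162_e181
  lab <- if (r6 > cal$alpha_c_boundary) "out" else "in"
  ca_of <- function(canonical) {
    au <- canonical_to_author(map, canonical)
    if (is.na(au)) {
      return(NULL)
    }
    res <- atoms[!atoms$is_hetero & atoms$resnum == au & atoms$name == "CA", ]
    if (nrow(res) == 0) {
      return(NULL)
    }
    c(res$x[1], res$y[1], res$z[1])
  }
  e <- ca_of(181)
  qm <- ca_of(177)
  qp <- ca_of(185)
  tibble::tibble(
    alpha_c = lab,
    alpha_c_margin = abs(r6 - cal$alpha_c_boundary),
    helix_i_im4 = if (!is.null(e) && !is.null(qm)) pt_distance(e, qm) else NA_real_,
    helix_i_ip4 = if (!is.null(e) && !is.null(qp)) pt_distance(e, qp) else NA_real_
  )
}

# G-loop raw gauges: mean circular (phi, psi) deviation over the loop span
# and the F144 side-chain COM distance to the ATP-site centroid.
gloop_geometry <- function(atoms, map, spec = com_spec()) {
  prot <- protein_atoms(atoms)
  chain <- prot$chain[1]
  span_author <- canonical_to_author(map, .gloop_span)
  present <- !is.na(span_author)
  devs <- rep(NA_real_, length(.gloop_span))
  for (i in seq_along(.gloop_span)) {
    if (!present[i]) next
    pp <- tryCatch(
      backbone_dihedrals(atoms, chain, span_author[i]),
      error = function(e) NULL
    )
    if (is.null(pp)) next
    devs[i] <- (circular_diff(pp["phi"], .gloop_phi_ref) +
      circular_diff(pp["psi"], .gloop_psi_ref)) / 2
  }
  if (mean(is.na(devs)) > 0.5) {
    stop("G-loop span too incomplete to gauge (",
      sum(is.na(devs)), "/", length(devs), " residues missing phi/psi)",
      call. = FALSE
    )
  }
  atp <- rowMeans(vapply(
    .atp_centroid_anchors,
    function(cn) anchor_com(atoms, map, cn, spec), numeric(3)
  ))
  f144 <- anchor_com(atoms, map, 144, spec, "F144")
  list(dev = mean(devs, na.rm = TRUE), f144_dist = pt_distance(f144, atp))
}

#' Classify the G-loop conformation
#'
#' "folded" when the mean circular phi/psi deviation of the loop span
#' (canonical 139-147) from the beta reference (-140, 135) exceeds the
#' calibrated threshold AND the F144 side-chain centre of mass sits closer to
#' the ATP-site centroid than the calibrated displacement boundary.
#'
#' @param atoms Atom tibble.
#' @param map Residue map.
#' @param cal A `kinconf_calibration` with G-loop thresholds.
#' @param spec A [com_spec()].
#' @return One-row tibble: `g_loop`, `gloop_dev`, `gloop_f144_dist`.
#' @export
classify_gloop <- function(atoms, map, cal = default_calibration(), spec = com_spec()) {
  if (!is.finite(cal$gloop_dev_threshold)) {
    stop("calibration has no G-loop thresholds (needs extended + folded references)",
      call. = FALSE
    )
  }
  g <- gloop_geometry(atoms, map, spec)
  folded <- g$dev > cal$gloop_dev_threshold && g$f144_dist < cal$gloop_f144_threshold
  tibble::tibble(
    g_loop = if (folded) "folded" else "extended",
    gloop_dev = g$dev,
    gloop_f144_dist = g$f144_dist
  )
}

#' Classify a structure's motif conformations
#'
#' Runs the full gauge: metric vectors, DFG nearest-centroid call, alphaC
#' salt-bridge call and G-loop call, for one chain.
#'
#' @param atoms Atom tibble (one model).
#' @param map Residue map; computed by aligning the chain sequence to the
#'   bundled reference profile when `NULL`.
#' @param cal A `kinconf_calibration`.
#' @param chain Chain id (default: first protein chain).
#' @param spec A [com_spec()].
#' @return One-row tibble with labels, margins and all metric parameters.
#' @export
classify_structure <- function(atoms, map = NULL, cal = default_calibration(),
                               chain = NULL, spec = com_spec()) {
  prot <- protein_atoms(atoms)
  chain <- chain %||% prot$chain[1]
  atoms_c <- atoms[atoms$chain == chain | atoms$is_hetero, , drop = FALSE]
  if (is.null(map)) {
    map <- align_to_reference(chain_sequence(atoms_c, chain))
  }
  inter <- inter_motif_metric(atoms_c, map, spec)
  intra <- intra_motif_metric(atoms_c, map, spec)
  dfg <- classify_dfg(inter, intra, cal)
  ac <- classify_alpha_c(atoms_c, map, inter, cal)
  gl <- classify_gloop(atoms_c, map, cal, spec)
  dplyr::bind_cols(
    tibble::tibble(chain = chain),
    dfg[, c("dfg", "dfg_margin")], ac[, c("alpha_c", "alpha_c_margin")], gl,
    inter, intra
  )
}

#' Write / read a calibration as a key-value text file
#'
#' @param cal A `kinconf_calibration`.
#' @param file Path.
#' @return `write_calibration` returns `file` invisibly; `read_calibration`
#'   returns the calibration.
#' @export
write_calibration <- function(cal, file) {
  ln <- c(
    paste0("version=", cal$version),
    paste0("provenance=", cal$provenance),
    paste0("features=", paste(cal$features, collapse = ",")),
    paste0("center=", paste(format(cal$center, digits = 12), collapse = ",")),
    paste0("scale=", paste(format(cal$scale, digits = 12), collapse = ",")),
    vapply(rownames(cal$centroids), function(cl) {
      paste0(
        "centroid.", cl, "=",
        paste(format(cal$centroids[cl, ], digits = 12), collapse = ",")
      )
    }, character(1)),
    paste0("alpha_c_boundary=", format(cal$alpha_c_boundary, digits = 12)),
    paste0("gloop_dev_threshold=", format(cal$gloop_dev_threshold, digits = 12)),
    paste0("gloop_f144_threshold=", format(cal$gloop_f144_threshold, digits = 12))
  )
  writeLines(ln, file)
  invisible(file)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(file) {
  kv <- readLines(file)
  kv <- kv[nzchar(kv) & !startsWith(kv, "#")]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  g <- stats::setNames(as.list(vals), keys)
  feats <- strsplit(g$features, ",")[[1]]
  numv <- function(s) as.numeric(strsplit(s, ",")[[1]])
  cents <- do.call(rbind, lapply(.dfg_levels, function(cl) numv(g[[paste0("centroid.", cl)]])))
  dimnames(cents) <- list(.dfg_levels, feats)
  structure(
    list(
      features = feats,
      center = stats::setNames(numv(g$center), feats),
      scale = stats::setNames(numv(g$scale), feats),
      centroids = cents,
      alpha_c_boundary = as.numeric(g$alpha_c_boundary),
      gloop_dev_threshold = as.numeric(g$gloop_dev_threshold),
      gloop_f144_threshold = as.numeric(g$gloop_f144_threshold),
      com_spec = com_spec(),
      provenance = g$provenance,
      version = g$version
    ),
    class = "kinconf_calibration"
  )
}
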