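#' Circular variance of atoms and residues
#'
#' The circular variance of an atom is 1 minus the normalised magnitude of
#' the sum of unit vectors pointing to all other atoms strictly within the
#' cutoff `r_c`. It measures the density of protein around a position:
#' values near 0 mark protruding atoms, values near 1 buried ones. The
#' residue value is the mean over the residue's heavy atoms. An atom with no
#' neighbour inside `r_c` is assigned 0 (the protrusion limit of an isolated
#' point).
#'
#' @param structure A `"jet_structure"`, or a coordinate matrix.
#' @param r_c Cutoff radius in Angstrom (strict inequality). The package
#'   uses 12 for a local description of surface geometry and 100 for a
#'   global one.
#' @return List with `atom` (per-atom CV) and, for a structure input,
#'   `residue` (named by residue id).
#' @export
compute_cv <- function(structure, r_c = 12) {
  stopifnot(r_c > 0)
  if (is.matrix(structure)) {
    return(list(atom = .cv_atoms(structure, r_c)))
  }
  xyz <- .atom_xyz(structure$atoms)
  cv <- .cv_atoms(xyz, r_c)
  res <- tapply(cv, structure$atoms$res_index, mean)
  residue <- as.numeric(res)[match(seq_len(nrow(structure$residues)),
                                   as.integer(names(res)))]
  names(residue) <- structure$residues$id
  list(atom = cv, residue = residue)
}

.cv_atoms <- function(xyz, r_c) {
  n <- nrow(xyz)
  stopifnot(n >= 2)
  cv <- numeric(n)
  r2 <- r_c^2
  for (i in seq_len(n)) {
    dx <- sweep(xyz, 2, xyz[i, ], "-")
    d2 <- rowSums(dx^2)
    sel <- which(d2 < r2 & d2 > 0)
    ni <- length(sel)
    if (ni == 0L) { cv[i] <- 0; next }
    u <- dx[sel, , drop = FALSE] / sqrt(d2[sel])
    cv[i] <- 1 - sqrt(sum(colSums(u)^2)) / ni
  }
  cv
}

#' Smooth raw conservation over the spatial neighborhood
#'
#' Each residue's raw relative trace significance d_j is blended with the
#' mean over its spatial neighbours I (residues with a heavy atom closer
#' than 5 Angstrom): T(j) = (w_env * mean(d_I) + w_self * d_j) /
#' (w_env + w_self), with weights fixed at 3 and 4. Residues without
#' neighbours keep d_j.
#'
#' @param d_raw Named numeric vector of raw conservation in [0,1], names are
#'   residue ids covering every graph node.
#' @param graph A `"jet_graph"` (5 Angstrom residue adjacency).
#' @param w_env Environment weight (default 3).
#' @param w_self Self weight (default 4).
#' @return Named numeric vector of smoothed, still unscaled conservation.
#' @export
smooth_conservation <- function(d_raw, graph, w_env = 3, w_self = 4) {
  stopifnot(w_env > 0, w_self > 0)
  d <- unname(d_raw[graph$ids])
  if (anyNA(d))
    stop("missing conservation value for residue(s): ",
         paste(utils::head(graph$ids[is.na(d)], 5), collapse = ", "))
  out <- numeric(graph$n)
  for (j in seq_len(graph$n)) {
    nb <- graph$adj[[j]]
    out[j] <- if (length(nb) == 0L) d[j] else
      (w_env * mean(d[nb]) + w_self * d[j]) / (w_env + w_self)
  }
  names(out) <- graph$ids
  out
}

#' Min-max scaling over a residue subset
#'
#' Linearly maps the minimum over `subset` to 0 and the maximum to 1;
#' positions outside the subset become NA. Descriptors are scaled over the
#' surface residues of the query protein, so predictions are
#' protein-specific. A constant vector maps to 0.5 everywhere (uninformative
#' but well defined).
#'
#' @param values Numeric vector (optionally named).
#' @param subset Logical or integer index of the positions defining the
#'   scaling range; default all positions.
#' @param invert If TRUE return 1 - scaled (used to form 1-CV).
#' @return Numeric vector like `values`, scaled on `subset`, NA elsewhere.
#' @export
scale_minmax <- function(values, subset = NULL, invert = FALSE) {
  n <- length(values)
  idx <- if (is.null(subset)) seq_len(n) else
    if (is.logical(subset)) which(subset) else as.integer(subset)
  if (length(idx) == 0L) stop("empty scaling subset")
  v <- values[idx]
  if (anyNA(v)) stop("NA values inside scaling subset")
  rng <- range(v)
  out <- rep(NA_real_, n)
  out[idx] <- if (rng[1] == rng[2]) 0.5 else (v - rng[1]) / (rng[2] - rng[1])
  if (invert) out[idx] <- 1 - out[idx]
  names(out) <- names(values)
  out
}

#' Amino-acid interface propensities
#'
#' Returns the raw interface-propensity value for each residue type. The
#' default scale shipped with the package is a constructed stand-in spanning
#' the 0-2.21 range of published interface propensities (see
#' `inst/extdata/interface_propensities_synthetic.tsv`); it can be replaced
#' by any user table.
#'
#' @param aa3 Character vector of 3-letter residue codes.
#' @param table Named numeric propensity vector; default [jet_propensities()].
#' @param fallback Use the mean table value for unknown residue types
#'   (default TRUE).
#' @return Numeric vector of raw propensities (scale with [scale_minmax()]).
#' @export
lookup_pc <- function(aa3, table = jet_propensities(), fallback = TRUE) {
  out <- unname(table[aa3])
  if (anyNA(out)) {
    if (!fallback)
      stop("no propensity for residue type(s): ",
           paste(unique(aa3[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- mean(table)
  }
  out
}

#' @rdname lookup_pc
#' @param path Optional path to an alternative two-column TSV (aa3, propensity).
#' @export
jet_propensities <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "interface_propensities_synthetic.tsv",
                        package = "jet2r")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Read a per-residue conservation file
#'
#' Tab-separated file with columns chain, resnum, icode, d_raw; d_raw is any
#' conservation score in [0,1] (typically an averaged phylogenetic tree
#' trace).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector keyed by `"chain:resno:icode"`.
#' @export
read_conservation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 4) stop("conservation file needs columns chain, resnum, icode, d_raw")
  v <- as.numeric(tab[[4]])
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("d_raw values must lie in [0,1]")
  stats::setNames(v, .res_id(tab[[1]], tab[[2]], as.character(tab[[3]])))
}

#' Per-residue descriptor table
#'
#' Computes everything the scoring schemes consume: solvent accessibility
#' (absolute and relative), the surface mask (rasa >= 0.05), circular
#' variance at the local (12 Angstrom) and global (100 Angstrom) cutoffs,
#' the scaled interface propensity, and the smoothed + scaled conservation
#' level. All scaled descriptors are min-max scaled over surface residues
#' only, so each spans [0,1] exactly on the surface of the query protein.
#'
#' @param structure A `"jet_structure"`.
#' @param conservation Named numeric vector in [0,1] keyed by residue id, a
#'   path to a conservation TSV, or NULL when no evolutionary information is
#'   available (conservation-based fields are then NA and only scheme SC3
#'   applies).
#' @param graph Optional precomputed `"jet_graph"` at 5 Angstrom.
#' @param probe Probe radius for SASA (default 1.4).
#' @param n_points SASA quadrature points per atom (default 256).
#' @param surface_rasa Relative-accessibility threshold for the surface mask
#'   (default 0.05: buried residues with asa < 5\% are ignored).
#' @param propensity Named propensity vector (default [jet_propensities()]).
#' @param max_asa Named reference-ASA vector (default [jet_max_asa()]).
#' @param w_env,w_self Conservation smoothing weights (defaults 3 and 4).
#' @param r_c_local,r_c_global Circular-variance cutoffs (12 and 100).
#' @return A data frame of class `"jet_descriptors"` with one row per
#'   residue: id, chain, resno, icode, aa3, asa, rasa, is_surface, d_raw,
#'   tjet, pc, cv_local, cv_global (scaled fields NA off-surface). The
#'   5 Angstrom graph is attached as attribute `"graph"`.
#' @export
residue_descriptors <- function(structure, conservation = NULL, graph = NULL,
                                probe = 1.4, n_points = 256L,
                                surface_rasa = 0.05,
                                propensity = jet_propensities(),
                                max_asa = jet_max_asa(),
                                w_env = 3, w_self = 4,
                                r_c_local = 12, r_c_global = 100) {
  if (is.null(graph)) graph <- neighbor_graph(structure, cutoff = 5)
  res <- structure$residues
  sasa <- compute_sasa(structure, probe = probe, n_points = n_points)
  rasa <- compute_rasa(sasa$residue, res$aa3, reference = max_asa)
  is_surface <- rasa >= surface_rasa
  if (!any(is_surface)) stop("no surface residues at rasa >= ", surface_rasa)
  cv_loc <- compute_cv(structure, r_c = r_c_local)$residue
  cv_glo <- compute_cv(structure, r_c = r_c_global)$residue
  pc_raw <- lookup_pc(res$aa3, table = propensity)
  if (is.character(conservation) && length(conservation) == 1L)
    conservation <- read_conservation(conservation)
  if (!is.null(conservation)) {
    d_raw <- unname(conservation[res$id])
    tjet_raw <- smooth_conservation(stats::setNames(d_raw, res$id), graph,
                                    w_env = w_env, w_self = w_self)
    tjet <- scale_minmax(tjet_raw, subset = is_surface)
  } else {
    d_raw <- rep(NA_real_, nrow(res))
    tjet <- rep(NA_real_, nrow(res))
  }
  out <- data.frame(
    id = res$id, chain = res$chain, resno = res$resno, icode = res$icode,
    aa3 = res$aa3,
    asa = unname(sasa$residue), rasa = unname(rasa),
    is_surface = unname(is_surface),
    d_raw = d_raw,
    tjet = unname(tjet),
    pc = unname(scale_minmax(pc_raw, subset = is_surface)),
    cv_local = unname(scale_minmax(cv_loc, subset = is_surface)),
    cv_global = unname(scale_minmax(cv_glo, subset = is_surface)),
    stringsAsFactors = FALSE
  )
  attr(out, "graph") <- graph
  class(out) <- c("jet_descriptors", "data.frame")
  out
}
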