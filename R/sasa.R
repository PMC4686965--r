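# Solvent-accessible surface area by Shrake-Rupley sphere-point quadrature.
# Quadrature points are placed on a golden-section spiral, which gives a
# deterministic quasi-uniform covering of the sphere.

.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# core routine on bare coordinates + radii
.sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 256L) {
  stopifnot(probe >= 0, n_points >= 64L)
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  expanded <- radii + probe
  asa <- numeric(n)
  max_r <- max(expanded)
  for (i in seq_len(n)) {
    ri <- expanded[i]
    dx <- sweep(xyz, 2, xyz[i, ])
    d2 <- rowSums(dx^2)
    nb <- which(d2 < (ri + max_r)^2 & d2 > 0)
    nb <- nb[sqrt(d2[nb]) < ri + expanded[nb]]
    if (length(nb) == 0L) {
      asa[i] <- 4 * pi * ri^2
      next
    }
    sp <- pts * ri
    sp <- sweep(sp, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      free <- free & dj2 >= expanded[j]^2
    }
    asa[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  asa
}

#' Solvent-accessible surface area
#'
#' Computes per-atom and per-residue solvent-accessible surface area (SASA)
#' by sphere-point quadrature: each atom is inflated by the probe radius,
#' covered with quasi-uniform test points, and the exposed fraction is the
#' fraction of points outside every other inflated atom.
#'
#' @param structure A `"jet_structure"`, or a numeric matrix of coordinates
#'   (then `radii` must be given).
#' @param probe Probe radius in Angstrom; default 1.4 (a water molecule).
#' @param n_points Number of quadrature points per atom (>= 64); default 256.
#' @param radii Per-atom radii when `structure` is a bare coordinate matrix.
#' @param include_het Include non-water hetero atoms as occluders; default
#'   FALSE so accessibility describes the protein alone.
#' @return List with `atom` (numeric, Angstrom^2 per atom) and, for a
#'   structure input, `residue` (named by residue id).
#' @export
compute_sasa <- function(structure, probe = 1.4, n_points = 256L,
                         radii = NULL, include_het = FALSE) {
  if (is.matrix(structure)) {
    stopifnot(!is.null(radii), length(radii) == nrow(structure))
    return(list(atom = .sasa_atoms(structure, radii, probe, n_points)))
  }
  at <- structure$atoms
  xyz <- .atom_xyz(at)
  radii <- at$vdw
  n_prot <- nrow(at)
  if (include_het && nrow(structure$het)) {
    xyz <- rbind(xyz, .atom_xyz(structure$het))
    radii <- c(radii, structure$het$vdw)
  }
  asa <- .sasa_atoms(xyz, radii, probe, n_points)[seq_len(n_prot)]
  res <- tapply(asa, at$res_index, sum)
  residue <- as.numeric(res)[match(seq_len(nrow(structure$residues)),
                                   as.integer(names(res)))]
  residue[is.na(residue)] <- 0
  names(residue) <- structure$residues$id
  list(atom = asa, residue = residue)
}

#' Relative solvent accessibility
#'
#' Divides per-residue SASA by a per-amino-acid reference maximum. Values may
#' slightly exceed 1 for extended conformations; they are left unclipped and
#' only the 5\% surface flag uses the raw ratio.
#'
#' @param asa Named numeric vector of residue SASA (Angstrom^2).
#' @param aa3 Character vector of 3-letter residue codes, same order as `asa`.
#' @param reference Named vector of maximum ASA per residue type; defaults to
#'   the table shipped with the package (see [jet_max_asa()]).
#' @param fallback Use the mean reference value for residue types missing
#'   from the table (default TRUE); with FALSE a missing type is an error.
#' @return Named numeric vector of relative accessibilities.
#' @export
compute_rasa <- function(asa, aa3, reference = jet_max_asa(), fallback = TRUE) {
  ref <- unname(reference[aa3])
  if (anyNA(ref)) {
    if (!fallback)
      stop("no reference ASA for residue type(s): ",
           paste(unique(aa3[is.na(ref)]), collapse = ", "))
    ref[is.na(ref)] <- mean(reference)
  }
  out <- asa / ref
  names(out) <- names(asa)
  out
}

#' Reference maximum accessible surface areas
#'
#' Theoretical maximum ASA per amino acid (Tien et al. 2013), used to
#' normalise residue SASA into relative accessibility.
#'
#' @param path Optional path to an alternative two-column TSV (aa3, max_asa).
#' @return Named numeric vector (Angstrom^2) over the 20 standard residues.
#' @export
jet_max_asa <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "max_asa_tien2013.tsv", package = "jet2r")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(tab[[2]], tab[[1]])
}
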