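# Synthetic protein-like fixtures with planted ground truth. Pseudo-residues
# (five alanine-like heavy atoms: N, CA, C, O, CB) are laid out on concentric
# shells to form a compact globule; a conserved surface patch, a protruding
# loop and a small hetero ligand can be planted with known residue labels.
# Everything is deterministic under a seed.

.aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")

# truncated normal on [0,1] by rejection; sd 0 returns the clamped mean
.rtrunc01 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(min(1, max(0, mean)), n))
  out <- numeric(n); k <- 0L
  while (k < n) {
    x <- stats::rnorm(n - k, mean, sd)
    x <- x[x >= 0 & x <= 1]
    if (length(x)) { out[k + seq_along(x)] <- x; k <- k + length(x) }
  }
  out
}

.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# residue centers: concentric shells of golden-spiral points, ~spacing apart
.globule_centers <- function(n, spacing) {
  centers <- matrix(0, 0, 3)
  k <- 0L
  while (nrow(centers) < n) {
    if (k == 0L) {
      pts <- matrix(0, 1, 3)
    } else {
      cap <- max(1L, round(4 * pi * k^2))
      pts <- .sphere_points(cap) * (k * spacing)
    }
    take <- min(nrow(pts), n - nrow(centers))
    centers <- rbind(centers, pts[seq_len(take), , drop = FALSE])
    k <- k + 1L
  }
  centers
}

.residue_atoms <- function(center, rot) {
  local <- rbind(N = c(-1.46, 0, 0), CA = c(0, 0, 0), C = c(1.0, 1.1, 0),
                 O = c(1.0, 2.33, 0.3), CB = c(-0.4, -0.9, 1.2))
  sweep(local %*% t(rot), 2, center, "+")
}

#' Generate a synthetic protein-like globule with planted features
#'
#' Builds a compact globule of pseudo-residues and, optionally, plants (i) a
#' contiguous surface patch with elevated conservation, (ii) a protruding
#' loop extending away from the surface, and (iii) a small hetero ligand
#' group sitting over the patch. The patch emulates the conserved nucleus
#' of a protein-protein interface; the loop emulates the highly protruding
#' rim regions that circular variance detects; the generator returns the
#' planted residue sets as ground-truth labels.
#'
#' @param n_residues Number of pseudo-residues (>= 20; default 150).
#' @param spacing Target inter-residue spacing in Angstrom (default 4).
#' @param patch_size Planted-patch size in residues (0 disables; default 25,
#'   about the expected interface size for a surface of this scale).
#' @param patch_contrast Mean conservation elevation of the patch over the
#'   background (default 0.5).
#' @param patch_profile `"noisy"` (a uniform elevation sharing the
#'   background noise), `"gradient"` (conservation decays from the patch
#'   centre outward, the heterogeneous signature of real interfaces),
#'   `"two-level"` (two discrete conservation levels inside the site), or
#'   `"constant"` (all patch values exactly background + contrast: a
#'   homogeneous, ligand-pocket-like site).
#' @param noise_sigma Truncated-normal conservation noise (default 0.1).
#' @param background Background conservation mean (default 0.3).
#' @param loop_size Residues in the planted protruding loop (default 0).
#' @param ligand Plant a 4-atom hetero group 2.5 Angstrom above the patch
#'   centre (default FALSE).
#' @param chain Chain identifier (default "A").
#' @param seed Integer RNG seed; the same seed reproduces the fixture
#'   bit-for-bit.
#' @return List with `structure` (a `"jet_structure"`), `conservation`
#'   (named vector), `labels` (data frame id/label with labels
#'   `"patch"`, `"loop"`, `"background"`), and `params`.
#' @export
synthetic_globule <- function(n_residues = 150, spacing = 4,
                              patch_size = 25, patch_contrast = 0.5,
                              patch_profile = c("noisy", "gradient", "two-level", "constant"),
                              noise_sigma = 0.1, background = 0.3,
                              loop_size = 0, ligand = FALSE,
                              chain = "A", seed = NULL) {
  stopifnot(n_residues >= 20)
  patch_profile <- match.arg(patch_profile)
  if (!is.null(seed)) set.seed(as.integer(seed))
  centers <- .globule_centers(n_residues, spacing)
  radii <- sqrt(rowSums(centers^2))
  r_out <- max(radii)
  # planted patch: outermost-shell residues closest in angle to +z
  patch_idx <- integer(0)
  if (patch_size > 0) {
    outer <- which(radii > r_out - spacing / 2)
    if (length(outer) < patch_size)
      stop("patch larger than the outer shell; reduce patch_size")
    ang <- acos(pmin(1, pmax(-1, centers[outer, 3] / radii[outer])))
    patch_idx <- outer[order(ang)][seq_len(patch_size)]
  }
  # planted loop: arc marching outward from the surface along +x
  loop_centers <- NULL
  if (loop_size > 0) {
    u <- c(1, 0, 0); v <- c(0, 0, 1)
    loop_centers <- t(vapply(seq_len(loop_size), function(k) {
      (r_out + 3.5 * k) * u + 1.5 * sin(k / 2) * v
    }, numeric(3)))
  }
  all_centers <- rbind(centers, loop_centers)
  n_tot <- nrow(all_centers)
  aa3 <- sample(.aa20, n_tot, replace = TRUE)
  atoms <- do.call(rbind, lapply(seq_len(n_tot), function(i) {
    xyz <- .residue_atoms(all_centers[i, ], .random_rotation())
    data.frame(type = "ATOM", chain = chain, resno = i, insert = "",
               resid = aa3[i], elety = rownames(xyz),
               element = substr(rownames(xyz), 1, 1),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
  if (ligand) {
    if (patch_size == 0) stop("ligand placement requires a planted patch")
    pc <- colMeans(centers[patch_idx, , drop = FALSE])
    pc <- pc / sqrt(sum(pc^2)) * (r_out + 2.5)
    off <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0), c(0.7, 0.7, 1.1))
    atoms <- rbind(atoms, data.frame(
      type = "HETATM", chain = chain, resno = n_tot + 1L, insert = "",
      resid = "LIG", elety = c("C1", "C2", "O1", "C3"),
      element = c("C", "C", "O", "C"),
      x = pc[1] + off[, 1], y = pc[2] + off[, 2], z = pc[3] + off[, 3],
      stringsAsFactors = FALSE))
  }
  st <- as_jet_structure(atoms)
  ids <- st$residues$id
  label <- rep("background", n_tot)
  label[patch_idx] <- "patch"
  if (loop_size > 0) label[n_residues + seq_len(loop_size)] <- "loop"
  d_raw <- .rtrunc01(n_tot, background, noise_sigma)
  if (length(patch_idx)) {
    d_raw[patch_idx] <- switch(patch_profile,
      noisy = .rtrunc01(length(patch_idx), background + patch_contrast,
                        noise_sigma),
      constant = min(1, background + patch_contrast),
      gradient = {
        # conservation decays from the patch centre outward, emulating the
        # support -> core -> rim conservation gradient of real interfaces
        frac <- (seq_along(patch_idx) - 1) / (length(patch_idx) - 1)
        g <- 1.4 - 1.1 * sqrt(frac)
        pmin(1, pmax(0, background + patch_contrast * g +
                       stats::rnorm(length(patch_idx), 0, noise_sigma / 2)))
      },
      `two-level` = {
        # two conservation levels inside the site (distinct anchor classes);
        # the +/-0.25 separation survives the 4/7 attenuation of
        # neighborhood smoothing, keeping the seed visibly heterogeneous
        half <- seq_along(patch_idx) %% 2 == 0
        lv <- ifelse(half, min(1, background + patch_contrast + 0.25),
                     max(0, background + patch_contrast - 0.25))
        pmin(1, pmax(0, lv + stats::rnorm(length(patch_idx), 0, noise_sigma / 2)))
      })
  }
  list(structure = st,
       conservation = stats::setNames(d_raw, ids),
       labels = data.frame(id = ids, label = label, stringsAsFactors = FALSE),
       params = list(n_residues = n_residues, spacing = spacing,
                     patch_size = patch_size, patch_contrast = patch_contrast,
                     patch_profile = patch_profile, noise_sigma = noise_sigma,
                     background = background, loop_size = loop_size,
                     ligand = ligand, seed = seed))
}

#' Standard fixture presets
#'
#' Four ready-made study conditions: `"conserved-patch"` (a localized,
#' heterogeneously conserved interface-like patch), `"protruding-loop"`
#' (flat conservation plus a protruding arc), `"ligand-pocket"` (a
#' homogeneous ultra-conserved pocket with a bound hetero ligand), and
#' `"flat"` (constant conservation, no planted features).
#'
#' @param preset Preset name.
#' @param seed Integer RNG seed.
#' @param ... Overrides forwarded to [synthetic_globule()].
#' @return See [synthetic_globule()].
#' @export
fixture_preset <- function(preset = c("conserved-patch", "protruding-loop",
                                      "ligand-pocket", "flat"),
                           seed = 1, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "conserved-patch" = list(patch_profile = "gradient"),
    "protruding-loop" = list(patch_size = 0, loop_size = 8, noise_sigma = 0),
    "ligand-pocket" = list(patch_profile = "constant", patch_contrast = 0.6,
                           ligand = TRUE),
    "flat" = list(patch_size = 0, noise_sigma = 0))
  do.call(synthetic_globule, utils::modifyList(args, c(list(seed = seed), list(...))))
}

#' Two-chain synthetic complex
#'
#' Places two independently generated globules (chains A and B) in contact
#' so that residues at the contact face lose solvent accessibility upon
#' "binding" — a ground-truth substrate for interface definition and
#' support/core/rim decomposition.
#'
#' @param n_a,n_b Residue counts of the two chains (defaults 120 and 90).
#' @param overlap Interpenetration of the two globules along the contact
#'   axis in Angstrom (default 4): pressing the quasi-spherical chains into
#'   each other creates a contact disc of buried residues, emulating the
#'   shape complementarity of a real interface.
#' @param seed Integer RNG seed.
#' @param ... Forwarded to both [synthetic_globule()] calls.
#' @return List with `structure` (two-chain `"jet_structure"`) and the two
#'   per-chain fixture lists `a` and `b`.
#' @export
synthetic_complex <- function(n_a = 120, n_b = 90, overlap = 4, seed = 1, ...) {
  fa <- synthetic_globule(n_a, chain = "A", patch_size = 0, seed = seed, ...)
  fb <- synthetic_globule(n_b, chain = "B", patch_size = 0, seed = seed + 1L, ...)
  # place B along +x, pressed `overlap` Angstrom into the contact face of A
  shift <- max(fa$structure$atoms$x) - min(fb$structure$atoms$x) - overlap
  atoms_b <- fb$structure$atoms
  atoms_b$x <- atoms_b$x + shift
  ab <- rbind(fa$structure$atoms, atoms_b)
  st <- as_jet_structure(ab[, c("type", "chain", "resno", "insert", "resid",
                                "elety", "element", "x", "y", "z")])
  list(structure = st, a = fa, b = fb, shift = shift)
}

#' Write a fixture to disk
#'
#' Writes the standard input file set: `fixture.pdb` (structure),
#' `conservation.tsv` (chain, resnum, icode, d_raw), `truth.tsv` (planted
#' labels) and `propensities.tsv` (a copy of the default propensity scale).
#'
#' @param fixture A list from [synthetic_globule()] or [fixture_preset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- fixture$structure
  at <- rbind(st$atoms[, c("type", "chain", "resno", "insert", "resid",
                           "elety", "element", "x", "y", "z")],
              if (nrow(st$het)) st$het[, c("type", "chain", "resno", "insert",
                                           "resid", "elety", "element",
                                           "x", "y", "z")])
  pdb_path <- file.path(dir, "fixture.pdb")
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.vector(t(.atom_xyz(at))),
                   type = at$type, resno = at$resno, resid = at$resid,
                   chain = at$chain, elety = at$elety, elesy = at$element,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  res <- st$residues
  cons_path <- file.path(dir, "conservation.tsv")
  utils::write.table(
    data.frame(chain = res$chain, resnum = res$resno, icode = res$icode,
               d_raw = unname(fixture$conservation[res$id])),
    cons_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(fixture$labels, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prop_path <- file.path(dir, "propensities.tsv")
  prop <- jet_propensities()
  utils::write.table(data.frame(aa3 = names(prop), propensity = unname(prop)),
                     prop_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pdb = pdb_path, conservation = cons_path, truth = truth_path,
              propensities = prop_path))
}
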