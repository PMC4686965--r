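#' Van der Waals radii by element
#'
#' Heavy-atom van der Waals radii (Angstrom) used for solvent-accessibility
#' calculations. Values follow the conventions of classical accessibility
#' programs; unknown elements fall back to the carbon radius.
#'
#' @return Named numeric vector of radii in Angstrom, with a `"default"`
#'   entry used for unlisted elements.
#' @export
jet_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    ZN = 1.39, MG = 1.73, CA = 2.31, FE = 1.94, MN = 1.97, "NA" = 2.27,
    K = 2.75, CU = 1.40, NI = 1.63, CO = 1.53,
    default = 1.70)
}

.water_names <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

# canonical residue identifier "chain:resno:icode"
.res_id <- function(chain, resno, icode) {
  icode[is.na(icode)] <- ""
  paste(chain, resno, icode, sep = ":")
}

.element_of <- function(elesy, elety) {
  el <- toupper(ifelse(is.na(elesy) | elesy == "", NA, elesy))
  miss <- is.na(el)
  if (any(miss)) {
    # derive from the atom name: strip digits, take leading letters
    nm <- gsub("[0-9' ]", "", toupper(elety[miss]))
    two <- substr(nm, 1, 2)
    known2 <- two %in% c("CL", "BR", "SE", "ZN", "MG", "FE", "MN", "NA", "CU", "NI", "CO")
    el[miss] <- ifelse(known2, two, substr(nm, 1, 1))
  }
  el
}

.assign_vdw <- function(element, vdw = jet_vdw_radii()) {
  r <- unname(vdw[element])
  r[is.na(r)] <- unname(vdw["default"])
  r
}

# Build a jet_structure from an atom table (internal; shared by the PDB
# reader and the synthetic-fixture generator). Required columns:
# type ("ATOM"/"HETATM"), chain, resno, insert, resid, elety, element, x, y, z.
as_jet_structure <- function(at, vdw = jet_vdw_radii()) {
  stopifnot(is.data.frame(at), nrow(at) > 0)
  at$insert[is.na(at$insert)] <- ""
  at$vdw <- .assign_vdw(at$element, vdw)
  is_water <- at$resid %in% .water_names
  is_het <- at$type == "HETATM" & !is_water
  prot <- at[at$type == "ATOM" & !is_water, , drop = FALSE]
  if (nrow(prot) == 0L) stop("structure contains no protein residues")
  prot$id <- .res_id(prot$chain, prot$resno, prot$insert)
  ids <- unique(prot$id)
  prot$res_index <- match(prot$id, ids)
  first <- !duplicated(prot$id)
  residues <- data.frame(
    id = prot$id[first], chain = prot$chain[first],
    resno = prot$resno[first], icode = prot$insert[first],
    aa3 = prot$resid[first], stringsAsFactors = FALSE
  )
  het <- at[is_het, , drop = FALSE]
  if (nrow(het)) het$group <- paste(het$chain, het$resno, het$resid, sep = ":")
  structure(
    list(atoms = prot, residues = residues, het = het,
         waters = at[is_water, , drop = FALSE]),
    class = "jet_structure"
  )
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records into a light-weight structure object holding
#' protein residues (heavy atoms only) and non-water heteroatom groups.
#' Alternate locations are resolved to the highest-occupancy conformer,
#' hydrogens are dropped, and waters are kept apart so they never enter
#' ligand-site definitions.
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector of chain identifiers to keep.
#' @param model Model number for multi-model files (default 1).
#' @param vdw Named vector of van der Waals radii, see [jet_vdw_radii()].
#' @return An object of class `"jet_structure"`: a list with data frames
#'   `atoms` (protein heavy atoms with coordinates and radii), `residues`
#'   (one row per residue, id = `"chain:resno:icode"`), `het` and `waters`.
#' @export
read_structure <- function(path, chains = NULL, model = 1, vdw = jet_vdw_radii()) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  multi <- model > 1
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (multi) {
    if (nrow(pdb$xyz) < model) stop("model ", model, " not present in file")
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at$chain[is.na(at$chain)] <- " "
  if (!is.null(chains)) {
    missing_ch <- setdiff(chains, unique(at$chain))
    if (length(missing_ch))
      stop("chain(s) not found in file: ", paste(missing_ch, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  at$element <- .element_of(at$elesy, at$elety)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  # resolve altlocs: keep highest occupancy per (chain, resno, insert, name)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  ord <- order(key, -at$o)
  keep <- ord[!duplicated(key[ord])]
  at <- at[sort(keep), , drop = FALSE]
  as_jet_structure(at[, c("type", "chain", "resno", "insert", "resid",
                          "elety", "element", "x", "y", "z")], vdw = vdw)
}

#' @export
print.jet_structure <- function(x, ...) {
  cat("Protein structure:", nrow(x$residues), "residues,",
      nrow(x$atoms), "heavy atoms,",
      length(unique(x$residues$chain)), "chain(s)\n")
  if (nrow(x$het))
    cat("Hetero groups:", paste(unique(x$het$group), collapse = ", "), "\n")
  invisible(x)
}

#' Residue identifiers of a structure
#' @param structure A `"jet_structure"`.
#' @return Character vector of `"chain:resno:icode"` identifiers.
#' @export
residue_ids <- function(structure) structure$residues$id

.atom_xyz <- function(df) as.matrix(df[, c("x", "y", "z")])

# squared distances between two coordinate sets, blocked for memory
.cross_dist2 <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Residue neighbor graph at a heavy-atom distance cutoff
#'
#' Two residues are connected when any pair of their heavy atoms lies
#' strictly closer than `cutoff` Angstrom. This 5 Angstrom adjacency is the
#' single notion of proximity used by conservation smoothing, seed grouping,
#' cluster extension and patch merging.
#'
#' @param structure A `"jet_structure"`.
#' @param cutoff Distance cutoff in Angstrom (strict inequality); default 5.
#' @return An object of class `"jet_graph"`: list with `ids`, integer `edges`
#'   matrix (2 columns, i < j), adjacency list `adj`, and `cutoff`.
#' @export
neighbor_graph <- function(structure, cutoff = 5) {
  stopifnot(cutoff > 0)
  xyz <- .atom_xyz(structure$atoms)
  ridx <- structure$atoms$res_index
  n_res <- nrow(structure$residues)
  n <- nrow(xyz)
  pairs_list <- list()
  block <- 2000L
  starts <- seq(1L, n, by = block)
  for (si in starts) {
    ia <- si:min(si + block - 1L, n)
    for (sj in starts[starts >= si]) {
      ib <- sj:min(sj + block - 1L, n)
      d2 <- .cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        gi <- ia[hit[, 1]]; gj <- ib[hit[, 2]]
        ok <- gi < gj
        if (any(ok))
          pairs_list[[length(pairs_list) + 1L]] <-
            cbind(ridx[gi[ok]], ridx[gj[ok]])
      }
    }
  }
  edges <- if (length(pairs_list)) do.call(rbind, pairs_list) else
    matrix(integer(0), ncol = 2)
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  }
  adj <- vector("list", n_res)
  for (k in seq_len(n_res)) adj[[k]] <- integer(0)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  structure(list(ids = structure$residues$id, n = n_res,
                 edges = edges, adj = adj, cutoff = cutoff),
            class = "jet_graph")
}

#' @export
print.jet_graph <- function(x, ...) {
  cat("Residue neighbor graph:", x$n, "residues,", nrow(x$edges),
      "edges at <", x$cutoff, "Angstrom\n")
  invisible(x)
}

# indices of graph neighbors of a set of residue indices (excluding the set)
.graph_neighbors <- function(graph, members) {
  nb <- unique(unlist(graph$adj[members], use.names = FALSE))
  setdiff(nb, members)
}

# connected components of an induced subgraph; returns list of index vectors
.components_of <- function(graph, members) {
  if (length(members) == 0L) return(list())
  sub <- graph$edges[graph$edges[, 1] %in% members &
                       graph$edges[, 2] %in% members, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(sub[, 1]), to = as.character(sub[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(members))
  )
  comp <- igraph::components(g)
  split(members[match(names(comp$membership), as.character(members))],
        comp$membership)
}

# minimum heavy-atom distance matrix between selected residues
.residue_min_dist <- function(structure, ids) {
  idx <- match(ids, structure$residues$id)
  if (anyNA(idx)) stop("unknown residue id(s)")
  n <- length(ids)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  coords <- lapply(idx, function(i)
    .atom_xyz(structure$atoms[structure$atoms$res_index == i, , drop = FALSE]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt(min(.cross_dist2(coords[[i]], coords[[j]])))
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}
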