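# Evaluation machinery: support/core/rim decomposition of experimental
# interfaces, small-ligand sites, confusion metrics with expected-value
# baselines, patch overlap and multi-patch classification.

.subset_structure <- function(structure, chains) {
  at <- structure$atoms[structure$atoms$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms for chain(s): ", paste(chains, collapse = ", "))
  as_jet_structure(at[, c("type", "chain", "resno", "insert", "resid",
                          "elety", "element", "x", "y", "z")])
}

#' Experimental interface with support / core / rim decomposition
#'
#' Defines the interface of one side of a complex from relative-accessibility
#' changes between the chain(s) taken alone (unbound, rasa_u) and within the
#' full complex (bound, rasa_b). Residues losing accessibility upon binding
#' form the interface; at the 0.25 threshold they split into *support*
#' (buried before and after binding), *core* (exposed before, buried after)
#' and *rim* (exposed before and after).
#'
#' @param complex A `"jet_structure"` holding all chains of the complex.
#' @param side Chain id(s) whose interface is computed.
#' @param partner Chain id(s) of the binding partner (disjoint from `side`).
#' @param probe Probe radius (default 1.4).
#' @param n_points SASA quadrature points (default 256).
#' @param tol Minimum rasa loss counting as burial (default 1e-6).
#' @param max_asa Reference ASA table.
#' @return Object of class `"scr_interface"`: data frame `residues` (id,
#'   aa3, rasa_u, rasa_b, region) plus sets `interface`, `support`, `core`,
#'   `rim`.
#' @export
scr_interface <- function(complex, side, partner, probe = 1.4,
                          n_points = 256L, tol = 1e-6,
                          max_asa = jet_max_asa()) {
  if (length(intersect(side, partner)))
    stop("side and partner chain sets overlap")
  unbound <- .subset_structure(complex, side)
  bound <- .subset_structure(complex, c(side, partner))
  asa_u <- compute_sasa(unbound, probe = probe, n_points = n_points)$residue
  asa_b_all <- compute_sasa(bound, probe = probe, n_points = n_points)$residue
  ids <- names(asa_u)
  asa_b <- asa_b_all[ids]
  aa3 <- unbound$residues$aa3
  rasa_u <- compute_rasa(asa_u, aa3, reference = max_asa)
  rasa_b <- compute_rasa(asa_b, aa3, reference = max_asa)
  iface <- (rasa_u - rasa_b) > tol
  region <- scr_region(rasa_u, rasa_b, iface)
  tab <- data.frame(id = ids, aa3 = aa3, rasa_u = unname(rasa_u),
                    rasa_b = unname(rasa_b), region = region,
                    stringsAsFactors = FALSE)
  structure(list(residues = tab,
                 interface = ids[iface],
                 support = ids[!is.na(region) & region == "support"],
                 core = ids[!is.na(region) & region == "core"],
                 rim = ids[!is.na(region) & region == "rim"]),
            class = "scr_interface")
}

#' Support / core / rim classification rule
#'
#' Classifies interface residues from their relative accessibilities before
#' (`rasa_u`) and after (`rasa_b`) binding at the 0.25 threshold: support =
#' buried in both states, core = becomes buried on binding, rim = exposed
#' in both. The fourth combination (buried before, exposed after) cannot
#' arise for a residue that loses accessibility on binding and raises a
#' data warning.
#'
#' @param rasa_u,rasa_b Numeric vectors of relative accessibilities.
#' @param iface Logical vector marking interface residues; non-interface
#'   positions get NA.
#' @return Character vector: `"support"`, `"core"`, `"rim"` or NA.
#' @export
scr_region <- function(rasa_u, rasa_b, iface = rep(TRUE, length(rasa_u))) {
  region <- rep(NA_character_, length(rasa_u))
  region[iface & rasa_u < 0.25 & rasa_b < 0.25] <- "support"
  region[iface & rasa_u >= 0.25 & rasa_b < 0.25] <- "core"
  region[iface & rasa_u >= 0.25 & rasa_b >= 0.25] <- "rim"
  impossible <- iface & rasa_u < 0.25 & rasa_b >= 0.25
  if (any(impossible)) {
    warning(sum(impossible), " interface residue(s) gained relative burial ",
            "class upon binding (rasa_u < 0.25 <= rasa_b); check input data")
    region[impossible] <- "rim"
  }
  region
}

#' @export
print.scr_interface <- function(x, ...) {
  cat("Experimental interface:", length(x$interface), "residues (",
      length(x$support), "support /", length(x$core), "core /",
      length(x$rim), "rim )\n")
  invisible(x)
}

#' Residues forming a small-ligand binding site
#'
#' All protein residues with a heavy atom strictly closer than `cutoff`
#' Angstrom to any atom of the hetero group. Waters are never treated as
#' ligands.
#'
#' @param structure A `"jet_structure"` with a non-empty `het` table.
#' @param group Hetero-group identifier (`"chain:resno:resname"`); default
#'   all non-water hetero atoms.
#' @param cutoff Distance cutoff in Angstrom (default 5, strict).
#' @return Character vector of residue ids.
#' @export
ligand_site <- function(structure, group = NULL, cutoff = 5) {
  het <- structure$het
  if (!is.null(group)) het <- het[het$group %in% group, , drop = FALSE]
  if (nrow(het) == 0L) stop("no (matching) hetero group in structure")
  d2 <- .cross_dist2(.atom_xyz(structure$atoms), .atom_xyz(het))
  near <- apply(d2, 1, min) < cutoff^2
  sort(unique(structure$atoms$id[near]))
}

#' Confusion metrics with expected-value baselines
#'
#' Scores a predicted residue set against an experimental truth set over
#' the surface-residue universe. Beyond sensitivity, specificity, accuracy
#' and precision, it reports the values expected for a random prediction of
#' the same size (coverage C = P/N): Sens_exp = C, Spe_exp = 1-C,
#' PPV_exp = S/N, Acc_exp = (1-C)(1-S/N) + C*S/N, and the differences
#' observed - expected (ScSens, ScSpe, ScPPV, ScAcc). Ratios with a zero
#' denominator are NA, never silently zero.
#'
#' @param predicted Character vector of predicted residue ids (subset of
#'   `surface`).
#' @param truth Character vector of true interface residue ids (subset of
#'   `surface`).
#' @param surface Character vector: the surface-residue universe.
#' @return Object of class `"jet_eval"`: a list with TP, TN, FP, FN, Sens,
#'   Spe, Acc, PPV, the *_exp baselines, Sc* scores, and sizes N, S, P, C.
#' @export
score_prediction <- function(predicted, truth, surface) {
  predicted <- unique(predicted); truth <- unique(truth)
  surface <- unique(surface)
  if (length(setdiff(predicted, surface)))
    stop("predicted set contains non-surface residues")
  if (length(setdiff(truth, surface)))
    stop("truth set contains non-surface residues")
  N <- length(surface)
  pos <- surface %in% truth
  pred <- surface %in% predicted
  TP <- sum(pred & pos); FP <- sum(pred & !pos)
  FN <- sum(!pred & pos); TN <- sum(!pred & !pos)
  S <- length(truth); P <- length(predicted); C <- P / N
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  Sens <- ratio(TP, TP + FN); Spe <- ratio(TN, TN + FP)
  PPV <- ratio(TP, TP + FP); Acc <- ratio(TP + TN, N)
  s_frac <- S / N
  out <- list(TP = TP, TN = TN, FP = FP, FN = FN,
              Sens = Sens, Spe = Spe, Acc = Acc, PPV = PPV,
              Sens_exp = C, Spe_exp = 1 - C, PPV_exp = s_frac,
              Acc_exp = (1 - C) * (1 - s_frac) + C * s_frac,
              N = N, S = S, P = P, C = C)
  out$ScSens <- Sens - out$Sens_exp
  out$ScSpe <- Spe - out$Spe_exp
  out$ScPPV <- PPV - out$PPV_exp
  out$ScAcc <- Acc - out$Acc_exp
  class(out) <- "jet_eval"
  out
}

#' @export
print.jet_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  (N = %d surface residues)\n",
              x$TP, x$FP, x$FN, x$TN, x$N))
  cat(sprintf("Sens %.3f (exp %.3f)  PPV %.3f (exp %.3f)\n",
              x$Sens, x$Sens_exp, x$PPV, x$PPV_exp))
  cat(sprintf("Spe  %.3f (exp %.3f)  Acc %.3f (exp %.3f)\n",
              x$Spe, x$Spe_exp, x$Acc, x$Acc_exp))
  invisible(x)
}

#' Asymmetric overlap between two predicted patches
#'
#' Fraction of the residues of `pred_i` that also belong to `pred_j`.
#'
#' @param pred_i Non-empty character vector of residue ids.
#' @param pred_j Character vector of residue ids.
#' @return Overlap fraction in [0,1].
#' @export
patch_overlap <- function(pred_i, pred_j) {
  pred_i <- unique(pred_i)
  if (length(pred_i) == 0L) stop("pred_i is empty")
  length(intersect(pred_i, unique(pred_j))) / length(pred_i)
}

#' Is a two-round prediction a multi-patch site?
#'
#' TRUE when the second clustering round added at least `min_added`
#' residues and those additions represent more than `min_fraction` of the
#' whole predicted site.
#'
#' @param prediction A `"jet2"` object fitted with `rounds = 2`.
#' @param min_added Minimum number of second-round residues (default 5).
#' @param min_fraction Minimum added fraction of the site (default 0.25,
#'   strict).
#' @return Logical flag.
#' @export
is_multipatch <- function(prediction, min_added = 5L, min_fraction = 0.25) {
  stopifnot(inherits(prediction, "jet2"))
  if (prediction$rounds != 2)
    stop("multi-patch classification needs a two-round prediction")
  tab <- prediction$residues
  all_ids <- unique(tab$id)
  round1 <- unique(tab$id[tab$round == 1])
  added <- setdiff(all_ids, round1)
  length(added) >= min_added &&
    length(added) / length(all_ids) > min_fraction
}

#' Geometric decomposition of an experimental interface into patches
#'
#' Average-linkage hierarchical clustering on minimum heavy-atom
#' inter-residue distances, cut at `h` Angstrom (default 20), separates an
#' interface into its recognition patches.
#'
#' @param interface Character vector of interface residue ids.
#' @param structure The `"jet_structure"` the residues belong to.
#' @param h Tree cut height in Angstrom (default 20).
#' @return Named integer vector of patch labels (1, 2, ...) keyed by
#'   residue id.
#' @export
interface_patches <- function(interface, structure, h = 20) {
  interface <- unique(interface)
  if (length(interface) == 0L) stop("empty interface")
  if (length(interface) == 1L)
    return(stats::setNames(1L, interface))
  dm <- .residue_min_dist(structure, interface)
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  stats::cutree(hc, h = h)
}
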