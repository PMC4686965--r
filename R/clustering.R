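# Patch clustering: thresholds from the expected interface size, greedy
# seed detection, gradient-constrained extension, one-pass outer layer,
# proximity merging.

#' Expected interface fraction of the protein surface
#'
#' Empirical size law for protein interfaces: the fraction of surface
#' residues expected to belong to an interface is 26.54/N + 0.03 for a
#' surface of N residues, capped at 1.
#'
#' @param n_surface Number of surface residues (>= 1).
#' @return Expected interface fraction in (0, 1].
#' @export
expected_interface_fraction <- function(n_surface) {
  stopifnot(n_surface >= 1)
  pmin(26.54 / n_surface + 0.03, 1)
}

# threshold at confidence level c: the score above which a fraction c of the
# distribution lies, i.e. the (1-c) empirical quantile (linear interpolation
# between order statistics); c clipped into (0, 1].
.confidence_threshold <- function(scores, c) {
  c <- min(max(c, 1e-12), 1)
  stats::quantile(scores, probs = 1 - c, type = 7, names = FALSE)
}

#' Clustering score thresholds
#'
#' Derives the three score cutoffs used by the clustering algorithm from
#' the empirical distribution of surface scores: `score_res_cut` at
#' confidence 2*f (residue admission), `score_clus_cut_seed` at f/4 (stop
#' of seed construction) and `score_clus_cut_ext` at f/2 (stop of cluster
#' extension), with f the expected interface fraction.
#'
#' @param scores Numeric score vector; NA entries (buried residues) are
#'   dropped.
#' @param n_surface Number of surface residues used for f; default the
#'   number of non-NA scores.
#' @return List of class `"jet_thresholds"` with `score_res_cut`,
#'   `score_clus_cut_seed`, `score_clus_cut_ext`, `n_surface`, `f_intfrac`.
#' @export
compute_thresholds <- function(scores, n_surface = NULL) {
  s <- scores[!is.na(scores)]
  if (length(s) == 0L) stop("no scores to compute thresholds from")
  if (is.null(n_surface)) n_surface <- length(s)
  f <- expected_interface_fraction(n_surface)
  structure(list(
    score_res_cut = .confidence_threshold(s, 2 * f),
    score_clus_cut_seed = .confidence_threshold(s, f / 4),
    score_clus_cut_ext = .confidence_threshold(s, f / 2),
    n_surface = n_surface, f_intfrac = f
  ), class = "jet_thresholds")
}

.new_patch <- function(seed, scheme, round_index = 1L) {
  structure(list(seed = seed, extension = character(0), outer = character(0),
                 scheme = scheme, round_index = round_index,
                 mean_score = NA_real_),
            class = "jet_patch")
}

#' @export
print.jet_patch <- function(x, ...) {
  cat(sprintf("Patch [%s, round %d]: %d seed / %d extension / %d outer\n",
              paste(x$scheme, collapse = "+"), x$round_index,
              length(x$seed), length(x$extension), length(x$outer)))
  invisible(x)
}

patch_members <- function(patch) c(patch$seed, patch$extension, patch$outer)

#' Detect cluster seeds
#'
#' Surface residues are visited in descending score order (score ties broken
#' at random) and accreted while each residue scores strictly above
#' `score_res_cut` and the running mean of the selected set stays above
#' `score_clus_cut_seed`. The selected residues are then split into
#' connected components of the 5 Angstrom adjacency graph; components
#' smaller than `min_seed_size` are discarded.
#'
#' @param scores Named layer score vector (NA off-surface).
#' @param graph A `"jet_graph"`.
#' @param thresholds A `"jet_thresholds"` object for these scores.
#' @param min_seed_size Minimum seed component size (default 3).
#' @param scheme Scheme label recorded on the patches.
#' @return List of `"jet_patch"` objects with only the seed layer filled;
#'   may be empty.
#' @export
detect_seeds <- function(scores, graph, thresholds, min_seed_size = 3L,
                         scheme = "SC1") {
  surf <- which(!is.na(scores))
  if (length(surf) == 0L) return(list())
  s <- scores[surf]
  ord <- surf[order(-s, stats::runif(length(s)))]
  selected <- integer(0)
  running_sum <- 0
  for (i in ord) {
    sc <- scores[i]
    if (sc <= thresholds$score_res_cut) break
    if ((running_sum + sc) / (length(selected) + 1) >
        thresholds$score_clus_cut_seed) {
      selected <- c(selected, i)
      running_sum <- running_sum + sc
    } else break
  }
  comps <- .components_of(graph, selected)
  comps <- comps[vapply(comps, length, 1L) >= min_seed_size]
  lapply(unname(comps), function(m) {
    p <- .new_patch(graph$ids[sort(m)], scheme)
    p$mean_score <- mean(scores[m])
    p
  })
}

#' Extend a cluster down the score gradient
#'
#' Iteratively grows a patch: at each iteration the neighbours (within
#' 5 Angstrom) of the current cluster whose scores lie strictly between
#' `score_res_cut` and the maximum score of the previous batch (`scoreMax`)
#' are added, and `scoreMax` is reset to the maximum over the new batch.
#' The loop stops when the cluster mean score reaches down
#' `score_clus_cut_ext` or no admissible neighbour remains. This enforces
#' the decreasing conservation/propensity gradient observed from the
#' support to the rim of experimental interfaces.
#'
#' @param patch A `"jet_patch"` with a non-empty seed.
#' @param scores Extension-layer score vector for the patch's scheme.
#' @param graph A `"jet_graph"`.
#' @param thresholds Thresholds computed from `scores`.
#' @return The patch with its `extension` layer filled.
#' @export
extend_cluster <- function(patch, scores, graph, thresholds) {
  members <- match(patch_members(patch), graph$ids)
  score_max <- max(scores[members])
  repeat {
    if (mean(scores[members]) <= thresholds$score_clus_cut_ext) break
    nb <- .graph_neighbors(graph, members)
    nb <- nb[!is.na(scores[nb])]
    new_res <- nb[scores[nb] > thresholds$score_res_cut &
                    scores[nb] < score_max]
    if (length(new_res) == 0L) break
    members <- c(members, new_res)
    patch$extension <- c(patch$extension, graph$ids[sort(new_res)])
    score_max <- max(scores[new_res])
  }
  patch$mean_score <- mean(scores[members])
  patch
}

#' Add the outer layer to a cluster
#'
#' One single pass over the current neighbours of the cluster: a residue is
#' included iff adding it would keep the mean cluster score (under the
#' outer-layer scoring, which combines propensity and protrusion) at least
#' as high as before, i.e. iff its score is >= the cluster mean. The mean is
#' computed once over the members present before the pass. This step picks
#' up the protruding loops that typically form the rim of an interface.
#'
#' @param patch A `"jet_patch"`.
#' @param outer_scores Outer-layer score vector.
#' @param graph A `"jet_graph"`.
#' @return The patch with its `outer` layer filled.
#' @export
add_outer_layer <- function(patch, outer_scores, graph) {
  members <- match(patch_members(patch), graph$ids)
  mu <- mean(outer_scores[members], na.rm = TRUE)
  nb <- .graph_neighbors(graph, members)
  nb <- nb[!is.na(outer_scores[nb])]
  add <- nb[outer_scores[nb] >= mu]
  patch$outer <- graph$ids[sort(add)]
  patch$mean_score <- mean(outer_scores[c(members, add)], na.rm = TRUE)
  patch
}

#' Merge patches closer than the graph cutoff
#'
#' Computes the transitive closure of the "some residue pair within
#' 5 Angstrom" relation between patches and fuses each group into one patch,
#' preserving per-layer membership (a residue seeded in one patch stays a
#' seed residue of the merged patch) and recording every contributing
#' scheme.
#'
#' @param patches List of `"jet_patch"` objects.
#' @param graph A `"jet_graph"`.
#' @return List of merged `"jet_patch"` objects.
#' @export
merge_patches <- function(patches, graph) {
  k <- length(patches)
  if (k <= 1L) return(patches)
  member_idx <- lapply(patches, function(p) match(patch_members(p), graph$ids))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) {
    nbi <- unique(c(member_idx[[i]],
                    unlist(graph$adj[member_idx[[i]]], use.names = FALSE)))
    for (j in (i + 1L):k) {
      if (length(intersect(nbi, member_idx[[j]]))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  out <- lapply(unique(roots), function(r) {
    grp <- patches[roots == r]
    seed <- sort(unique(unlist(lapply(grp, `[[`, "seed"))))
    ext <- setdiff(sort(unique(unlist(lapply(grp, `[[`, "extension")))), seed)
    outer <- setdiff(sort(unique(unlist(lapply(grp, `[[`, "outer")))),
                     c(seed, ext))
    p <- .new_patch(seed, sort(unique(unlist(lapply(grp, `[[`, "scheme")))),
                    min(vapply(grp, `[[`, 1L, "round_index")))
    p$extension <- ext
    p$outer <- outer
    p$mean_score <- mean(vapply(grp, `[[`, 1, "mean_score"))
    p
  })
  out
}
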