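# Orchestration: automated scheme selection, single prediction runs with one
# or two clustering rounds, and the iterative consensus mode.

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

.cv_mode_for <- function(scheme, is_main) {
  if (scheme == "SC3" && is_main) "global" else "local"
}

#' Automatic choice of the main scoring scheme
#'
#' Implements the first-round decision cascade: (1) if the proportion of
#' surface residues with scaled conservation above 0.6 is below 0.3 times
#' the expected interface fraction, the evolutionary signal is too weak and
#' SC3 is chosen; (2) otherwise SC1 seed detection is attempted, and an
#' empty result switches to SC3; (3) if every SC1 seed has a score
#' dispersion-to-mean ratio below one sixth of the surface-wide ratio the
#' conservation signal is suspiciously homogeneous (a small-ligand pocket)
#' and SC2 is chosen; (4) otherwise SC1 is kept.
#'
#' @param desc A `"jet_descriptors"` table.
#' @param graph A `"jet_graph"`; default taken from `desc`.
#' @param min_seed_size Passed to [detect_seeds()].
#' @param jitter_sd Uniform jitter amplitude on seed scores (see [jet2()]).
#' @return List with `scheme` and `trace`, a data frame recording each
#'   evaluated predicate with its value and verdict.
#' @export
select_main_scheme <- function(desc, graph = attr(desc, "graph"),
                               min_seed_size = 3L, jitter_sd = 0) {
  surf <- desc$is_surface
  n_surf <- sum(surf)
  f <- expected_interface_fraction(n_surf)
  tj <- desc$tjet[surf]
  prop_conserved <- if (all(is.na(tj))) 0 else mean(tj > 0.6, na.rm = TRUE)
  trace <- data.frame(
    predicate = "prop(T_JET > 0.6) < 0.3 * f_intfrac",
    value = prop_conserved, threshold = 0.3 * f,
    result = prop_conserved < 0.3 * f, stringsAsFactors = FALSE
  )
  if (prop_conserved < 0.3 * f)
    return(list(scheme = "SC3", trace = trace))
  seed_scores <- .jittered(layer_score("SC1", "seed", desc, "local"), jitter_sd)
  th <- compute_thresholds(seed_scores, n_surf)
  seeds <- detect_seeds(seed_scores, graph, th, min_seed_size, scheme = "SC1")
  trace <- rbind(trace, data.frame(
    predicate = "SC1 seeds found", value = length(seeds), threshold = 1,
    result = length(seeds) >= 1
  ))
  if (length(seeds) == 0L)
    return(list(scheme = "SC3", trace = trace))
  surf_scores <- seed_scores[!is.na(seed_scores)]
  ratio_surf <- .pop_sd(surf_scores) / mean(surf_scores)
  ratios <- vapply(seeds, function(p) {
    s <- seed_scores[p$seed]
    .pop_sd(s) / mean(s)
  }, 1.0)
  homogeneous <- all(ratios < ratio_surf / 6)
  trace <- rbind(trace, data.frame(
    predicate = "all seeds: sd/mean < (1/6) * surface sd/mean",
    value = max(ratios), threshold = ratio_surf / 6, result = homogeneous
  ))
  list(scheme = if (homogeneous) "SC2" else "SC1", trace = trace)
}

.jittered <- function(scores, jitter_sd) {
  if (jitter_sd <= 0) return(scores)
  ok <- !is.na(scores)
  scores[ok] <- pmin(1, pmax(0, scores[ok] +
    stats::runif(sum(ok), -jitter_sd, jitter_sd)))
  scores
}

# one full clustering round under a fixed scheme
.run_round <- function(scheme, desc, graph, steps, is_main, round_index,
                       min_seed_size, jitter_sd) {
  n_surf <- sum(desc$is_surface)
  cv_mode <- .cv_mode_for(scheme, is_main)
  seed_scores <- .jittered(layer_score(scheme, "seed", desc, cv_mode),
                           jitter_sd)
  th_seed <- compute_thresholds(seed_scores, n_surf)
  patches <- detect_seeds(seed_scores, graph, th_seed, min_seed_size,
                          scheme = scheme)
  patches <- lapply(patches, function(p) { p$round_index <- round_index; p })
  if (steps == "seed" || length(patches) == 0L) return(patches)
  ext_scores <- layer_score(scheme, "extension", desc, cv_mode)
  th_ext <- compute_thresholds(ext_scores, n_surf)
  patches <- lapply(patches, extend_cluster, scores = ext_scores,
                    graph = graph, thresholds = th_ext)
  patches <- merge_patches(patches, graph)
  if (steps == "seed+ext") return(patches)
  outer_mode <- if (scheme == "SC3" && is_main) "global" else "local"
  outer_scores <- layer_score(scheme, "outer", desc, outer_mode)
  lapply(patches, add_outer_layer, outer_scores = outer_scores, graph = graph)
}

#' Predict protein-protein interface patches on a single structure
#'
#' The main fitting function. Scores every surface residue with a scoring
#' scheme (chosen automatically by default), grows patches through seed
#' detection, gradient-constrained extension and an outer layer of
#' protruding residues, and optionally runs a second round with a
#' complementary scheme (SC3 after SC1/SC2, SC2 after SC3) whose patches
#' are fused with first-round patches when closer than 5 Angstrom and kept
#' as separate sites otherwise.
#'
#' @param structure A `"jet_structure"` (see [read_structure()]).
#' @param conservation Conservation input passed to [residue_descriptors()];
#'   ignored when `desc` is supplied.
#' @param mode `"auto"` or a forced scheme `"SC1"`/`"SC2"`/`"SC3"`.
#' @param rounds 1 or 2 clustering rounds (default 2, the complete
#'   procedure).
#' @param steps `"full"`, `"seed+ext"` or `"seed"`: truncates each round.
#' @param seed Integer RNG seed for tie-breaking and score jitter;
#'   `NULL` leaves the RNG state untouched.
#' @param jitter Add uniform score jitter of amplitude `jitter_sd` before
#'   seed detection (default TRUE). Repeated jittered runs emulate the
#'   run-to-run variability of trace computation and feed the consensus
#'   mode.
#' @param jitter_sd Jitter amplitude (default 0.01).
#' @param min_seed_size Minimum seed size in residues (default 3).
#' @param desc Optional precomputed `"jet_descriptors"` (avoids recomputing
#'   accessibility and circular variance across repeated runs).
#' @param graph Optional precomputed `"jet_graph"`.
#' @return Object of class `"jet2"`: list with `patches`, `residues` (data
#'   frame id/patch/layer/scheme/round), `main_scheme`,
#'   `complementary_scheme`, `decision_trace`, `run_seed`, and the
#'   descriptor table.
#' @export
jet2 <- function(structure, conservation = NULL, mode = c("auto", "SC1", "SC2", "SC3"),
                 rounds = 2, steps = c("full", "seed+ext", "seed"),
                 seed = NULL, jitter = TRUE, jitter_sd = 0.01,
                 min_seed_size = 3L, desc = NULL, graph = NULL, ...) {
  mode <- match.arg(mode)
  steps <- match.arg(steps)
  stopifnot(rounds %in% c(1, 2))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(desc))
    desc <- residue_descriptors(structure, conservation, graph = graph, ...)
  if (is.null(graph)) graph <- attr(desc, "graph")
  jsd <- if (jitter) jitter_sd else 0
  if (mode == "auto") {
    sel <- select_main_scheme(desc, graph, min_seed_size, jitter_sd = jsd)
    main <- sel$scheme
    trace <- sel$trace
  } else {
    main <- mode
    trace <- data.frame(predicate = "manual mode", value = NA_real_,
                        threshold = NA_real_, result = NA)
  }
  patches <- .run_round(main, desc, graph, steps, is_main = TRUE,
                        round_index = 1L, min_seed_size, jsd)
  comp <- NULL
  if (rounds == 2) {
    comp <- if (main %in% c("SC1", "SC2")) "SC3" else "SC2"
    comp_ok <- !(comp == "SC2" && all(is.na(desc$tjet[desc$is_surface])))
    if (comp_ok) {
      patches2 <- .run_round(comp, desc, graph, steps, is_main = FALSE,
                             round_index = 2L, min_seed_size, jsd)
      patches <- merge_patches(c(patches, patches2), graph)
    }
  }
  res_tab <- .patch_table(patches)
  structure(list(patches = patches, residues = res_tab,
                 main_scheme = main, complementary_scheme = comp,
                 decision_trace = trace, run_seed = seed,
                 desc = desc, graph = graph, steps = steps, rounds = rounds),
            class = "jet2")
}

.patch_table <- function(patches) {
  if (length(patches) == 0L)
    return(data.frame(id = character(0), patch = integer(0),
                      layer = character(0), scheme = character(0),
                      round = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(patches), function(k) {
    p <- patches[[k]]
    ids <- c(p$seed, p$extension, p$outer)
    data.frame(id = ids, patch = k,
               layer = rep(c("seed", "extension", "outer"),
                           c(length(p$seed), length(p$extension),
                             length(p$outer))),
               scheme = paste(p$scheme, collapse = "+"),
               round = p$round_index, stringsAsFactors = FALSE)
  }))
}

#' Residues predicted by a run or consensus
#' @param x A `"jet2"` or `"ijet2"` object.
#' @return Character vector of predicted residue ids.
#' @export
predicted_residues <- function(x) {
  if (inherits(x, "ijet2")) return(x$members)
  unique(x$residues$id)
}

#' @export
print.jet2 <- function(x, ...) {
  cat("Interface prediction (", x$rounds, "round(s), steps =", x$steps, ")\n")
  cat("Main scheme:", x$main_scheme,
      if (!is.null(x$complementary_scheme))
        paste0("(complementary: ", x$complementary_scheme, ")"), "\n")
  cat(length(x$patches), "patch(es),",
      length(predicted_residues(x)), "residues predicted of",
      sum(x$desc$is_surface), "surface residues\n")
  invisible(x)
}

#' @export
summary.jet2 <- function(object, ...) {
  cat("Decision trace:\n")
  print(object$decision_trace, row.names = FALSE)
  cat("\nPatches:\n")
  for (p in object$patches) print(p)
  invisible(object)
}

#' Plot a prediction
#'
#' Projects residue coordinates on their first two principal axes and marks
#' patch membership by colour and layer by symbol.
#'
#' @param x A `"jet2"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.jet2 <- function(x, ...) {
  tab <- x$residues
  surf_scores <- layer_score(x$main_scheme, "seed", x$desc,
                             .cv_mode_for(x$main_scheme, TRUE))
  graphics::plot(surf_scores[!is.na(surf_scores)],
                 col = ifelse(names(surf_scores[!is.na(surf_scores)]) %in%
                                tab$id, "firebrick", "grey60"),
                 pch = 16, xlab = "surface residue (index)",
                 ylab = paste(x$main_scheme, "seed score"), ...)
  graphics::legend("topright", legend = c("predicted", "other"),
                   col = c("firebrick", "grey60"), pch = 16, bty = "n")
  invisible(x)
}

#' Iterative consensus prediction
#'
#' Runs [jet2()] `n_runs` times with derived seeds (base seed + run
#' counter), counts for every residue the fraction of runs in which it was
#' predicted, and thresholds the counts at `cutoff` runs to form the
#' consensus member set. Predictions are stable from a consensus of 2 runs
#' out of 10.
#'
#' @param structure A `"jet_structure"`.
#' @param conservation Conservation input (see [jet2()]).
#' @param n_runs Number of independent runs (default 10).
#' @param cutoff Minimum number of runs predicting a residue (default 2).
#' @param seed Base RNG seed (default 1).
#' @param ... Options forwarded to [jet2()].
#' @return Object of class `"ijet2"`: list with `frequency` (named, in
#'   [0,1]), `counts`, `members`, `n_runs`, `cutoff`, `runs` (per-run
#'   predicted sets) and `schemes` (main scheme per run).
#' @export
ijet2 <- function(structure, conservation = NULL, n_runs = 10, cutoff = 2,
                  seed = 1, ...) {
  stopifnot(cutoff >= 1, cutoff <= n_runs)
  desc <- residue_descriptors(structure, conservation)
  graph <- attr(desc, "graph")
  counts <- stats::setNames(integer(nrow(desc)), desc$id)
  runs <- vector("list", n_runs)
  schemes <- character(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- jet2(structure, desc = desc, graph = graph,
                seed = as.integer(seed) + r - 1L, ...)
    ids <- predicted_residues(fit)
    counts[ids] <- counts[ids] + 1L
    runs[[r]] <- ids
    schemes[r] <- fit$main_scheme
  }
  structure(list(frequency = counts / n_runs, counts = counts,
                 members = names(counts)[counts >= cutoff],
                 n_runs = n_runs, cutoff = cutoff,
                 runs = runs, schemes = schemes, base_seed = seed),
            class = "ijet2")
}

#' @export
print.ijet2 <- function(x, ...) {
  cat("Consensus prediction over", x$n_runs, "runs (cutoff", x$cutoff, "runs)\n")
  cat(length(x$members), "consensus residues; schemes used:",
      paste(sprintf("%s x%d", names(table(x$schemes)), table(x$schemes)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Consensus member set at another cutoff
#' @param x An `"ijet2"` object.
#' @param cutoff Minimum number of runs.
#' @return Character vector of residue ids.
#' @export
consensus_members <- function(x, cutoff) {
  stopifnot(inherits(x, "ijet2"), cutoff >= 1, cutoff <= x$n_runs)
  names(x$counts)[x$counts >= cutoff]
}
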