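# The three scoring schemes. Each (scheme, layer) score is the unweighted
# arithmetic mean of scaled descriptors; 1-CV denotes the inverted scaled
# circular variance:
#   SC1  seed = T_JET          ext = mean(T_JET, PC)     outer = mean(PC, 1-CV)
#   SC2  seed = ext = mean(T_JET, 1-CV)                  outer = mean(PC, 1-CV)
#   SC3  seed = ext = outer = mean(PC, 1-CV)
# SC1 targets generic conserved interfaces, SC2 interfaces bordering
# small-ligand pockets, SC3 interfaces with little evolutionary signal.

.schemes <- c("SC1", "SC2", "SC3")
.layers <- c("seed", "extension", "outer")

#' Per-residue layer score for a scoring scheme
#'
#' @param scheme One of `"SC1"`, `"SC2"`, `"SC3"`.
#' @param layer One of `"seed"`, `"extension"`, `"outer"`.
#' @param desc A `"jet_descriptors"` table.
#' @param cv_mode `"local"` (r_c = 12) or `"global"` (r_c = 100). The global
#'   cutoff is used when SC3 is the main scheme, to capture protrusion at
#'   the whole-protein scale.
#' @return Named numeric vector over all residues; values in [0,1] on the
#'   surface, NA elsewhere. Attributes `scheme`, `layer`, `cv_mode` record
#'   provenance.
#' @export
layer_score <- function(scheme, layer, desc, cv_mode = c("local", "global")) {
  scheme <- match.arg(scheme, .schemes)
  layer <- match.arg(layer, .layers)
  cv_mode <- match.arg(cv_mode)
  cv <- if (cv_mode == "local") desc$cv_local else desc$cv_global
  inv_cv <- 1 - cv
  tjet <- desc$tjet
  pc <- desc$pc
  needs_tjet <- (scheme == "SC1" && layer != "outer") ||
    (scheme == "SC2" && layer != "outer")
  if (needs_tjet && all(is.na(tjet[desc$is_surface])))
    stop(scheme, "/", layer, " requires conservation values")
  s <- switch(scheme,
    SC1 = switch(layer,
      seed = tjet,
      extension = (tjet + pc) / 2,
      outer = (pc + inv_cv) / 2),
    SC2 = switch(layer,
      seed = (tjet + inv_cv) / 2,
      extension = (tjet + inv_cv) / 2,
      outer = (pc + inv_cv) / 2),
    SC3 = (pc + inv_cv) / 2
  )
  s[!desc$is_surface] <- NA_real_
  names(s) <- desc$id
  attr(s, "scheme") <- scheme
  attr(s, "layer") <- layer
  attr(s, "cv_mode") <- cv_mode
  s
}
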