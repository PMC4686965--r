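# Shared toy builders used across the suite.

# structure with one atom per residue at given centers
toy_structure <- function(centers, aa3 = "ALA", chain = "A") {
  n <- nrow(centers)
  as_jet_structure(data.frame(
    type = "ATOM", chain = chain, resno = seq_len(n), insert = "",
    resid = rep_len(aa3, n), elety = "CA", element = "C",
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    stringsAsFactors = FALSE
  ))
}

# thresholds object with explicit cut values
toy_thresholds <- function(res_cut, seed_cut, ext_cut, n_surface = 100) {
  structure(list(score_res_cut = res_cut, score_clus_cut_seed = seed_cut,
                 score_clus_cut_ext = ext_cut, n_surface = n_surface,
                 f_intfrac = expected_interface_fraction(n_surface)),
            class = "jet_thresholds")
}

# a seed-only patch for the clustering operations
toy_patch <- function(seed_ids, scheme = "SC1") {
  p <- list(seed = seed_ids, extension = character(0), outer = character(0),
            scheme = scheme, round_index = 1L, mean_score = NA_real_)
  class(p) <- "jet_patch"
  p
}

# minimal descriptor table for scheme-selection and scoring tests
toy_descriptors <- function(tjet, pc = NULL, cv = NULL, structure = NULL,
                            graph = NULL) {
  n <- length(tjet)
  if (is.null(pc)) pc <- rep(0.5, n)
  if (is.null(cv)) cv <- rep(0.5, n)
  d <- data.frame(
    id = if (!is.null(graph)) graph$ids else sprintf("A:%d:", seq_len(n)),
    chain = "A", resno = seq_len(n), icode = "", aa3 = "ALA",
    asa = 50, rasa = 0.5, is_surface = TRUE,
    d_raw = tjet, tjet = tjet, pc = pc, cv_local = cv, cv_global = cv,
    stringsAsFactors = FALSE
  )
  if (!is.null(graph)) attr(d, "graph") <- graph
  class(d) <- c("jet_descriptors", "data.frame")
  d
}

# brute-force per-atom circular variance (independent double loop)
oracle_cv <- function(xyz, r_c) {
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- c(0, 0, 0); ni <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      v <- xyz[j, ] - xyz[i, ]
      d <- sqrt(sum(v^2))
      if (d < r_c) { acc <- acc + v / d; ni <- ni + 1 }
    }
    out[i] <- if (ni == 0) 0 else 1 - sqrt(sum(acc^2)) / ni
  }
  out
}

# sort-based quantile with linear interpolation between order statistics
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
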