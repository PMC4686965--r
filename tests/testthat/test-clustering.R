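# Thresholds, seed detection, extension, outer layer and merging.

test_that("expected interface fraction follows the surface-size law", {
  expect_equal(expected_interface_fraction(100), 0.2954)
  expect_equal(expected_interface_fraction(2654), 0.04)
  expect_equal(expected_interface_fraction(10), 1)  # capped at 1
})

test_that("confidence thresholds are upper-tail quantiles", {
  s <- seq(0.01, 1, length.out = 100)
  # confidence 0.2 selects the top 20%: the 80th-percentile score
  expect_equal(.confidence_threshold(s, 0.2),
               unname(stats::quantile(s, 0.8)))
  # confidence >= 1 makes everything selectable
  expect_equal(.confidence_threshold(s, 1.3), min(s))
})

test_that("thresholds match a sort-based quantile oracle and are ordered", {
  set.seed(41)
  for (k in 1:25) {
    s <- stats::runif(sample(20:200, 1))
    n <- sample(30:500, 1)
    th <- compute_thresholds(s, n)
    f <- expected_interface_fraction(n)
    expect_equal(th$score_res_cut, oracle_quantile(s, 1 - min(2 * f, 1)))
    expect_equal(th$score_clus_cut_seed, oracle_quantile(s, 1 - f / 4))
    expect_equal(th$score_clus_cut_ext, oracle_quantile(s, 1 - f / 2))
    expect_true(th$score_res_cut <= th$score_clus_cut_ext + 1e-12)
    expect_true(th$score_clus_cut_ext <= th$score_clus_cut_seed + 1e-12)
  }
})

test_that("a smaller surface (larger f) never raises the residue cut", {
  set.seed(42)
  s <- stats::runif(120)
  expect_lte(compute_thresholds(s, 50)$score_res_cut,
             compute_thresholds(s, 400)$score_res_cut)
})

test_that("seed detection groups high scorers by proximity", {
  triad <- function(ctr) rbind(ctr, ctr + c(3, 0, 0), ctr + c(0, 3, 0))
  st <- toy_structure(rbind(triad(c(0, 0, 0)), triad(c(30, 0, 0)),
                            c(60, 0, 0), c(70, 0, 0)))
  g <- neighbor_graph(st, 5)
  th <- toy_thresholds(res_cut = 0.5, seed_cut = 0.9, ext_cut = 0.7)
  # nothing above the residue cut -> no seeds
  set.seed(1)
  expect_length(detect_seeds(stats::setNames(rep(0.2, 8), g$ids), g, th), 0)
  # one triad above -> one seed of size 3
  sc <- stats::setNames(c(rep(1, 3), rep(0.1, 5)), g$ids)
  set.seed(1)
  seeds <- detect_seeds(sc, g, th)
  expect_length(seeds, 1)
  expect_setequal(seeds[[1]]$seed, g$ids[1:3])
  # both triads above -> two seeds (20+ Angstrom apart)
  sc2 <- stats::setNames(c(rep(1, 6), 0.1, 0.1), g$ids)
  set.seed(1)
  seeds2 <- detect_seeds(sc2, g, th)
  expect_length(seeds2, 2)
  # components below min_seed_size are filtered
  set.seed(1)
  expect_length(detect_seeds(sc2, g, th, min_seed_size = 4L), 0)
})

test_that("a planted connected blob over zero background is recovered exactly", {
  fx <- synthetic_globule(n_residues = 100, patch_size = 5, seed = 6)
  st <- fx$structure
  g <- neighbor_graph(st, 5)
  blob <- fx$labels$id[fx$labels$label == "patch"]
  sc <- stats::setNames(ifelse(g$ids %in% blob, 1, 0), g$ids)
  th <- compute_thresholds(sc, length(sc))
  set.seed(2)
  seeds <- detect_seeds(sc, g, th)
  expect_length(seeds, 1)
  expect_setequal(seeds[[1]]$seed, blob)
})

test_that("extension follows the hand trace of the growth pseudocode", {
  # 6-residue path, adjacent residues 3 Angstrom apart
  st <- toy_structure(cbind(seq(0, 15, by = 3), 0, 0))
  g <- neighbor_graph(st, 5)
  sc <- stats::setNames(c(1.0, 0.9, 0.8, 0.7, 0.2, 0.1), g$ids)
  p <- toy_patch(g$ids[1])
  # res_cut 0.3 stops at residue 5; scoreMax gate admits 2, 3, 4 in turn
  got <- extend_cluster(p, sc, g, toy_thresholds(0.3, 0.95, 0.5))
  expect_equal(got$extension, g$ids[2:4])
  # higher mean cut stops the loop after two additions
  got2 <- extend_cluster(p, sc, g, toy_thresholds(0.3, 0.95, 0.92))
  expect_equal(got2$extension, g$ids[2:3])
  # no admissible neighbor: patch unchanged
  got3 <- extend_cluster(p, sc, g, toy_thresholds(0.95, 0.99, 0.5))
  expect_length(got3$extension, 0)
})

test_that("extension equals an independent step simulator and batch maxima decrease", {
  # literal re-implementation of the growth loop on explicit sets
  simulate_extension <- function(seed_idx, sc, g, res_cut, ext_cut) {
    C <- seed_idx
    score_max <- max(sc[C])
    batch_maxima <- numeric(0)
    repeat {
      if (mean(sc[C]) <= ext_cut) break
      nbr <- setdiff(unique(unlist(g$adj[C])), C)
      new_res <- nbr[sc[nbr] > res_cut & sc[nbr] < score_max]
      if (!length(new_res)) break
      C <- c(C, new_res)
      score_max <- max(sc[new_res])
      batch_maxima <- c(batch_maxima, score_max)
    }
    list(members = sort(C), maxima = batch_maxima)
  }
  set.seed(44)
  for (k in 1:10) {
    fx <- synthetic_globule(n_residues = 60, patch_size = 0, seed = 100 + k)
    g <- neighbor_graph(fx$structure, 5)
    sc <- stats::setNames(stats::runif(g$n), g$ids)
    seed_idx <- which.max(sc)
    ref <- simulate_extension(seed_idx, sc, g, res_cut = 0.2, ext_cut = 0.55)
    p <- extend_cluster(toy_patch(g$ids[seed_idx]), sc, g,
                        toy_thresholds(0.2, 0.99, 0.55))
    expect_setequal(c(p$seed, p$extension), g$ids[ref$members])
    if (length(ref$maxima) > 1)
      expect_true(all(diff(ref$maxima) < 0))
  }
})

test_that("outer layer adds residues scoring at least the cluster mean, one pass", {
  st <- toy_structure(cbind(c(-3, 0, 3, 6), 0, 0))  # path r3-r1-r2-r4
  g <- neighbor_graph(st, 5)
  p <- toy_patch(g$ids[2:3])
  outer <- stats::setNames(c(0.7, 0.8, 0.6, 0.65), g$ids)  # mu(C) = 0.7
  got <- add_outer_layer(p, outer, g)
  expect_equal(got$outer, g$ids[1])   # 0.7 >= 0.7 in; 0.65 out
  # the pass never lowers the mean outer score
  expect_gte(got$mean_score, mean(outer[2:3]))
})

test_that("outer-layer mean is fixed during the pass", {
  # both neighbors score >= the initial mean; a sequentially updated mean
  # would exclude the second one after admitting the first
  st <- toy_structure(cbind(c(0, 3, -3), 0, 0))
  g <- neighbor_graph(st, 5)
  p <- toy_patch(g$ids[1])
  outer <- stats::setNames(c(0.5, 0.9, 0.5), g$ids)
  got <- add_outer_layer(p, outer, g)
  expect_setequal(got$outer, g$ids[2:3])
})

test_that("patches merge transitively below the cutoff", {
  st <- toy_structure(cbind(c(0, 4, 8, 30), 0, 0))
  g <- neighbor_graph(st, 5)
  p <- lapply(g$ids, toy_patch)
  merged <- merge_patches(p[c(1, 2)], g)
  expect_length(merged, 1)                       # 4 Angstrom apart
  expect_length(merge_patches(p[c(1, 4)], g), 2) # 30 Angstrom apart
  chain <- merge_patches(p[1:3], g)              # 1-2, 2-3 close; 1-3 far
  expect_length(chain, 1)
  expect_setequal(chain[[1]]$seed, g$ids[1:3])
})

test_that("merging preserves layer membership with seed priority", {
  st <- toy_structure(cbind(c(0, 4), 0, 0))
  g <- neighbor_graph(st, 5)
  p1 <- toy_patch(g$ids[1], scheme = "SC1")
  p2 <- toy_patch(g$ids[2], scheme = "SC3")
  p2$extension <- g$ids[1]   # residue 1 is seed in p1, extension in p2
  m <- merge_patches(list(p1, p2), g)
  expect_length(m, 1)
  expect_setequal(m[[1]]$seed, g$ids)
  expect_length(m[[1]]$extension, 0)
  expect_setequal(m[[1]]$scheme, c("SC1", "SC3"))
})
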