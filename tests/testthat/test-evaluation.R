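# Experimental-interface definition, confusion metrics with expected-value
# baselines, overlap, multi-patch rule and geometric decomposition.

test_that("support/core/rim classification at the 0.25 thresholds", {
  expect_equal(scr_region(0.10, 0.05), "support")
  expect_equal(scr_region(0.40, 0.10), "core")
  expect_equal(scr_region(0.40, 0.30), "rim")
  expect_true(is.na(scr_region(0.40, 0.30, iface = FALSE)))
  expect_warning(scr_region(0.10, 0.40), "check input data")
})

test_that("the interface partitions exactly into support, core and rim", {
  cx <- synthetic_complex(n_a = 80, n_b = 60, seed = 2)
  for (side in list(c("A", "B"), c("B", "A"))) {
    scr <- scr_interface(cx$structure, side[1], side[2])
    expect_gt(length(scr$interface), 0)
    parts <- c(scr$support, scr$core, scr$rim)
    expect_setequal(parts, scr$interface)
    expect_equal(length(parts), length(scr$interface))  # pairwise disjoint
    tab <- scr$residues[scr$residues$id %in% scr$interface, ]
    expect_true(all(tab$rasa_u - tab$rasa_b > 0))
  }
  expect_error(scr_interface(cx$structure, "A", "A"), "overlap")
})

test_that("ligand sites use a strict 5 Angstrom heavy-atom rule", {
  # one residue at 4.9, one at exactly 5.0 from a single-atom ligand
  at <- data.frame(
    type = c("ATOM", "ATOM", "HETATM"), chain = "A", resno = c(1, 2, 9),
    insert = "", resid = c("GLY", "GLY", "LIG"), elety = c("CA", "CA", "C1"),
    element = "C", x = c(4.9, -5.0, 0), y = 0, z = 0, stringsAsFactors = FALSE)
  st <- as_jet_structure(at)
  expect_equal(ligand_site(st), "A:1:")
  fp <- fixture_preset("ligand-pocket", seed = 3)
  site <- ligand_site(fp$structure)
  # brute-force distance scan oracle
  het <- fp$structure$het
  d2 <- .cross_dist2(.atom_xyz(fp$structure$atoms), .atom_xyz(het))
  expected <- sort(unique(fp$structure$atoms$id[apply(d2, 1, min) < 25]))
  expect_identical(site, expected)
  st_noligand <- fixture_preset("flat", seed = 1)$structure
  expect_error(ligand_site(st_noligand), "hetero")
})

test_that("confusion metrics match hand arithmetic and brute force", {
  surface <- sprintf("r%d", 1:100)
  truth <- surface[1:10]
  ev <- score_prediction(truth, truth, surface)
  expect_equal(c(ev$Sens, ev$Spe, ev$Acc, ev$PPV), c(1, 1, 1, 1))
  # TP=5 FN=5 FP=5 TN=85
  ev2 <- score_prediction(c(surface[1:5], surface[11:15]), truth, surface)
  expect_equal(ev2$Sens, 0.5)
  expect_equal(ev2$PPV, 0.5)
  expect_equal(ev2$Spe, 85 / 90)
  expect_equal(ev2$Acc, 0.9)
  # random set pairs against per-residue label comparison
  set.seed(61)
  for (k in 1:20) {
    pred <- sample(surface, sample(0:40, 1))
    tr <- sample(surface, sample(1:30, 1))
    ev3 <- score_prediction(pred, tr, surface)
    lab_p <- surface %in% pred; lab_t <- surface %in% tr
    expect_equal(c(ev3$TP, ev3$FP, ev3$FN, ev3$TN),
                 c(sum(lab_p & lab_t), sum(lab_p & !lab_t),
                   sum(!lab_p & lab_t), sum(!lab_p & !lab_t)))
    expect_equal(ev3$TP + ev3$TN + ev3$FP + ev3$FN, 100)
  }
  expect_error(score_prediction("zz", truth, surface), "non-surface")
})

test_that("expected-value formulas and degenerate denominators", {
  surface <- sprintf("r%d", 1:100)
  ev <- score_prediction(surface[1:20], surface[5:14], surface)
  expect_equal(ev$Sens_exp, 0.2)   # C = 20/100
  expect_equal(ev$Spe_exp, 0.8)
  expect_equal(ev$PPV_exp, 0.1)    # S/N
  expect_equal(ev$Acc_exp, 0.8 * 0.9 + 0.2 * 0.1)
  expect_equal(ev$ScSens, ev$Sens - 0.2)
  # empty prediction: PPV undefined, not zero
  ev0 <- score_prediction(character(0), surface[1:10], surface)
  expect_true(is.na(ev0$PPV))
  expect_equal(ev0$Sens, 0)
})

test_that("pertinence scores average zero for random fixed-size predictions", {
  set.seed(62)
  surface <- sprintf("r%d", 1:80)
  truth <- surface[1:16]
  draws <- 1000
  sc <- replicate(draws, {
    ev <- score_prediction(sample(surface, 20), truth, surface)
    c(ev$ScSens, ev$ScSpe, ev$ScPPV, ev$ScAcc)
  })
  se <- apply(sc, 1, stats::sd) / sqrt(draws)
  expect_true(all(abs(rowMeans(sc)) < 3 * se))
})

test_that("patch overlap is an asymmetric containment fraction", {
  p1 <- c("a", "b", "c", "d"); p3 <- c("c", "d")
  expect_equal(patch_overlap(p3, p1), 1)
  expect_equal(patch_overlap(p1, p3), 0.5)
  expect_equal(patch_overlap(p1, c("x", "y")), 0)
  expect_equal(patch_overlap(p1, p1), 1)
  expect_error(patch_overlap(character(0), p1), "empty")
})

test_that("multi-patch rule needs 5 residues and over a quarter of the site", {
  mk <- function(n1, n2) {
    ids <- sprintf("r%d", seq_len(n1 + n2))
    structure(list(rounds = 2, residues = data.frame(
      id = ids, patch = 1, layer = "seed", scheme = "SC1",
      round = rep(c(1, 2), c(n1, n2)), stringsAsFactors = FALSE)),
      class = "jet2")
  }
  expect_true(is_multipatch(mk(10, 5)))    # 5/15 > 0.25
  expect_false(is_multipatch(mk(10, 4)))   # fewer than 5 added
  expect_false(is_multipatch(mk(30, 9)))   # 9/39 <= 0.25
  one_round <- structure(list(rounds = 1), class = "jet2")
  expect_error(is_multipatch(one_round), "two-round")
})

test_that("interface decomposition separates distant blobs at the 20 A cut", {
  blob <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(3, 3, 0), c(1.5, 1.5, 3))
  st <- toy_structure(rbind(blob, sweep(blob, 2, c(35, 0, 0), "+")))
  expect_equal(unname(interface_patches(st$residues$id[1], st)), 1L)
  lab <- interface_patches(st$residues$id, st)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:5])), 1)
  expect_equal(length(unique(lab[6:10])), 1)
})

test_that("decomposition equals a naive average-linkage oracle", {
  naive_average_linkage <- function(dm, h) {
    n <- nrow(dm)
    clusters <- as.list(seq_len(n))
    repeat {
      k <- length(clusters)
      if (k == 1) break
      best <- c(NA, NA); best_d <- Inf
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        d <- mean(dm[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
      if (best_d > h) break
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    lab <- integer(n)
    for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
    lab
  }
  set.seed(63)
  for (k in 1:5) {
    fx <- synthetic_globule(n_residues = 60, patch_size = 0, seed = 200 + k)
    ids <- sample(fx$structure$residues$id, 18)
    got <- interface_patches(ids, fx$structure, h = 20)
    dm <- .residue_min_dist(fx$structure, ids)
    ref <- naive_average_linkage(dm, 20)
    # same partition up to label permutation
    expect_equal(length(unique(got)), length(unique(ref)))
    expect_true(all(outer(got, got, "==") == outer(ref, ref, "==")))
    # permutation invariance of the residue input order
    perm <- sample(length(ids))
    got2 <- interface_patches(ids[perm], fx$structure, h = 20)
    same1 <- outer(got, got, "==")
    same2 <- outer(got2[match(ids, ids[perm])],
                   got2[match(ids, ids[perm])], "==")
    expect_true(all(same1 == same2))
  }
})
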