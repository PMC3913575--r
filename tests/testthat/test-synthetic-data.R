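# Synthetic generators: anchor guarantees, seed determinism, ground-truth
# structure, and distributional calibration of the background sampler.

test_that("generated germlines carry exactly the required anchors", {
  g <- generate_germlines(2, length = 110, seed = 1)
  expect_equal(nrow(g), 2)
  expect_false(any(duplicated(g$sequence)))
  for (i in 1:2) {
    s <- g$sequence[i]
    hits <- gregexpr("WG.G", s)[[1]]
    expect_length(hits[hits > 0], 1)           # exactly one J motif
    cys <- gregexpr("C", s, fixed = TRUE)[[1]]
    expect_true(any(cys > 0 & cys < hits[1]))  # Cys upstream of it
  }
  k <- generate_germlines(1, length = 110, seed = 1, chain = "kappa")
  expect_length(gregexpr("FG.G", k$sequence)[[1]], 1)
})

test_that("germline generation enforces its length precondition", {
  expect_error(generate_germlines(1, length = 59, seed = 1), "60")
  expect_error(generate_germlines(0, length = 110), ">= 1")
})

test_that("generators are seed-deterministic", {
  expect_identical(generate_germlines(3, 110, seed = 7),
                   generate_germlines(3, 110, seed = 7))
  g <- generate_germline_set(seed = 4)
  cfg <- repertoire_config(n_clones = 25, seed = 9)
  expect_identical(generate_repertoire(cfg, g), generate_repertoire(cfg, g))
  pc <- panel_config(n_wells = 200, seed = 3)
  expect_identical(generate_panel(pc), generate_panel(pc))
  cc <- competition_config(seed = 11)
  expect_identical(generate_competition(cc), generate_competition(cc))
})

test_that("lineage_fraction = 0 yields only singleton clonotypes and no shm
           leaves framework sequence untouched", {
  g <- generate_germline_set(seed = 1)
  rep <- generate_repertoire(
    repertoire_config(n_clones = 30, lineage_fraction = 0, shm_rate = 0,
                      seed = 5), g)
  expect_false(any(duplicated(rep$true_clonotype)))
  expect_true(all(rep$true_vh_mutations == 0))
  # outside CDR3 the VH equals its germline: prefix up to Cys and J suffix
  germ <- setNames(g$sequence, g$id)
  for (i in seq_len(nrow(rep))) {
    gs <- germ[[rep$true_vh_germline[i]]]
    cys_end <- gregexpr("C", gs, fixed = TRUE)[[1]][1]
    expect_identical(substr(rep$vh[i], 1, cys_end), substr(gs, 1, cys_end))
    expect_identical(substr(rep$vh[i], nchar(rep$vh[i]) - 9, nchar(rep$vh[i])),
                     substr(gs, nchar(gs) - 9, nchar(gs)))
  }
})

test_that("fraction of clones in multi-member clonotypes tracks lineage_fraction", {
  g <- generate_germline_set(seed = 1)
  rep <- generate_repertoire(
    repertoire_config(n_clones = 227, lineage_fraction = 0.25, seed = 11), g)
  multi <- table(rep$true_clonotype)
  frac <- mean(rep$true_clonotype %in% names(multi)[multi >= 2])
  se <- sqrt(0.25 * 0.75 / 227)
  expect_lt(abs(frac - 0.25), 3 * se + 4 / 227)  # binomial error + grouping slack
})

test_that("lineage members stay within the configured CDR3 divergence and
           never span animals", {
  g <- generate_germline_set(seed = 1)
  rep <- generate_repertoire(
    repertoire_config(n_clones = 120, lineage_fraction = 0.5,
                      lineage_mutations = 2, seed = 13), g)
  ann <- annotate_repertoire(rep, g)
  for (ct in unique(rep$true_clonotype)) {
    idx <- which(rep$true_clonotype == ct)
    if (length(idx) < 2) next
    expect_length(unique(rep$animal[idx]), 1)
    for (j in idx[-1]) {
      d <- cdr3_pair_distance(ann[idx[1], ], ann[j, ])
      expect_false(is.null(d))
      expect_true(all(d <= 4))  # founder-relative bound doubles pairwise
    }
  }
})

test_that("panel background follows the configured Johnson SU law", {
  # positive_fraction 0: all wells are pure background
  p <- generate_panel(panel_config(
    n_wells = 10000, background_law = c(gamma = 0, delta = 1, xi = 0, lambda = 1),
    positive_fraction = 0, igg_positive_fraction = 0, fc_binder_fraction = 0,
    seed = 3))
  expect_false(any(p$is_binder))
  q99 <- unname(stats::quantile(p$od_hu, 0.99))
  expect_lt(abs(q99 - sinh(qnorm(0.99))), 0.15)
  # quantile convergence at n = 1e5 against the closed form, 2%
  p2 <- generate_panel(panel_config(
    n_wells = 1e5, background_law = c(gamma = -1, delta = 1.5,
                                      xi = 0.05, lambda = 0.03),
    positive_fraction = 0, igg_positive_fraction = 0, fc_binder_fraction = 0,
    seed = 8))
  truth <- qjohnson_su(0.99, -1, 1.5, 0.05, 0.03)
  expect_lt(abs(unname(stats::quantile(p2$od_hu, 0.99)) / truth - 1), 0.02)
})

test_that("different panel seeds give different samples, same law", {
  cfg1 <- panel_config(n_wells = 5000, positive_fraction = 0,
                       igg_positive_fraction = 0, seed = 1)
  cfg2 <- panel_config(n_wells = 5000, positive_fraction = 0,
                       igg_positive_fraction = 0, seed = 2)
  a <- generate_panel(cfg1)$od_hu; b <- generate_panel(cfg2)$od_hu
  expect_false(identical(a, b))
  expect_lt(abs(median(a) - median(b)), 0.01)
})

test_that("competition matrix plants the configured group structure", {
  cm <- generate_competition(competition_config(n_antibodies = 16,
                                                n_groups = 6, seed = 5))
  expect_equal(dim(cm$values), c(16, 16))
  expect_equal(as.vector(table(cm$true_groups)), c(3, 3, 3, 3, 2, 2))
  # zero noise: within-group entries at the low mean, between at the high
  cm0 <- generate_competition(competition_config(n_antibodies = 6, n_groups = 2,
                                                 noise_sd = 0, seed = 1))
  same <- outer(cm0$true_groups, cm0$true_groups, "==")
  expect_true(all(cm0$values[same] == 0.15))
  expect_true(all(cm0$values[!same] == 1.0))
  expect_true(isSymmetric(unname(cm0$values)))
  # single group: everything from the within law
  cm1 <- generate_competition(competition_config(n_antibodies = 5, n_groups = 1,
                                                 noise_sd = 0, seed = 1))
  expect_true(all(cm1$values == 0.15))
})

test_that("asymmetric pair overrides flip exactly one direction", {
  cc <- competition_config(n_antibodies = 6, n_groups = 2, noise_sd = 0,
                           asymmetric_pairs = rbind(c(1, 4)), seed = 2)
  cm <- generate_competition(cc)
  expect_false(cm$true_groups[1] == cm$true_groups[4])
  expect_equal(cm$values[1, 4], 0.15)  # flipped to competition
  expect_equal(cm$values[4, 1], 1.0)   # reverse direction untouched
})

test_that("config validation rejects invalid parameters", {
  expect_error(repertoire_config(lineage_fraction = 1.5), "lineage_fraction")
  expect_error(repertoire_config(shm_rate = -1), "shm_rate")
  expect_error(panel_config(positive_fraction = 2), "fractions")
  expect_error(competition_config(n_antibodies = 4, n_groups = 6), "n_groups")
  expect_error(competition_config(asymmetric_pairs = rbind(c(1, 99))),
               "invalid")
})
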