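# Clonotype clustering: pair distances, single-linkage closure,
# brute-force agreement, monotonicity and categorisation accounting.

test_that("cdr3_pair_distance counts per-chain mismatches and flags
           incomparable lengths", {
  expect_equal(cdr3_pair_distance(c("ARDFGY", "QQGYSSPFT"),
                                  c("ARDFGY", "QQGYSSPFT")),
               c(h3 = 0, l3 = 0))
  expect_equal(cdr3_pair_distance(c("ARDFGY", "QQGYSSPFT"),
                                  c("ARDFGW", "QQGYSSPFT")),
               c(h3 = 1, l3 = 0))
  expect_null(cdr3_pair_distance(c("ARDFGYARDF", "QQG"),
                                 c("ARDFGYARDFGY", "QQG")))
})

test_that("identical CDR3 pairs form one cluster; single linkage chains
           through intermediates", {
  df <- toy_clones(c("AAAA", "AAAA"), c("LLLL", "LLLL"))
  cl <- cluster_clonotypes(df)
  expect_length(cl$clusters, 1)
  expect_length(cl$unique_ids, 0)
  # A-B distance (1,0), B-C (2,0), A-C (3,0): one cluster by single linkage
  tri <- toy_clones(c("AAAAAA", "AAAAAV", "AAAVVV"),
                    rep("LLLL", 3))
  d_ab <- cdr3_pair_distance(tri[1, ], tri[2, ])
  d_bc <- cdr3_pair_distance(tri[2, ], tri[3, ])
  d_ac <- cdr3_pair_distance(tri[1, ], tri[3, ])
  expect_equal(unname(d_ab[1]), 1)
  expect_equal(unname(d_bc[1]), 2)
  expect_equal(unname(d_ac[1]), 3)
  cl_tri <- cluster_clonotypes(tri, threshold = 2)
  expect_length(cl_tri$clusters, 1)
  expect_setequal(cl_tri$clusters[[1]], tri$clone_id)
  # complete linkage splits the same triple
  cl_comp <- cluster_clonotypes(tri, threshold = 2, linkage = "complete")
  expect_gt(length(cl_comp$unique_ids) + length(cl_comp$clusters), 1)
})

test_that("clustering equals the brute-force union-find oracle", {
  set.seed(77)
  for (rep_i in 1:5) {
    n <- 50
    # mixture of shared founders (perturbed) and fresh CDR3s
    founders_h <- rand_cdr3(12, 9); founders_l <- rand_cdr3(12, 8)
    pick <- sample(12, n, replace = TRUE)
    h3 <- founders_h[pick]; l3 <- founders_l[pick]
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      for (p in sample(length(ch), k)) ch[p] <- sample(c("A","V","T","S"), 1)
      paste(ch, collapse = "")
    }
    for (i in seq_len(n)) {
      h3[i] <- mut(h3[i], sample(0:3, 1))
      l3[i] <- mut(l3[i], sample(0:3, 1))
    }
    fresh <- sample(n, 10)
    h3[fresh] <- rand_cdr3(10, 11)
    df <- toy_clones(h3, l3)
    cl <- cluster_clonotypes(df, threshold = 2)
    got <- ifelse(is.na(cl$membership), paste0("u", seq_along(cl$membership)),
                  cl$membership)
    oracle <- oracle_clonotype_partition(h3, l3, threshold = 2)
    expect_equal(rand_index(got, oracle), 1)
  }
})

test_that("raising the threshold never increases the cluster-plus-singleton
           count", {
  set.seed(5)
  df <- toy_clones(rand_cdr3(40, 6), rand_cdr3(40, 5))
  counts <- sapply(0:4, function(t) {
    cl <- cluster_clonotypes(df, threshold = t)
    length(cl$clusters) + length(cl$unique_ids)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("30 clones with 21 singleton truth clonotypes give 70% unique", {
  rows <- data.frame(animal = "68", bleed = 2, n = 30, unique = 21)
  df <- accounting_clones(rows)
  cl <- cluster_clonotypes(df)
  expect_length(cl$unique_ids, 21)
  cat_tab <- categorize(cl, df)
  expect_equal(cat_tab$pct_unique, 70)
  expect_equal(cat_tab$n_clustered, 9)
})

test_that("clustering on synthetic repertoires recovers truth clonotypes", {
  g <- generate_germline_set(seed = 2)
  for (s in c(21, 22)) {
    rep <- generate_repertoire(
      repertoire_config(n_clones = 100, lineage_fraction = 0.3, seed = s), g)
    ann <- annotate_repertoire(rep, g)
    cl <- cluster_clonotypes(ann, threshold = 2)
    got <- ifelse(is.na(cl$membership), paste0("u", seq_along(cl$membership)),
                  cl$membership)
    expect_gte(rand_index(got, rep$true_clonotype), 0.95)
  }
})

test_that("categorize reports per-group identity counts with the subset
           relation and sharing flags", {
  df <- toy_clones(
    h3 = c("AAAA", "AAAA", "DDDD", "DDDD", "EEEE"),
    l3 = c("LLLL", "LLLL", "MMMM", "MMMN", "PPPP"))
  df$vh <- paste0("VH", c(1, 1, 2, 3, 4)); df$vl <- paste0("VL", c(1, 1, 2, 3, 4))
  df$animal <- "68"; df$bleed <- c(1, 1, 1, 2, 1)
  cl <- cluster_clonotypes(df)
  tab <- categorize(cl, df)
  r1 <- tab[tab$bleed == 1, ]
  expect_equal(r1$n_identical_cdr3hl, 2)   # the exact duplicate pair
  expect_equal(r1$n_identical_vhvl, 2)
  expect_true(all(tab$n_identical_vhvl <= tab$n_identical_cdr3hl))
  # the DDDD cluster spans bleeds 1 and 2 of one animal
  expect_length(attr(tab, "cross_bleed"), 1)
  expect_length(attr(tab, "cross_animal"), 0)
})

test_that("all-unique input yields zero clustered counts and no sharing", {
  df <- toy_clones(rand_cdr3(8, 12), rand_cdr3(8, 10))
  cl <- cluster_clonotypes(df)
  tab <- categorize(cl, df)
  expect_equal(sum(tab$n_clustered), 0)
  expect_equal(sum(tab$n_unique), 8)
})

test_that("campaigns without cross-animal lineages share no clusters between
           animals", {
  g <- generate_germline_set(seed = 9)
  rep <- generate_repertoire(
    repertoire_config(n_clones = 120, lineage_fraction = 0.35, seed = 31), g)
  ann <- annotate_repertoire(rep, g)
  cl <- cluster_clonotypes(ann)
  tab <- categorize(cl, ann)
  expect_length(attr(tab, "cross_animal"), 0)
})
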