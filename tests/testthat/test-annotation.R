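# Germline assignment, region delineation and replacement counting.

test_that("assign_germline recovers an identical reference with 0 replacements", {
  g <- generate_germlines(2, seed = 1)
  res <- assign_germline(g$sequence[1], g)
  expect_equal(res$germline_id, "VH1a1")
  expect_equal(res$replacements, 0)
})

test_that("assign_germline picks the Hamming-closest reference on a toy pair", {
  g <- generate_germlines(1, seed = 2)
  base <- g$sequence[1]
  sub_at <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  g2 <- base
  for (p in c(3, 7, 12)) g2 <- sub_at(g2, p, if (substr(g2, p, p) == "A") "V" else "A")
  refs <- data.frame(id = c("G1", "G2"), chain = "heavy",
                     sequence = c(base, g2), stringsAsFactors = FALSE)
  query <- sub_at(base, 5, if (substr(base, 5, 5) == "A") "V" else "A")
  res <- assign_germline(query, refs)
  expect_equal(res$germline_id, "G1")
  expect_equal(res$replacements, 1)
})

test_that("ties break by reference order", {
  g <- generate_germlines(1, seed = 3)
  base <- g$sequence[1]
  sub_at <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  other <- function(x) if (x == "A") "V" else "A"
  r1 <- sub_at(base, 2, other(substr(base, 2, 2)))
  r2 <- sub_at(base, 9, other(substr(base, 9, 9)))
  refs <- data.frame(id = c("first", "second"), chain = "heavy",
                     sequence = c(r1, r2), stringsAsFactors = FALSE)
  res <- assign_germline(base, refs)   # equidistant (1 mismatch each)
  expect_equal(unname(res$all_replacements), c(1, 1))
  expect_equal(res$germline_id, "first")
})

test_that("assign_germline validates its inputs", {
  g <- generate_germlines(1, seed = 1)
  expect_error(assign_germline("ACDEFHIKLM", g), "60")
  expect_error(assign_germline(g$sequence[1], g[0, ]), "empty")
  bad <- paste(rep("B", 80), collapse = "")
  expect_error(assign_germline(bad, g), "non-standard")
})

test_that("germline assignment equals the exhaustive argmin oracle", {
  set.seed(42)
  g <- generate_germlines(5, seed = 20)
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  sub_at <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  for (rep_i in 1:50) {
    base <- g$sequence[sample(5, 1)]
    q <- base
    for (p in sample(nchar(base), sample(0:12, 1)))
      q <- sub_at(q, p, sample(setdiff(c("A","V","L","I","T","S"),
                                       substr(q, p, p)), 1))
    oracle_d <- vapply(g$sequence, hamming, numeric(1), a = q)
    res <- assign_germline(q, g)
    expect_equal(res$germline_id, g$id[which.min(oracle_d)])
    expect_equal(res$replacements, unname(min(oracle_d)))
  }
})

test_that("CDR3 is delineated between the last Cys and the J motif", {
  # heavy: hand application of the anchor rule
  h <- "ASTLDKEAKNTLYYCARDFGYWGQGTLVTISS"
  rh <- delineate_regions(h, "heavy",
                          cdr_offsets = list(cdr1 = c(2, 5), cdr2 = c(7, 10)))
  expect_true(rh$ok)
  expect_equal(rh$cdr3_sequence, "ARDFGY")
  expect_equal(unname(rh$boundaries$cdr3), c(15, 21))
  expect_equal(unname(rh$boundaries$fr4[1]), 21)  # FR4 starts at the W
  # kappa hand example
  k <- "ASTLDKEAKNTLYYCQQGYSSPFTFGQGTKV"
  rk <- delineate_regions(k, "kappa",
                          cdr_offsets = list(cdr1 = c(2, 5), cdr2 = c(7, 10)))
  expect_equal(rk$cdr3_sequence, "QQGYSSPFT")
})

test_that("missing anchors flag an annotation failure", {
  no_motif <- paste(rep("ACDEF", 14), collapse = "")
  r <- delineate_regions(no_motif, "heavy")
  expect_false(r$ok)
  expect_match(r$reason, "J motif")
  no_cys <- paste0(paste(rep("ADEFH", 12), collapse = ""), "WGQGTLV")
  r2 <- delineate_regions(no_cys, "heavy")
  expect_false(r2$ok)
})

test_that("region boundaries partition the sequence and CDR3 extraction is
           idempotent", {
  g <- generate_germline_set(seed = 6)
  rep <- generate_repertoire(repertoire_config(n_clones = 15, seed = 7), g)
  for (i in seq_len(nrow(rep))) {
    r <- delineate_regions(rep$vh[i], "heavy")
    expect_true(r$ok)
    b <- r$boundaries
    expect_equal(unname(b$fr1[1]), 0)
    expect_equal(unname(b$fr4[2]), nchar(rep$vh[i]))
    nm <- names(b)
    for (j in seq_len(length(b) - 1))
      expect_equal(unname(b[[nm[j]]][2]), unname(b[[nm[j + 1]]][1]))
    # idempotence: re-annotating the same sequence reproduces the CDR3
    expect_identical(delineate_regions(rep$vh[i], "heavy")$cdr3_sequence,
                     r$cdr3_sequence)
  }
})

test_that("replacements are counted per region, indels excluded", {
  g <- generate_germlines(1, seed = 9)
  germ <- g$sequence[1]
  reg <- delineate_regions(germ, "heavy",
                           cdr_offsets = list(cdr1 = c(g$cdr1_start, g$cdr1_end),
                                              cdr2 = c(g$cdr2_start, g$cdr2_end)))
  # identity
  expect_equal(as.vector(count_replacements(germ, germ, reg)), c(0, 0, 0))
  # 2 FR substitutions + 1 CDR substitution -> (2, 1, 3)
  sub_at <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  other <- function(x) if (x == "A") "V" else "A"
  q <- germ
  fr_pos <- c(2, g$cdr1_end + 2)          # FR1 and FR2 (1-based)
  cdr_pos <- g$cdr1_start + 2             # inside CDR1
  for (p in c(fr_pos, cdr_pos)) q <- sub_at(q, p, other(substr(q, p, p)))
  counts <- count_replacements(q, germ, delineate_regions(
    q, "heavy", cdr_offsets = list(cdr1 = c(g$cdr1_start, g$cdr1_end),
                                   cdr2 = c(g$cdr2_start, g$cdr2_end))))
  expect_equal(as.vector(counts), c(2, 1, 3))
  # a pure CDR insertion contributes nothing
  ins <- paste0(substr(germ, 1, g$cdr1_start + 3), "AA",
                substr(germ, g$cdr1_start + 4, nchar(germ)))
  reg_ins <- delineate_regions(ins, "heavy",
                               cdr_offsets = list(cdr1 = c(g$cdr1_start, g$cdr1_end + 2),
                                                  cdr2 = c(g$cdr2_start + 2, g$cdr2_end + 2)))
  counts_ins <- count_replacements(ins, germ, reg_ins)
  expect_equal(as.vector(counts_ins), c(0, 0, 0))
})

test_that("annotation recovers generator ground truth", {
  g <- generate_germline_set(seed = 1)
  rep <- generate_repertoire(repertoire_config(n_clones = 60, seed = 2), g)
  ann <- annotate_repertoire(rep, g)
  expect_true(all(ann$annotation_ok))
  # 100% germline recovery (references differ far more than 2x shm rate)
  expect_identical(ann$vh_germline, rep$true_vh_germline)
  expect_identical(ann$vl_germline, rep$true_vl_germline)
  # placed mutations recovered exactly on the germline-templated segment
  expect_equal(ann$vh_repl_v, rep$true_vh_mutations)
  expect_equal(ann$vl_repl_v, rep$true_vl_mutations)
})

test_that("mean recovered replacement load matches the configured shm rate", {
  g <- generate_germline_set(seed = 3)
  r <- 8
  rep <- generate_repertoire(
    repertoire_config(n_clones = 150, shm_rate = r, seed = 4), g)
  ann <- annotate_repertoire(rep, g)
  se <- sd(ann$vh_repl_v) / sqrt(nrow(ann))
  expect_lt(abs(mean(ann$vh_repl_v) - r), 3 * se)
})

test_that("clones failing annotation are flagged and retained", {
  g <- generate_germline_set(seed = 5)
  rep <- generate_repertoire(repertoire_config(n_clones = 5, seed = 6), g)
  rep$vh[2] <- gsub("WG", "YY", rep$vh[2])  # destroy the J motif
  ann <- annotate_repertoire(rep, g)
  expect_equal(nrow(ann), 5)
  expect_false(ann$annotation_ok[2])
  expect_true(all(ann$annotation_ok[-2]))
})
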