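# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately re-derive results from first principles
# (exhaustive search, union-find, objective recomputation) so they stay
# independent of the implementation paths they check.

# exhaustive union-find closure over all clone pairs under the clonotype
# relation (equal CDR3 lengths per chain, <= threshold mismatches each)
oracle_clonotype_partition <- function(h3, l3, threshold) {
  n <- length(h3)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (nchar(h3[i]) != nchar(h3[j]) || nchar(l3[i]) != nchar(l3[j])) next
    if (hamming(h3[i], h3[j]) <= threshold &&
        hamming(l3[i], l3[j]) <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# brute-force Ward agglomeration recomputing the merge objective
# 2*nA*nB/(nA+nB) * ||cA - cB||^2 from the raw points at every step;
# returns the sequence of merged leaf sets and heights
oracle_ward_merges <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; bd <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(m[a, , drop = FALSE]); cb <- colMeans(m[b, , drop = FALSE])
      d <- 2 * length(a) * length(b) / (length(a) + length(b)) *
        sum((ca - cb)^2)
      ka <- min(min(a), min(b)); kb <- max(min(a), min(b))
      if (d < bd - 1e-12 ||
          (abs(d - bd) <= 1e-12 &&
           (ka < best$ka || (ka == best$ka && kb < best$kb)))) {
        bd <- d; best <- list(i = i, j = j, ka = ka, kb = kb)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, sqrt(bd))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(merges = merges, heights = heights)
}

# leaf sets produced by each merge of an hclust-style merge matrix
merge_leaf_sets <- function(merge) {
  sets <- vector("list", nrow(merge))
  expand <- function(node) if (node < 0) -node else sets[[node]]
  for (s in seq_len(nrow(merge)))
    sets[[s]] <- sort(c(expand(merge[s, 1]), expand(merge[s, 2])))
  sets
}

# toy annotated clone table built directly from CDR3 strings
toy_clones <- function(h3, l3, animal = "68", bleed = 1) {
  n <- length(h3)
  data.frame(clone_id = sprintf("c%02d", seq_len(n)),
             animal = rep_len(animal, n), bleed = rep_len(bleed, n),
             cdr3_h = h3, cdr3_l = l3, stringsAsFactors = FALSE)
}

# random CDR3-like strings over the generator's safe alphabet
rand_cdr3 <- function(n, len) {
  alph <- setdiff(c("A","D","E","F","H","I","K","L","M","N",
                    "P","Q","R","S","T","V","W","Y"), NULL)
  vapply(seq_len(n), function(i)
    paste(sample(alph, len, replace = TRUE), collapse = ""), character(1))
}

# clone table for Table-5 style accounting: per (animal, bleed) row,
# n_unique singleton clonotypes plus clusters (sizes >= 2) covering the
# remaining clones; every CDR3 globally distinct across rows
accounting_clones <- function(rows) {
  out <- list(); serial <- 0
  alph <- c("A","D","E","F","H","I","K","L","M","N",
            "P","Q","R","S","T","V","W","Y")
  # serial -> 3 base-18 digits, each repeated 3x: distinct serials are
  # always > 2 mismatches apart, so they never co-cluster at threshold 2
  mk <- function() {
    serial <<- serial + 1
    d <- c(serial %/% 324, (serial %/% 18) %% 18, serial %% 18) + 1
    paste(rep(alph[d], each = 3), collapse = "")
  }
  for (r in seq_len(nrow(rows))) {
    n <- rows$n[r]; u <- rows$unique[r]
    cl <- n - u
    sizes <- integer(0)
    while (cl > 0) { s <- if (cl == 4 || cl < 3) min(cl, 2) else 3; sizes <- c(sizes, s); cl <- cl - s }
    h3 <- character(0); l3 <- character(0)
    for (i in seq_len(u)) { h3 <- c(h3, mk()); l3 <- c(l3, mk()) }
    for (s in sizes) { h <- mk(); l <- mk(); h3 <- c(h3, rep(h, s)); l3 <- c(l3, rep(l, s)) }
    out[[r]] <- toy_clones(h3, l3, animal = rows$animal[r], bleed = rows$bleed[r])
  }
  df <- do.call(rbind, out)
  df$clone_id <- sprintf("c%04d", seq_len(nrow(df)))
  df
}
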