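# CDR3 clonotype clustering and per-animal/bleed categorisation.
#
# Two clones belong to the same clonotype when their CDR-H3 and CDR-L3
# are identical or very similar: equal lengths on both chains and at most
# `threshold` (default 2) replacement mismatches per chain. Clusters are
# the single-linkage transitive closure of that relation; clones in no
# cluster are "unique". CDR3s of different length are incomparable:
# "replacements" are substitutions, not indels.

#' CDR3 pair distance between two clones
#'
#' @param a,b either annotated clone rows (with `cdr3_h`, `cdr3_l`) or
#'   two-element character vectors `c(cdr3_h, cdr3_l)`.
#' @return named integer vector `c(h3, l3)` of per-chain Hamming
#'   mismatches, or `NULL` ("incomparable") when either chain's CDR3
#'   lengths differ.
#' @examples
#' cdr3_pair_distance(c("ARDFGY", "QQGYSSPFT"), c("ARDFGW", "QQGYSSPFT"))
#' @export
cdr3_pair_distance <- function(a, b) {
  get3 <- function(x) {
    if (is.data.frame(x) || is.list(x)) c(x$cdr3_h[1], x$cdr3_l[1]) else x[1:2]
  }
  a <- get3(a); b <- get3(b)
  if (nchar(a[1]) != nchar(b[1]) || nchar(a[2]) != nchar(b[2])) return(NULL)
  hamming <- function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  c(h3 = hamming(a[1], b[1]), l3 = hamming(a[2], b[2]))
}

# all within-threshold pairs among equal-length (H3, L3) groups; returns a
# 2-column index matrix into `h3`
clonotype_edges <- function(h3, l3, threshold) {
  n <- length(h3)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  key <- paste(nchar(h3), nchar(l3))
  edges <- list()
  for (grp in split(seq_len(n), key)) {
    if (length(grp) < 2) next
    hm <- utils::combn(grp, 2)
    for (j in seq_len(ncol(hm))) {
      i1 <- hm[1, j]; i2 <- hm[2, j]
      d <- cdr3_pair_distance(c(h3[i1], l3[i1]), c(h3[i2], l3[i2]))
      if (!is.null(d) && d["h3"] <= threshold && d["l3"] <= threshold)
        edges[[length(edges) + 1L]] <- c(i1, i2)
    }
  }
  if (!length(edges)) matrix(integer(0), ncol = 2) else do.call(rbind, edges)
}

#' Cluster clones into CDR3 clonotypes
#'
#' Single-linkage transitive closure (graph connected components) of the
#' relation "both CDR3 chains comparable and within `threshold` mismatches
#' each". A complete-linkage variant (every pair in a cluster within
#' threshold) is available.
#'
#' @param clones `annotated_repertoire` (or any data.frame with `clone_id`,
#'   `cdr3_h`, `cdr3_l`; an `annotation_ok` column, if present, restricts
#'   clustering to successfully annotated clones).
#' @param threshold maximum mismatches per chain (default 2).
#' @param linkage `"single"` (default, transitive closure) or
#'   `"complete"`.
#' @return object of class `clonotype_clustering`: list with `membership`
#'   (named vector clone_id -> cluster label, `NA` for unique clones),
#'   `clusters` (list of clone-id vectors, all of size >= 2), `unique_ids`,
#'   `threshold`, `linkage`, `n`.
#' @examples
#' df <- data.frame(clone_id = c("a", "b", "c"),
#'                  cdr3_h = c("ARDFGY", "ARDFGW", "TTTTTT"),
#'                  cdr3_l = c("QQGYSSPFT", "QQGYSSPFT", "QQGYSSPFT"))
#' cluster_clonotypes(df)$clusters
#' @export
cluster_clonotypes <- function(clones, threshold = 2,
                               linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(nrow(clones) >= 1)
  use <- if ("annotation_ok" %in% names(clones)) which(clones$annotation_ok)
         else seq_len(nrow(clones))
  ids <- clones$clone_id[use]
  h3 <- clones$cdr3_h[use]; l3 <- clones$cdr3_l[use]
  n <- length(ids)

  if (linkage == "single") {
    edges <- clonotype_edges(h3, l3, threshold)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges))
      g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
  } else {
    # complete linkage: hierarchical clustering on max per-chain mismatch,
    # incomparable pairs at an unreachable distance, cut at threshold
    d <- matrix(1e6, n, n)
    edges <- clonotype_edges(h3, l3, Inf)
    if (nrow(edges)) {
      for (j in seq_len(nrow(edges))) {
        i1 <- edges[j, 1]; i2 <- edges[j, 2]
        dd <- max(cdr3_pair_distance(c(h3[i1], l3[i1]), c(h3[i2], l3[i2])))
        d[i1, i2] <- d[i2, i1] <- dd
      }
    }
    diag(d) <- 0
    comp <- if (n == 1) 1L else
      stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"),
                    h = threshold + 0.5)
  }

  sizes <- table(comp)
  clustered <- comp %in% as.integer(names(sizes)[sizes >= 2])
  membership <- stats::setNames(rep(NA_character_, n), ids)
  relabel <- stats::setNames(
    sprintf("cl%03d", seq_along(unique(comp[clustered]))),
    unique(comp[clustered]))
  membership[clustered] <- relabel[as.character(comp[clustered])]
  clusters <- split(ids[clustered], membership[clustered])
  structure(list(membership = membership,
                 clusters = clusters,
                 unique_ids = ids[!clustered],
                 threshold = threshold, linkage = linkage, n = n),
            class = "clonotype_clustering")
}

#' @export
print.clonotype_clustering <- function(x, ...) {
  cat("Clonotype clustering (", x$linkage, " linkage, threshold ",
      x$threshold, ")\n", sep = "")
  cat("  ", x$n, " clones: ", length(x$unique_ids), " unique (",
      percent_of(length(x$unique_ids), x$n, 0), "%), ",
      x$n - length(x$unique_ids), " clustered in ",
      length(x$clusters), " clusters\n", sep = "")
  invisible(x)
}

#' @export
summary.clonotype_clustering <- function(object, ...) {
  sizes <- lengths(object$clusters)
  cat("Cluster sizes:\n"); print(if (length(sizes)) table(sizes) else "none")
  invisible(object)
}

dup_members <- function(x) x %in% x[duplicated(x)]

#' Categorise clones per animal and bleed
#'
#' Per-(animal, bleed) accounting of clonotype diversity: clone counts,
#' unique/clustered split with integer-rounded percent unique, and counts
#' of clones sharing (within the same animal and bleed) an identical
#' CDR-H3, CDR-L3, CDR-H3+CDR-L3, VH, VL or VH+VL with another clone.
#' Cross-bleed and cross-animal cluster sharing is reported as attributes.
#'
#' @param clustering a [cluster_clonotypes()] result.
#' @param clones the annotated clone table the clustering was built from.
#' @return data.frame of class `clone_categories`, one row per
#'   (bleed, animal): `bleed`, `animal`, `n_clones`, `n_unique`,
#'   `pct_unique` (half-up integer), `n_clustered`, `n_identical_cdr3h`,
#'   `n_identical_cdr3l`, `n_identical_cdr3hl`, `n_identical_vh`,
#'   `n_identical_vl`, `n_identical_vhvl`. Attributes `cross_bleed` and
#'   `cross_animal` list cluster labels spanning several bleeds of one
#'   animal resp. several animals.
#' @export
categorize <- function(clustering, clones) {
  stopifnot(inherits(clustering, "clonotype_clustering"))
  needed <- c("clone_id", "animal", "bleed", "cdr3_h", "cdr3_l")
  stopifnot(all(needed %in% names(clones)))
  cl <- as.data.frame(clones)
  cl <- cl[cl$clone_id %in% names(clustering$membership), , drop = FALSE]
  cl$cluster <- clustering$membership[cl$clone_id]
  has_chain <- all(c("vh", "vl") %in% names(cl))

  groups <- split(cl, list(cl$bleed, cl$animal), drop = TRUE)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    n_unique <- sum(is.na(g$cluster))
    data.frame(
      bleed = g$bleed[1], animal = g$animal[1],
      n_clones = n, n_unique = n_unique,
      pct_unique = percent_of(n_unique, n, 0),
      n_clustered = n - n_unique,
      n_identical_cdr3h = sum(dup_members(g$cdr3_h)),
      n_identical_cdr3l = sum(dup_members(g$cdr3_l)),
      n_identical_cdr3hl = sum(dup_members(paste(g$cdr3_h, g$cdr3_l))),
      n_identical_vh = if (has_chain) sum(dup_members(g$vh)) else NA_integer_,
      n_identical_vl = if (has_chain) sum(dup_members(g$vl)) else NA_integer_,
      n_identical_vhvl = if (has_chain)
        sum(dup_members(paste(g$vh, g$vl))) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bleed, out$animal), , drop = FALSE]
  rownames(out) <- NULL

  clustered <- cl[!is.na(cl$cluster), , drop = FALSE]
  span <- function(f) {
    tapply(seq_len(nrow(clustered)), clustered$cluster, function(i)
      length(unique(f(clustered[i, , drop = FALSE]))) > 1)
  }
  cross_animal <- character(0); cross_bleed <- character(0)
  if (nrow(clustered)) {
    sa <- span(function(g) g$animal)
    cross_animal <- names(sa)[sa]
    sb <- span(function(g) paste(g$animal, g$bleed))
    # bleed-spanning within one animal: spans bleeds but not animals
    multi_bleed <- names(sb)[sb]
    cross_bleed <- setdiff(multi_bleed, cross_animal)
  }
  structure(out, cross_bleed = cross_bleed, cross_animal = cross_animal,
            class = c("clone_categories", "data.frame"))
}
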