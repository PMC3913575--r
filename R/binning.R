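# Epitope binning from a cross-competition matrix: row normalisation,
# agglomerative Ward clustering of competition profiles (Lance-Williams
# recurrence on squared Euclidean distances), gap-based cluster-count
# selection as an automated stand-in for manual dendrogram inspection,
# PCA confirmation, a row-vs-column (transposed) agreement check, and
# asymmetric-binder detection.

as_comp_matrix <- function(matrix) {
  if (inherits(matrix, "competition_matrix")) matrix$values
  else as.matrix(matrix)
}

#' Normalise a competition matrix
#'
#' Scales each row (one first-captured antibody's competition profile) to
#' \[0, 1\] by its no-competition reference: the row maximum by default, or
#' an explicit control column. After normalisation, values near 0 mean
#' full competition and values near 1 mean none.
#'
#' @param matrix square numeric matrix or `competition_matrix`.
#' @param control optional column index/name holding each row's
#'   no-competition reference signal.
#' @return the normalised square matrix (orientation preserved).
#' @examples
#' normalize_matrix(rbind(c(1, 2, 4), c(4, 2, 1), c(1, 4, 2)))
#' @export
normalize_matrix <- function(matrix, control = NULL) {
  m <- as_comp_matrix(matrix)
  if (nrow(m) != ncol(m)) stop("competition matrix must be square")
  if (!all(is.finite(m))) stop("competition matrix has non-finite entries")
  ref <- if (is.null(control)) apply(m, 1, max) else m[, control]
  if (any(ref <= 0) || any(ref - apply(m, 1, min) <= 0))
    stop("zero-range row: no usable no-competition reference")
  m / ref
}

#' Ward hierarchical clustering of competition profiles
#'
#' Agglomerative clustering of the matrix rows under Ward's
#' minimum-variance criterion, implemented with the Lance-Williams update
#' on squared Euclidean distances. Merge heights follow the convention
#' \eqn{h(A,B) = \sqrt{2 n_A n_B / (n_A + n_B)} \, \lVert c_A - c_B \rVert}
#' (for two singletons, their Euclidean distance), so heights are
#' monotone non-decreasing. Ties are broken by the smallest involved leaf
#' index.
#'
#' @param matrix numeric matrix; rows are the objects to cluster (use
#'   [normalize_matrix()] first for competition data).
#' @return object of class `ward_dendrogram` with `merge`, `height`,
#'   `order`, `labels` in [stats::hclust()] layout; convert with
#'   [as.hclust()].
#' @export
ward_cluster <- function(matrix) {
  m <- as.matrix(matrix)
  if (!all(is.finite(m))) stop("non-finite entries")
  n <- nrow(m)
  if (n < 2) stop("need at least 2 rows to cluster")
  labels <- rownames(m)

  # D[i,j] = 2 nA nB/(nA+nB) * ||cA - cB||^2; for singletons the squared
  # Euclidean distance
  D <- as.matrix(stats::dist(m))^2
  diag(D) <- Inf
  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: negative = leaf
  minleaf <- seq_len(n)        # smallest leaf index per active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    best <- min(sub)
    cand <- which(sub == best, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: smallest minimal leaf, then smallest partner leaf
    keyA <- pmin(minleaf[act[cand[, 1]]], minleaf[act[cand[, 2]]])
    keyB <- pmax(minleaf[act[cand[, 1]]], minleaf[act[cand[, 2]]])
    pick <- order(keyA, keyB)[1]
    i <- act[cand[pick, 1]]; j <- act[cand[pick, 2]]

    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- sqrt(D[i, j])

    # Lance-Williams Ward update into slot i
    ni <- size[i]; nj <- size[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- size[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    active[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
  }

  structure(list(merge = merge, height = height,
                 order = dendro_order(merge),
                 labels = labels, method = "ward"),
            class = "ward_dendrogram")
}

# leaf order for plotting, by recursive left-right traversal of merges
dendro_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' @export
as.hclust.ward_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "ward",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("Ward dendrogram over", nrow(x$merge) + 1L, "profiles;",
      "merge heights", paste(round(range(x$height), 3), collapse = " - "), "\n")
  invisible(x)
}

#' @export
plot.ward_dendrogram <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
  invisible(x)
}

#' Select the cluster count from a dendrogram
#'
#' Automated stand-in for manual dendrogram inspection: cuts at the
#' largest relative gap between successive merge heights,
#' \eqn{(h_{m+1} - h_m)/h_m}, giving \eqn{k = n - m} clusters. When no
#' merge-height gap stands out (all heights equal, within tolerance) the
#' convention is a single cluster. A manual `k` can always be passed to
#' downstream functions instead.
#'
#' @param dendrogram a [ward_cluster()] result (or `hclust`).
#' @param min_gap minimum relative gap regarded as dominant (default 0.1).
#' @return list with `k`, `cut_height` (midpoint of the gap) and
#'   `gap` (the winning relative gap; 0 when none).
#' @examples
#' m <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5))
#' select_k(ward_cluster(m))$k  # 2
#' @export
select_k <- function(dendrogram, min_gap = 0.1) {
  h <- dendrogram$height
  n <- length(h) + 1L
  if (n < 2) stop("need at least 2 leaves")
  if (length(h) == 1)
    return(list(k = if (h > 0) 2L else 1L, cut_height = h / 2, gap = NA_real_))
  dh <- diff(h)
  rel <- ifelse(h[-length(h)] > 0, dh / h[-length(h)],
                ifelse(dh > 0, Inf, 0))
  m <- which.max(rel)
  if (rel[m] <= min_gap)
    return(list(k = 1L, cut_height = max(h) + 1, gap = max(rel, 0)))
  list(k = n - m, cut_height = (h[m] + h[m + 1]) / 2, gap = rel[m])
}

#' PCA confirmation of an epitope grouping
#'
#' Centred principal component analysis of the competition profiles, with
#' the first up to three components, their explained-variance shares, and
#' a between/within separation score for a given grouping (mean pairwise
#' distance between group centroids over mean within-group distance to the
#' centroid).
#'
#' @param matrix normalised competition matrix (rows = profiles).
#' @param k number of groups (for the report only).
#' @param labels group label per row.
#' @return list of class `pca_confirmation`: `coordinates` (n x <=3),
#'   `variance_shares` (all components, non-increasing), `separation`,
#'   `k`, `labels`.
#' @export
pca_confirm <- function(matrix, k, labels) {
  m <- as.matrix(matrix)
  if (nrow(m) < 4) stop("need at least 4 profiles for PCA confirmation")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- min(3L, sum(pc$sdev > 1e-12))
  if (ncomp < 3) warning("profile matrix has rank < 3; returning ",
                         ncomp, " component(s)")
  coords <- pc$x[, seq_len(ncomp), drop = FALSE]

  centroids <- do.call(rbind, lapply(split(seq_len(nrow(m)), labels),
                                     function(i) colMeans(m[i, , drop = FALSE])))
  within <- mean(unlist(lapply(split(seq_len(nrow(m)), labels), function(i) {
    if (length(i) < 2) return(numeric(0))
    ctr <- colMeans(m[i, , drop = FALSE])
    sqrt(rowSums((m[i, , drop = FALSE] -
                    matrix(ctr, length(i), ncol(m), byrow = TRUE))^2))
  })))
  between <- if (nrow(centroids) > 1) mean(stats::dist(centroids)) else 0
  structure(list(coordinates = coords, variance_shares = shares,
                 separation = if (is.finite(within) && within > 0)
                   between / within else Inf,
                 k = k, labels = labels),
            class = "pca_confirmation")
}

#' Row-vs-column clustering agreement
#'
#' Clusters the rows and the columns (transposed matrix) independently at
#' a matched cluster count and reports the adjusted Rand index between the
#' two partitions. Values near 1 mean the binning does not depend on which
#' antibody was captured first.
#'
#' @param matrix normalised square competition matrix.
#' @param k cluster count; defaults to [select_k()] on the row dendrogram.
#' @return list with `agreement` (adjusted Rand index), `k`,
#'   `row_labels`, `col_labels`.
#' @export
transpose_check <- function(matrix, k = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  dr <- ward_cluster(m)
  if (is.null(k)) k <- select_k(dr)$k
  rl <- stats::cutree(stats::as.hclust(dr), k = k)
  cl <- stats::cutree(stats::as.hclust(ward_cluster(t(m))), k = k)
  list(agreement = mclust::adjustedRandIndex(rl, cl), k = k,
       row_labels = rl, col_labels = cl)
}

#' Detect asymmetric competition pairs
#'
#' Flags ordered pairs whose competition differs by more than `margin`
#' depending on which antibody was captured first versus pre-complexed
#' with the antigen — the signature of binders whose blocking depends on
#' complex preformation.
#'
#' @param matrix normalised square competition matrix.
#' @param margin minimum |value(i,j) - value(j,i)| to flag (default 0.3 on
#'   the normalised scale).
#' @return data.frame with columns `first`, `second`, `value_ij`,
#'   `value_ji`, `delta`, one row per flagged unordered pair (reported in
#'   the direction of the larger value).
#' @export
detect_asymmetry <- function(matrix, margin = 0.3) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  out <- list()
  for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):ncol(m)) {
    d <- m[i, j] - m[j, i]
    if (abs(d) > margin) {
      a <- if (d > 0) i else j; b <- if (d > 0) j else i
      out[[length(out) + 1L]] <-
        data.frame(first = ids[a], second = ids[b],
                   value_ij = m[a, b], value_ji = m[b, a],
                   delta = abs(d), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(first = character(0), second = character(0),
                      value_ij = numeric(0), value_ji = numeric(0),
                      delta = numeric(0)))
  do.call(rbind, out)
}

#' Bin antibodies into epitope groups
#'
#' End-to-end binning of a cross-competition matrix: row normalisation,
#' Ward clustering, gap-based (or manual) cluster-count selection, PCA
#' confirmation, transpose agreement and asymmetric-binder detection.
#'
#' @param matrix square competition matrix (raw ODs) or
#'   `competition_matrix`.
#' @param k manual cluster-count override; `NULL` (default) selects it
#'   with [select_k()].
#' @param margin asymmetry margin, see [detect_asymmetry()].
#' @param control optional no-competition control column, see
#'   [normalize_matrix()].
#' @return object of class `epitope_binning`: list with `k`, `labels`
#'   (group id per antibody), `dendrogram`, `normalized`, `pca`,
#'   `transpose_agreement`, `asymmetric_pairs`.
#' @examples
#' cm <- generate_competition(competition_config(seed = 5))
#' bins <- bin_epitopes(cm)
#' bins$k
#' @export
bin_epitopes <- function(matrix, k = NULL, margin = 0.3, control = NULL) {
  norm <- normalize_matrix(matrix, control = control)
  dendro <- ward_cluster(norm)
  sel <- if (is.null(k)) select_k(dendro) else list(k = as.integer(k))
  labels <- stats::cutree(stats::as.hclust(dendro), k = sel$k)
  pca <- if (nrow(norm) >= 4) pca_confirm(norm, sel$k, labels) else NULL
  structure(list(k = sel$k, labels = labels, dendrogram = dendro,
                 normalized = norm, pca = pca,
                 transpose_agreement = transpose_check(norm, k = sel$k),
                 asymmetric_pairs = detect_asymmetry(norm, margin = margin)),
            class = "epitope_binning")
}

#' @export
print.epitope_binning <- function(x, ...) {
  cat("Epitope binning:", length(x$labels), "antibodies in", x$k, "groups\n")
  print(table(group = x$labels))
  cat("row/column clustering agreement (ARI):",
      round(x$transpose_agreement$agreement, 3), "\n")
  if (nrow(x$asymmetric_pairs))
    cat(nrow(x$asymmetric_pairs), "asymmetric pair(s) flagged\n")
  invisible(x)
}

#' @describeIn bin_epitopes three-colour heatmap of the normalised matrix
#'   (low = strong competition) with the dendrogram ordering.
#' @param x an `epitope_binning` object.
#' @param ... ignored.
#' @export
plot.epitope_binning <- function(x, ...) {
  ord <- x$dendrogram$order
  m <- x$normalized[ord, ord]
  cols <- grDevices::colorRampPalette(c("green3", "black", "red3"))(31)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), t(m)[, rev(seq_len(nrow(m)))],
                  col = cols, axes = FALSE, xlab = "second antibody",
                  ylab = "first antibody",
                  main = "Cross-competition (green = competition)")
  invisible(x)
}
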