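# Synthetic pairwise cross-competition ELISA matrix.
#
# Entry (i, j) is the detection signal with antibody i captured first and
# antibody j pre-complexed with the antigen: LOW signal means j blocks i
# (competition, same epitope), HIGH signal means no competition. Planted
# epitope groups give same-group ordered pairs the low-OD law and
# different-group pairs the high-OD law; listed asymmetric pairs have one
# direction swapped, mimicking antibodies whose competition depends on
# which partner is pre-complexed with the antigen.

#' Competition simulation configuration
#'
#' @param n_antibodies number of antibodies (default 16).
#' @param n_groups number of planted epitope groups (default 6); sizes are
#'   as equal as possible.
#' @param within_mean,between_mean mean OD for same-group (competition,
#'   low) and different-group (no competition, high) ordered pairs.
#' @param noise_sd Gaussian OD noise sd added to every entry.
#' @param asymmetric_pairs integer matrix / 2-column structure of ordered
#'   antibody index pairs (i, j) whose (i, j) entry gets the opposite law.
#' @param seed integer RNG seed.
#' @return validated list of class `competition_config`.
#' @export
competition_config <- function(n_antibodies = 16, n_groups = 6,
                               within_mean = 0.15, between_mean = 1.0,
                               noise_sd = 0.15,
                               asymmetric_pairs = NULL, seed = 1) {
  if (n_groups > n_antibodies) stop("n_groups must be <= n_antibodies")
  if (n_groups < 1 || n_antibodies < 2) stop("need >= 2 antibodies, >= 1 group")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(asymmetric_pairs)) {
    asymmetric_pairs <- matrix(as.integer(asymmetric_pairs), ncol = 2)
    if (any(asymmetric_pairs < 1 | asymmetric_pairs > n_antibodies))
      stop("asymmetric_pairs reference invalid antibody indices")
  }
  structure(list(n_antibodies = as.integer(n_antibodies),
                 n_groups = as.integer(n_groups),
                 within_mean = within_mean, between_mean = between_mean,
                 noise_sd = noise_sd,
                 asymmetric_pairs = asymmetric_pairs,
                 seed = as.integer(seed)),
            class = "competition_config")
}

#' Generate a synthetic cross-competition matrix
#'
#' @param config a [competition_config()].
#' @return list of class `competition_matrix`: `values` (square matrix,
#'   rows = first-captured antibody, ODs clipped at 0), `antibody_ids`,
#'   and ground truth `true_groups` (group label per antibody) and
#'   `asymmetric_pairs`.
#' @examples
#' cm <- generate_competition(competition_config(seed = 5))
#' table(cm$true_groups)
#' @export
generate_competition <- function(config) {
  stopifnot(inherits(config, "competition_config"))
  set.seed(config$seed)
  n <- config$n_antibodies; k <- config$n_groups
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  groups <- rep(seq_len(k), times = sizes)
  same <- outer(groups, groups, "==")
  m <- ifelse(same, config$within_mean, config$between_mean)
  if (!is.null(config$asymmetric_pairs)) {
    for (r in seq_len(nrow(config$asymmetric_pairs))) {
      i <- config$asymmetric_pairs[r, 1]; j <- config$asymmetric_pairs[r, 2]
      m[i, j] <- if (same[i, j]) config$between_mean else config$within_mean
    }
  }
  m <- m + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
  m[m < 0] <- 0
  ids <- sprintf("ab%03d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  structure(list(values = m, antibody_ids = ids, true_groups = groups,
                 asymmetric_pairs = config$asymmetric_pairs),
            class = "competition_matrix")
}

#' @export
print.competition_matrix <- function(x, ...) {
  cat("Cross-competition matrix:", length(x$antibody_ids), "antibodies,",
      length(unique(x$true_groups)), "planted groups\n")
  invisible(x)
}
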