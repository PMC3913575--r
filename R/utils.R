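# Small shared helpers: rounding conventions, percentage formatting,
# partition agreement, input checks.

#' Round half away from zero
#'
#' Plate-report percentages use commercial ("half-up") rounding, not the
#' IEC 60559 half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(22.45, 1)  # 22.5
#' round_half_up(0.5, 0)    # 1
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a denominator
#'
#' @param n numerator count.
#' @param d denominator count.
#' @param digits decimal places kept (half-up rounding); funnel reports use
#'   1, repertoire accounting tables use 0.
#' @return numeric percentage on the 0-100 scale.
#' @examples
#' percent_of(978, 7644)            # 12.8
#' percent_of(227, 242, digits = 0) # 94
#' @export
percent_of <- function(n, d, digits = 1) {
  stopifnot(length(n) == length(d))
  if (any(d <= 0)) stop("denominator must be positive")
  round_half_up(100 * n / d, digits)
}

#' Rand index between two partitions
#'
#' Plain (unadjusted) Rand index: the fraction of object pairs on which two
#' partitions agree (both together or both apart). The adjusted version is
#' delegated to [mclust::adjustedRandIndex()].
#'
#' @param a,b partition label vectors of equal length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  s  <- function(x) sum(choose(x, 2))
  np <- choose(n, 2)
  same_a <- s(rowSums(tab)); same_b <- s(colSums(tab)); same_ab <- s(tab)
  (np + 2 * same_ab - same_a - same_b) / np
}

check_aa <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty string")
  bad <- setdiff(strsplit(seq, "")[[1]], .AA20)
  if (length(bad))
    stop(what, " contains non-standard residues: ", paste(unique(bad), collapse = ", "))
  invisible(seq)
}

# deterministic child seeds below 2^31, derived from one user seed
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}
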