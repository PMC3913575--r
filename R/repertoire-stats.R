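# Repertoire diversity and maturation statistics: CDR-H3 length
# distribution, replacement-mutation distributions per stratum, and
# Kyte-Doolittle hydropathy.
#
# Standard deviations default to the population form (n denominator);
# sample sds are also reported. Strata with fewer than two clones report
# their sd as NA, printed "nd", matching campaign report conventions.

sd_pop <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

strat_table <- function(values, data, strata) {
  if (is.null(strata) || !length(strata)) {
    key <- rep("all", length(values))
    keys <- data.frame(stratum = "all")
  } else {
    key <- do.call(paste, c(data[strata], sep = "|"))
    keys <- unique(data[strata])
  }
  rows <- lapply(split(seq_along(values), key), function(i) {
    v <- values[i]
    data.frame(n = length(v), min = min(v), max = max(v), mean = mean(v),
               sd = sd_pop(v),
               sd_sample = if (length(v) < 2) NA_real_ else stats::sd(v))
  })
  out <- do.call(rbind, rows)
  split_keys <- do.call(rbind, strsplit(rownames(out), "|", fixed = TRUE))
  if (!is.null(strata) && length(strata)) {
    colnames(split_keys) <- strata
    out <- cbind(as.data.frame(split_keys, stringsAsFactors = FALSE), out)
  }
  rownames(out) <- NULL
  out
}

#' CDR-H3 length statistics
#'
#' Histogram, mean and population sd of annotated CDR-H3 lengths, overall
#' and per stratum.
#'
#' @param clones `annotated_repertoire` (uses `cdr3_h_length` and
#'   `annotation_ok`).
#' @param strata character vector of metadata columns to stratify by
#'   (e.g. `c("animal", "bleed")`), or `NULL` for the overall summary.
#' @return object of class `repertoire_summary`: list with `histogram`
#'   (named counts by length), `mean`, `sd` (population), `sd_sample`, `n`
#'   and `by_stratum` (data.frame with n/min/max/mean/sd per stratum,
#'   sd `NA` when n < 2).
#' @export
cdr3_length_stats <- function(clones, strata = NULL) {
  stopifnot(nrow(clones) >= 1)
  ok <- if ("annotation_ok" %in% names(clones)) clones$annotation_ok
        else rep(TRUE, nrow(clones))
  cl <- clones[ok, , drop = FALSE]
  len <- cl$cdr3_h_length
  structure(list(histogram = table(factor(len, levels = min(len):max(len))),
                 mean = mean(len), sd = sd_pop(len),
                 sd_sample = if (length(len) < 2) NA_real_ else stats::sd(len),
                 n = length(len),
                 by_stratum = strat_table(len, cl, strata)),
            class = "repertoire_summary")
}

#' Replacement-mutation statistics per stratum
#'
#' Means, population sds and ranges of per-clone replacement counts,
#' stratified by any subset of animal, bleed, assigned germline and region
#' (framework vs CDR).
#'
#' @param clones `annotated_repertoire`.
#' @param strata metadata columns to stratify by; `"germline"` maps to the
#'   chain's assigned germline column.
#' @param chain `"vh"` or `"vl"`.
#' @param region `"v"` (default: FR1-FR3 + CDR1/2, the germline-templated
#'   load), `"total"` (adds CDR3 substitution columns), `"fr"` or `"cdr"`;
#'   `"split"` reports framework and CDR separately.
#' @return for a single region, a `repertoire_summary`; for
#'   `region = "split"` a named list with `fr` and `cdr` summaries.
#' @export
replacement_stats <- function(clones, strata = NULL, chain = c("vh", "vl"),
                              region = c("v", "total", "fr", "cdr", "split")) {
  chain <- match.arg(chain); region <- match.arg(region)
  ok <- if ("annotation_ok" %in% names(clones)) clones$annotation_ok
        else rep(TRUE, nrow(clones))
  cl <- clones[ok, , drop = FALSE]
  if (!is.null(strata)) {
    strata[strata == "germline"] <- paste0(chain, "_germline")
    stopifnot(all(strata %in% names(cl)))
  }
  one <- function(col) {
    v <- cl[[paste0(chain, "_repl_", col)]]
    structure(list(histogram = table(v), mean = mean(v), sd = sd_pop(v),
                   sd_sample = if (length(v) < 2) NA_real_ else stats::sd(v),
                   n = length(v), range = range(v),
                   by_stratum = strat_table(v, cl, strata)),
              class = "repertoire_summary")
  }
  if (region == "split") list(fr = one("fr"), cdr = one("cdr"))
  else one(region)
}

#' @export
print.repertoire_summary <- function(x, digits = 3, ...) {
  cat("n =", x$n, " mean =", round(x$mean, digits),
      " sd =", if (is.na(x$sd)) "nd" else round(x$sd, digits), "\n")
  bs <- x$by_stratum
  if (!is.null(bs) && nrow(bs) > 1) {
    show <- bs
    show$sd <- ifelse(is.na(bs$sd), "nd", format(round(bs$sd, digits)))
    show$sd_sample <- NULL
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn cdr3_length_stats histogram plot of the length (or
#'   replacement) distribution.
#' @param x a `repertoire_summary`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.repertoire_summary <- function(x, ...) {
  graphics::barplot(x$histogram, xlab = "value", ylab = "clones", ...)
  invisible(x)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean residue hydropathy of a sequence under a hydropathy scale
#' (Kyte-Doolittle by default).
#'
#' @param seq amino-acid sequence (standard 20-letter alphabet).
#' @param scale named numeric vector of per-residue hydropathy values.
#' @return numeric GRAVY score.
#' @examples
#' gravy("II")  # 4.5
#' gravy("RI")  # 0
#' @export
gravy <- function(seq, scale = .KYTE_DOOLITTLE) {
  check_aa(seq, "sequence")
  mean(scale[strsplit(seq, "")[[1]]])
}
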