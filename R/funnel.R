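# Multi-assay screening funnel: ordered gates over the plate-panel
# channels with the calibrated positivity thresholds, reported as counts
# and percentages of the conventional denominators (IgG-positive wells for
# binding and counterscreen gates, antigen binders for inhibition).

#' Screening-funnel threshold configuration
#'
#' Defaults are the campaign's calibrated cut-offs: rabbit IgG
#' > 0.013 ug/ml, human antigen binding > OD 0.195, human-Fc counterscreen
#' <= OD 0.125, cynomolgus > OD 0.184, murine > OD 0.164, biochemical
#' inhibition >= 40%, and a 0.02 ug/ml IgG floor for PCR eligibility.
#'
#' @param igg_pos IgG positivity threshold (ug/ml, exclusive).
#' @param hu_pos human antigen binding OD threshold (exclusive).
#' @param huFc_neg_max maximum tolerated human-Fc counterscreen OD
#'   (inclusive); wells above it are Fc binders and excluded.
#' @param cyno_pos,mu_pos cynomolgus / murine binding OD thresholds
#'   (exclusive).
#' @param inhibition_min minimum biochemical inhibition (%, inclusive).
#' @param pcr_igg_min IgG floor for selecting clones into the PCR workflow
#'   (ug/ml, inclusive).
#' @return list of class `funnel_config`.
#' @export
funnel_config <- function(igg_pos = 0.013, hu_pos = 0.195,
                          huFc_neg_max = 0.125, cyno_pos = 0.184,
                          mu_pos = 0.164, inhibition_min = 40,
                          pcr_igg_min = 0.02) {
  cfg <- list(igg_pos = igg_pos, hu_pos = hu_pos,
              huFc_neg_max = huFc_neg_max, cyno_pos = cyno_pos,
              mu_pos = mu_pos, inhibition_min = inhibition_min,
              pcr_igg_min = pcr_igg_min)
  if (!all(vapply(cfg, is.finite, logical(1))))
    stop("all funnel thresholds must be finite")
  structure(cfg, class = "funnel_config")
}

#' Percent inhibition from assay controls
#'
#' `100 * (positive - sample) / (positive - negative)`, unclipped. The
#' positive control contains all assay components but no antibody; the
#' negative control lacks the receptor.
#'
#' @param sample_od sample OD (vectorised).
#' @param positive_control,negative_control control ODs;
#'   `positive_control > negative_control` required.
#' @return percent inhibition (may fall outside \[0, 100\] through noise).
#' @examples
#' percent_inhibition(0.6, 1.0, 0.2)  # 50
#' @export
percent_inhibition <- function(sample_od, positive_control, negative_control) {
  if (!is.finite(positive_control) || !is.finite(negative_control) ||
      positive_control <= negative_control)
    stop("positive control must exceed negative control")
  100 * (positive_control - sample_od) / (positive_control - negative_control)
}

funnel_gate_rows <- function(counts) {
  with(counts, {
    rows <- list(
      c("total_wells", total, NA, NA),
      c("igg_positive", igg_pos, total, percent_of(igg_pos, total)),
      c("fc_binders_excluded", fc, igg_pos,
        if (is.na(fc)) NA else percent_of(fc, igg_pos)),
      c("hu_binders", hu, igg_pos, percent_of(hu, igg_pos)),
      c("cyno_binders", cyno, igg_pos, percent_of(cyno, igg_pos)),
      c("mu_binders", mu, igg_pos, percent_of(mu, igg_pos)),
      c("inhibitors", inhibitors, hu, percent_of(inhibitors, hu)))
    out <- data.frame(
      gate = vapply(rows, `[[`, character(1), 1),
      count = as.numeric(vapply(rows, `[[`, character(1), 2)),
      denominator = as.numeric(vapply(rows, `[[`, character(1), 3)),
      percent = as.numeric(vapply(rows, `[[`, character(1), 4)),
      stringsAsFactors = FALSE)
    out
  })
}

#' Apply the screening funnel
#'
#' Gates a well panel through the ordered screening funnel: IgG positivity,
#' human-Fc counterscreen exclusion, human/cynomolgus/murine antigen
#' binding, and biochemical inhibition. Binding and counterscreen gates are
#' reported as percentages of the IgG-positive wells, inhibition as a
#' percentage of the human-antigen binders; percentages use 1-decimal
#' half-up rounding. Alternatively a list of precomputed gate counts can be
#' supplied to reproduce a printed report's arithmetic.
#'
#' @param panel an `assay_panel` data.frame (see [generate_panel()] or
#'   [read_panel_csv()]), or `NULL` when `counts` is given.
#' @param config a [funnel_config()].
#' @param counts optional named list/vector with `total`, `igg_pos`, `hu`,
#'   `cyno`, `mu`, `inhibitors` and optionally `fc`; bypasses the panel.
#' @return object of class `funnel_report`: data.frame with one row per
#'   gate (`gate`, `count`, `denominator`, `percent`) plus attributes
#'   `avg_igg` (mean IgG over IgG-positive wells, panel input only),
#'   `n_pcr_eligible`, and `selection` (logical index of wells passing
#'   all binding + inhibition gates).
#' @examples
#' apply_funnel(counts = list(total = 7644, igg_pos = 978, hu = 220,
#'                            cyno = 201, mu = 56, inhibitors = 36))
#' @export
apply_funnel <- function(panel = NULL, config = funnel_config(),
                         counts = NULL) {
  stopifnot(inherits(config, "funnel_config"))
  if (is.null(counts)) {
    needed <- c("igg", "od_hu", "od_cyno", "od_mu", "od_hufc",
                "inhib_biochem")
    missing_ch <- setdiff(needed, names(panel))
    if (length(missing_ch))
      stop("panel is missing channels: ", paste(missing_ch, collapse = ", "))
    igg_pos <- panel$igg > config$igg_pos
    fc <- igg_pos & panel$od_hufc > config$huFc_neg_max
    eligible <- igg_pos & !fc
    hu <- eligible & panel$od_hu > config$hu_pos
    cyno <- hu & panel$od_cyno > config$cyno_pos
    mu <- hu & panel$od_mu > config$mu_pos
    inh <- hu & panel$inhib_biochem >= config$inhibition_min
    counts <- list(total = nrow(panel), igg_pos = sum(igg_pos),
                   fc = sum(fc), hu = sum(hu), cyno = sum(cyno),
                   mu = sum(mu), inhibitors = sum(inh))
    avg_igg <- mean(panel$igg[igg_pos])
    pcr <- sum(inh & panel$igg >= config$pcr_igg_min)
    selection <- inh
  } else {
    counts <- as.list(counts)
    if (is.null(counts$fc)) counts$fc <- NA
    avg_igg <- NA_real_; pcr <- NA_integer_; selection <- NULL
  }
  stopifnot(all(c("total", "igg_pos", "hu", "cyno", "mu", "inhibitors")
                %in% names(counts)))
  out <- funnel_gate_rows(counts)
  structure(out, avg_igg = avg_igg, n_pcr_eligible = pcr,
            selection = selection, config = config,
            class = c("funnel_report", "data.frame"))
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel report\n")
  df <- as.data.frame(x)
  df$percent <- ifelse(is.na(df$percent), "", sprintf("%.1f", df$percent))
  df$denominator <- ifelse(is.na(df$denominator), "", df$denominator)
  print(df, row.names = FALSE)
  if (!is.na(attr(x, "avg_igg")))
    cat(sprintf("average IgG over IgG-positive wells: %.3f ug/ml\n",
                attr(x, "avg_igg")))
  if (!is.na(attr(x, "n_pcr_eligible")))
    cat("PCR-eligible selected wells:", attr(x, "n_pcr_eligible"), "\n")
  invisible(x)
}

#' Squared correlation above an inhibition cut-off
#'
#' Squared Pearson correlation between two paired percent-inhibition
#' readouts, restricted to pairs whose first coordinate reaches the
#' cut-off. Sign-blind by construction (a perfect negative relation also
#' gives RSq 1).
#'
#' @param x,y equal-length paired percentage vectors (e.g. biochemical and
#'   cellular inhibition).
#' @param cutoff minimum `x` for a pair to enter (inclusive).
#' @return list with `rsq` and `n` (pairs used).
#' @export
threshold_correlation <- function(x, y, cutoff) {
  stopifnot(length(x) == length(y))
  keep <- which(x >= cutoff)
  if (length(keep) < 3)
    stop("fewer than 3 pairs above the cut-off")
  list(rsq = stats::cor(x[keep], y[keep])^2, n = length(keep))
}
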