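# Synthetic primary-screening plate panel.
#
# Emulates the multi-channel well measurements a B-cell culture campaign
# produces: IgG concentration, optical densities for human/cynomolgus/
# murine antigen binding and the human-Fc counterscreen, and biochemical
# plus cellular percent inhibition. Negative-well ODs follow a Johnson SU
# background law; binder wells add a log-normal OD shift on top. Rates
# default to the observed campaign: 12.8% of wells IgG-positive, 22.5% of
# those antigen binders, 14.2% Fc binders, cyno/murine cross-reactivity
# among binders, 16.4% of binders inhibitory. Ground-truth labels are kept
# so gating can be scored.

#' Panel simulation configuration
#'
#' @param n_wells number of wells (default 7644, one campaign's scale).
#' @param background_law Johnson SU parameters (named `gamma`, `delta`,
#'   `xi`, `lambda`) for negative-well OD; the default law has its 99%
#'   quantile near OD 0.19.
#' @param positive_fraction fraction of IgG-positive wells that bind the
#'   antigen.
#' @param positive_shift log-normal OD shift law for binder wells, named
#'   `meanlog`, `sdlog`.
#' @param igg_law log-normal law (`meanlog`, `sdlog`) for the IgG
#'   concentration of secreting wells, in ug/ml.
#' @param inhibitor_fraction fraction of antigen binders that inhibit the
#'   receptor-ligand interaction.
#' @param igg_positive_fraction fraction of wells that secrete IgG.
#' @param fc_binder_fraction fraction of IgG-positive wells binding the
#'   human-Fc counterscreen.
#' @param cyno_cross_fraction,mu_cross_fraction fractions of antigen
#'   binders cross-reactive with the cynomolgus resp. murine ortholog.
#' @param seed integer RNG seed.
#' @return validated list of class `panel_config`.
#' @export
panel_config <- function(n_wells = 7644,
                         background_law = c(gamma = -1, delta = 1.5,
                                            xi = 0.05, lambda = 0.03),
                         positive_fraction = 0.225,
                         positive_shift = c(meanlog = log(0.8), sdlog = 0.4),
                         igg_law = c(meanlog = log(0.55), sdlog = 1),
                         inhibitor_fraction = 0.164,
                         igg_positive_fraction = 0.128,
                         fc_binder_fraction = 0.142,
                         cyno_cross_fraction = 0.91,
                         mu_cross_fraction = 0.25,
                         seed = 1) {
  fr <- c(positive_fraction, inhibitor_fraction, igg_positive_fraction,
          fc_binder_fraction, cyno_cross_fraction, mu_cross_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  check_su_par(background_law["gamma"], background_law["delta"],
               background_law["xi"], background_law["lambda"])
  structure(list(n_wells = as.integer(n_wells),
                 background_law = background_law,
                 positive_fraction = positive_fraction,
                 positive_shift = positive_shift,
                 igg_law = igg_law,
                 inhibitor_fraction = inhibitor_fraction,
                 igg_positive_fraction = igg_positive_fraction,
                 fc_binder_fraction = fc_binder_fraction,
                 cyno_cross_fraction = cyno_cross_fraction,
                 mu_cross_fraction = mu_cross_fraction,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Generate a synthetic screening panel
#'
#' @param config a [panel_config()].
#' @return data.frame of class `assay_panel`, one row per well: `well_id`,
#'   channels `igg` (ug/ml), `od_hu`, `od_cyno`, `od_mu`, `od_hufc` (OD,
#'   clipped at 0), `inhib_biochem`, `inhib_cellular` (percent), and
#'   ground-truth labels `is_igg_pos`, `is_binder`, `is_fc_binder`,
#'   `is_cyno`, `is_mu`, `is_inhibitor`.
#' @examples
#' p <- generate_panel(panel_config(n_wells = 500, seed = 1))
#' mean(p$is_igg_pos)
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  n <- config$n_wells
  bg <- config$background_law
  rbg <- function(m) pmax(0, rjohnson_su(m, bg["gamma"], bg["delta"],
                                         bg["xi"], bg["lambda"]))
  shift <- function(m) stats::rlnorm(m, config$positive_shift["meanlog"],
                                     config$positive_shift["sdlog"])

  is_igg <- stats::rbinom(n, 1, config$igg_positive_fraction) == 1
  is_binder <- is_igg & stats::rbinom(n, 1, config$positive_fraction) == 1
  is_fc <- is_igg & stats::rbinom(n, 1, config$fc_binder_fraction) == 1
  is_cyno <- is_binder & stats::rbinom(n, 1, config$cyno_cross_fraction) == 1
  is_mu <- is_binder & stats::rbinom(n, 1, config$mu_cross_fraction) == 1
  is_inh <- is_binder & stats::rbinom(n, 1, config$inhibitor_fraction) == 1

  igg <- ifelse(is_igg,
                stats::rlnorm(n, config$igg_law["meanlog"],
                              config$igg_law["sdlog"]),
                stats::runif(n, 0, 0.012))
  od_hu <- rbg(n) + ifelse(is_binder, shift(n), 0)
  od_cyno <- rbg(n) + ifelse(is_cyno, shift(n), 0)
  od_mu <- rbg(n) + ifelse(is_mu, shift(n), 0)
  od_hufc <- rbg(n) + ifelse(is_fc, shift(n), 0)

  # inhibition: non-binders hover around 0%, binders around 10% unless
  # inhibitory (40-100%); cellular agrees tightly only above ~90%
  inhib <- ifelse(is_inh, stats::runif(n, 40, 100),
                  ifelse(is_binder, stats::rnorm(n, 10, 12),
                         stats::rnorm(n, 0, 8)))
  cellular <- ifelse(inhib > 90, inhib + stats::rnorm(n, 0, 1),
                     0.45 * inhib + stats::rnorm(n, 0, 18))
  cellular <- pmin(pmax(cellular, -50), 150)

  structure(
    data.frame(well_id = sprintf("w%05d", seq_len(n)),
               igg = igg, od_hu = od_hu, od_cyno = od_cyno, od_mu = od_mu,
               od_hufc = od_hufc,
               inhib_biochem = inhib, inhib_cellular = cellular,
               is_igg_pos = is_igg, is_binder = is_binder,
               is_fc_binder = is_fc, is_cyno = is_cyno, is_mu = is_mu,
               is_inhibitor = is_inh,
               stringsAsFactors = FALSE),
    class = c("assay_panel", "data.frame"))
}
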