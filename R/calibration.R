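# Assay-positivity threshold calibration: upper-tail outlier trimming,
# Johnson SU fit, 99% quantile. The three steps mirror how screening
# cut-offs are set from the background signal of a whole plate campaign:
# strong positives "stick out" of the negative-well background and must be
# trimmed before the background law is fitted.

#' Remove upper-tail outliers
#'
#' Iterative upper-tail trimming: points above
#' `median(x) + k * mad(x)` are removed, the rule is re-evaluated once on
#' the retained points, and the union of both removal sets is reported.
#' `mad()` uses the usual 1.4826 consistency constant. A zero-spread guard
#' removes nothing when the MAD is zero (e.g. constant input).
#'
#' Only the upper tail is trimmed: screening positives can only inflate
#' optical densities, never deflate them.
#'
#' @param values numeric vector, `length(values) >= 20`.
#' @param k multiplier on the MAD (default 6).
#' @return list with `retained` (values kept), `removed` (integer indices
#'   into `values` of removed points) and `cutoffs` (the per-pass cut-off
#'   values), class `outlier_trim`.
#' @examples
#' x <- c(rnorm(100), 50, 60)
#' remove_outliers(x)$removed  # the two injected points
#' @export
remove_outliers <- function(values, k = 6) {
  if (length(values) < 20) stop("need at least 20 values for outlier analysis")
  if (any(!is.finite(values))) stop("values must be finite")
  removed <- integer(0)
  cutoffs <- numeric(0)
  keep <- seq_along(values)
  for (pass in 1:2) {
    x <- values[keep]
    spread <- stats::mad(x)
    if (spread == 0) break  # zero-spread guard
    cut <- stats::median(x) + k * spread
    cutoffs <- c(cutoffs, cut)
    out <- keep[values[keep] > cut]
    if (!length(out)) break
    removed <- c(removed, out)
    keep <- setdiff(keep, out)
  }
  structure(list(retained = values[keep], removed = sort(removed),
                 cutoffs = cutoffs, k = k, n = length(values)),
            class = "outlier_trim")
}

#' @export
print.outlier_trim <- function(x, ...) {
  cat("Upper-tail outlier trim (k =", x$k, "): removed",
      length(x$removed), "of", x$n, "values\n")
  invisible(x)
}

#' Calibrate an assay-positivity threshold
#'
#' Composition of the three calibration steps: [remove_outliers()] on the
#' raw channel values, [fit_johnson_su()] on the retained background, and
#' the fitted 99% quantile as the threshold. Because the trim imposes a
#' known upper cut-off on the retained sample, the fit uses the
#' right-truncated likelihood at that cut-off; otherwise the trimmed tail
#' would drag the fitted quantile down. The returned audit record
#' keeps the sorted sample so that the threshold can be checked visually
#' against the sharp kink where positives depart from the background
#' (see the `plot` method).
#'
#' @param values numeric channel measurements (one plate campaign's wells).
#' @param k outlier-trim MAD multiplier, passed to [remove_outliers()].
#' @param quantile_level threshold quantile (default 0.99).
#' @return object of class `threshold_calibration`: list with `threshold`,
#'   `fit` (a [fit_johnson_su()] object), `trim` (the outlier audit) and
#'   `sorted` (sorted input values).
#' @examples
#' set.seed(7)
#' bg <- rjohnson_su(2000, -1, 1.5, 0.05, 0.03)
#' cal <- calibrate_threshold(bg)
#' cal$threshold
#' @export
calibrate_threshold <- function(values, k = 6, quantile_level = 0.99) {
  if (!length(values)) stop("no values supplied")
  trim <- remove_outliers(values, k = k)
  upper <- if (length(trim$cutoffs)) min(trim$cutoffs) else NULL
  fit <- fit_johnson_su(trim$retained, quantile_level = quantile_level,
                        upper = upper)
  structure(list(threshold = fit$threshold, fit = fit, trim = trim,
                 sorted = sort(values)),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, digits = 4, ...) {
  cat("Assay threshold calibration\n")
  cat("  outliers removed:", length(x$trim$removed), "of", x$trim$n, "\n")
  cat(sprintf("  %.0f%% quantile threshold: %s\n",
              100 * x$fit$quantile_level,
              format(x$threshold, digits = digits)))
  invisible(x)
}

#' @describeIn calibrate_threshold sorted-sample diagnostic plot; the
#'   threshold line should sit at the kink where positives leave the
#'   background.
#' @param x a `threshold_calibration` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.threshold_calibration <- function(x, ...) {
  graphics::plot(seq_along(x$sorted), x$sorted, type = "l",
                 xlab = "sorted well rank", ylab = "signal",
                 main = "Sorted sample vs calibrated threshold", ...)
  graphics::abline(h = x$threshold, col = "red3", lty = 2)
  invisible(x)
}
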