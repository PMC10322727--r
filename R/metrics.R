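#' Replicate-level performance summary of an estimator
#'
#' Aggregates per-replicate log odds ratio estimates against the known
#' full-population value: mean, bias (mean minus truth), percent bias,
#' empirical standard error (sample standard deviation, denominator n - 1)
#' and Monte Carlo error (empirical SE divided by the square root of the
#' number of replicates used).
#'
#' @param estimates per-replicate log OR estimates (length >= 2).
#' @param truth full-population log OR.
#' @return An object of class `scenario_summary`: list with `n_sim_used`,
#'   `mean_log_or`, `bias`, `percent_bias`, `empirical_se`, `mc_error`.
#' @examples
#' summarise_replicates(c(0.3, 0.5), truth = 0.405)
#' @export
summarise_replicates <- function(estimates, truth) {
  stopifnot(length(estimates) >= 2L, is.finite(truth))
  n <- length(estimates)
  m <- mean(estimates)
  s <- stats::sd(estimates)
  if (truth == 0) stop("percent bias undefined: truth is 0")
  structure(list(n_sim_used = n, mean_log_or = m, bias = m - truth,
                 percent_bias = 100 * (m - truth) / truth,
                 empirical_se = s, mc_error = s / sqrt(n)),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf(
    "Scenario summary over %d replicates: mean log OR %.4f, bias %.4f (%.2f%%), empirical SE %.4f, MC error %.4f\n",
    x$n_sim_used, x$mean_log_or, x$bias, x$percent_bias, x$empirical_se,
    x$mc_error))
  invisible(x)
}

#' Monte Carlo error bar half-width
#'
#' 1.96 times the Monte Carlo error, the half-width of the interval used to
#' display simulation uncertainty around a mean percent bias or mean
#' estimate.
#'
#' @param summary a [summarise_replicates()] result.
#' @return Numeric half-width.
#' @export
error_bar <- function(summary) {
  stopifnot(inherits(summary, "scenario_summary"))
  1.96 * summary$mc_error
}

#' Percent gain in precision of MI over complete-case analysis
#'
#' `100 * (se_cc / se_mi - 1)`: the complete-case standard error divided by
#' the MI standard error, expressed as a percent increase in precision
#' (so 24% means the complete-case SE is 1.24 times the MI SE). Losses come
#' out negative and are reported as such, never clipped.
#'
#' @param se_cc complete-case standard error (> 0).
#' @param se_mi multiple-imputation standard error (> 0).
#' @return Percent gain (numeric).
#' @examples
#' precision_gain(1.24, 1)  # 24
#' @export
precision_gain <- function(se_cc, se_mi) {
  stopifnot(se_cc > 0, se_mi > 0)
  100 * (se_cc / se_mi - 1)
}
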