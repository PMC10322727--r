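#' Default configuration of the factorial simulation study
#'
#' The reference design: Factor 1 (fraction of missing outcome data)
#' 20/40/60/80%; Factor 2 (auxiliary sensitivity) 25%/75%; Factor 3
#' (exposure-by-outcome interaction in the selection model) no/yes; Factor 4
#' (fraction of the auxiliary missing) 0/25%, with the nonzero Factor-4
#' block run only at sensitivity 75% and interaction present. Cohorts of
#' 10,000, 1,000 replicates, 100 imputations, burn-in 20; generator targets
#' prevalence 15%, log OR 0.405, exposure prevalence 25%, auxiliary
#' specificity 97.5%; selection mechanism observation OR 0.75 per SD
#' (logit link).
#'
#' @return A nested list of configuration values (see
#'   [read_study_config()] for the YAML equivalent).
#' @export
default_study_config <- function() {
  list(
    n = 10000L, n_sim = 1000L, m = 100L, burn_in = 20L, seed = 1L,
    strict = TRUE,
    population = list(prev = 0.15, log_or = 0.405, pi_x = 0.25,
                      dicho = "threshold"),
    mechanism = list(gy_or = 0.75, link = "logit"),
    aux = list(specificity = 0.975),
    factors = list(frac_missing = c(0.2, 0.4, 0.6, 0.8),
                   sensitivity = c(0.25, 0.75),
                   interaction = c(FALSE, TRUE),
                   frac_missing_aux = c(0, 0.25)),
    factor4_fixed = list(sensitivity = 0.75, interaction = TRUE)
  )
}

#' Read a study configuration from YAML
#'
#' Loads a YAML file whose keys mirror [default_study_config()] and merges
#' it over the defaults (missing keys keep their default values).
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_study_config(), cfg)
}

#' Expand a configuration into the factorial scenario list
#'
#' Builds the deterministic scenario table: the full cross of Factors 1-3
#' with a fully observed auxiliary, followed by one block per nonzero
#' Factor-4 level in which only Factor 1 varies and Factors 2-3 are fixed
#' (`factor4_fixed`, sensitivity 75% and interaction present by default).
#' Within each block Factor 1 varies fastest, then Factor 2, then Factor 3.
#' The reference configuration expands to exactly 20 scenarios. Under
#' `strict = TRUE`, a nonzero Factor-4 scenario without the interaction is a
#' validation error (no such row exists in the reference design).
#'
#' @param config a configuration list (default [default_study_config()]).
#' @return An object of class `study_design`: list with `scenarios` (data
#'   frame with `scenario_id`, `factor1` fraction missing outcome, `factor2`
#'   sensitivity, `factor3` interaction, `factor4` fraction missing
#'   auxiliary) and `config`.
#' @examples
#' nrow(expand_design()$scenarios)  # 20
#' @export
expand_design <- function(config = default_study_config()) {
  f <- config$factors
  stopifnot(length(f$frac_missing) >= 1, all(f$frac_missing > 0),
            all(f$frac_missing < 1), length(f$sensitivity) >= 1,
            is.logical(f$interaction) || all(f$interaction %in% c(0, 1)))
  f$interaction <- as.logical(f$interaction)
  base <- expand.grid(factor1 = f$frac_missing, factor2 = f$sensitivity,
                      factor3 = f$interaction, KEEP.OUT.ATTRS = FALSE)
  base$factor4 <- 0
  blocks <- list(base)
  for (f4 in setdiff(f$frac_missing_aux, 0)) {
    stopifnot(f4 > 0, f4 < 1)
    blk <- data.frame(factor1 = f$frac_missing,
                      factor2 = config$factor4_fixed$sensitivity,
                      factor3 = as.logical(config$factor4_fixed$interaction),
                      factor4 = f4)
    blocks <- c(blocks, list(blk))
  }
  scen <- do.call(rbind, blocks)
  if (isTRUE(config$strict) && any(scen$factor4 > 0 & !scen$factor3))
    stop("strict design: nonzero auxiliary missingness requires the ",
         "interaction mechanism")
  scen <- cbind(scenario_id = seq_len(nrow(scen)), scen)
  structure(list(scenarios = scen, config = config), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Factorial study design: %d scenarios (n_sim = %d, m = %d)\n",
              nrow(x$scenarios), x$config$n_sim, x$config$m))
  print(x$scenarios, row.names = FALSE)
  invisible(x)
}

# build the scenario_spec for one design row
.spec_for_row <- function(row, config, pop) {
  miss <- default_missingness(pop, row$factor1,
                              interaction = row$factor3,
                              gy_or = config$mechanism$gy_or,
                              link = config$mechanism$link)
  sp <- scenario_spec(n = config$n, n_sim = config$n_sim, m = config$m,
                      frac_missing = row$factor1,
                      sensitivity = row$factor2,
                      interaction = row$factor3,
                      frac_missing_aux = row$factor4,
                      seed = config$seed, population = pop,
                      missingness = miss, burn_in = config$burn_in,
                      scenario_id = row$scenario_id)
  sp$aux <- aux_model(row$factor2,
                      specificity = config$aux$specificity,
                      frac_missing = row$factor4)
  sp
}

#' Run one scenario: replicate loop with CC and MI estimation
#'
#' Draws `n_sim` replicate cohorts, imposes outcome (and, where configured,
#' auxiliary) missingness, and computes the complete-case and
#' multiple-imputation exposure estimates for each. Replicates whose fits
#' fail or do not converge are logged, excluded and counted, never fatal.
#'
#' @param spec a [scenario_spec()].
#' @param truth full-population log OR (for the summaries).
#' @param methods subset of `c("cc", "mi")`.
#' @param verbose print per-replicate failures as they happen?
#' @return A list with per-method estimate vectors, mean FMI, failure count
#'   and the [summarise_replicates()] summaries.
#' @export
run_scenario <- function(spec, truth = full_log_or(spec$population),
                         methods = c("cc", "mi"), verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  cc <- mi <- fmi <- rep(NA_real_, spec$n_sim)
  failures <- 0L
  for (r in seq_len(spec$n_sim)) {
    res <- tryCatch({
      coh <- draw_cohort(spec, replicate = r)
      coh <- impose_missingness(coh)
      if (spec$frac_missing_aux > 0) coh <- impose_aux_missingness(coh)
      out <- list()
      if ("cc" %in% methods) {
        f <- complete_case_estimate(coh)
        if (!f$converged) stop("complete-case fit: ", f$message)
        out$cc <- f$estimate
      }
      if ("mi" %in% methods) {
        p <- mi_estimate(coh)
        out$mi <- p$qbar
        out$fmi <- p$fmi
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (verbose) message("replicate ", r, " failed: ",
                           conditionMessage(res))
    } else {
      if (!is.null(res$cc)) cc[r] <- res$cc
      if (!is.null(res$mi)) { mi[r] <- res$mi; fmi[r] <- res$fmi }
    }
  }
  # fewer than two usable replicates: report an all-NA summary (with the
  # usable count) instead of failing the whole study
  summarise_or_na <- function(est) {
    if (length(est) >= 2L) summarise_replicates(est, truth)
    else structure(list(n_sim_used = length(est), mean_log_or = NA_real_,
                        bias = NA_real_, percent_bias = NA_real_,
                        empirical_se = NA_real_, mc_error = NA_real_),
                   class = "scenario_summary")
  }
  out <- list(failures = failures, n_sim = spec$n_sim)
  if ("cc" %in% methods) {
    out$cc <- cc[!is.na(cc)]
    out$summary_cc <- summarise_or_na(out$cc)
  }
  if ("mi" %in% methods) {
    out$mi <- mi[!is.na(mi)]
    out$mean_fmi <- if (any(!is.na(fmi))) mean(fmi, na.rm = TRUE) else NA_real_
    out$summary_mi <- summarise_or_na(out$mi)
  }
  out
}

#' Run the full factorial simulation study
#'
#' Executes every scenario of a [expand_design()] design in order and
#' returns one row per scenario and method. Replicates are seeded from
#' (seed, scenario id, replicate, stage), so the result table is fully
#' determined by the configuration: identical config and seed give an
#' identical table.
#'
#' @param design a `study_design` (default: the reference design).
#' @param n_sim,m,seed optional overrides of the design's configuration
#'   (e.g. a desk-scale `n_sim = 200, m = 20` run).
#' @param methods subset of `c("cc", "mi")`.
#' @param verbose print progress per scenario?
#' @return A data frame with columns `scenario_id`, `factor1`..`factor4`,
#'   `method`, `n_sim_used`, `mean_log_or`, `bias`, `percent_bias`,
#'   `empirical_se`, `mc_error`, `mean_fmi`, `precision_gain_pct`,
#'   `failure_rate`.
#' @export
run_study <- function(design = expand_design(), n_sim = NULL, m = NULL,
                      seed = NULL, methods = c("cc", "mi"),
                      verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  config <- design$config
  if (!is.null(n_sim)) config$n_sim <- as.integer(n_sim)
  if (!is.null(m)) config$m <- as.integer(m)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  pop <- calibrate_dichotomisation(target_prev = config$population$prev,
                                   target_log_or = config$population$log_or,
                                   pi_x = config$population$pi_x,
                                   kind = config$population$dicho)
  truth <- full_log_or(pop)
  rows <- list()
  for (i in seq_len(nrow(design$scenarios))) {
    row <- design$scenarios[i, ]
    if (verbose)
      message(sprintf("scenario %d/%d (missing %.0f%%, sens %.0f%%, %s%s)",
                      i, nrow(design$scenarios), 100 * row$factor1,
                      100 * row$factor2,
                      if (row$factor3) "interaction" else "no interaction",
                      if (row$factor4 > 0)
                        sprintf(", aux %.0f%% missing", 100 * row$factor4)
                      else ""))
    spec <- .spec_for_row(row, config, pop)
    res <- run_scenario(spec, truth, methods = methods, verbose = verbose)
    fr <- res$failures / res$n_sim
    mk <- function(method, s, mean_fmi = NA_real_, gain = NA_real_) {
      data.frame(row, method = method, n_sim_used = s$n_sim_used,
                 mean_log_or = s$mean_log_or, bias = s$bias,
                 percent_bias = s$percent_bias,
                 empirical_se = s$empirical_se, mc_error = s$mc_error,
                 mean_fmi = mean_fmi, precision_gain_pct = gain,
                 failure_rate = fr)
    }
    if ("cc" %in% methods) rows <- c(rows, list(mk("cc", res$summary_cc)))
    if ("mi" %in% methods) {
      gain <- if ("cc" %in% methods &&
                  isTRUE(res$summary_cc$empirical_se > 0) &&
                  isTRUE(res$summary_mi$empirical_se > 0))
        precision_gain(res$summary_cc$empirical_se,
                       res$summary_mi$empirical_se) else NA_real_
      rows <- c(rows, list(mk("mi", res$summary_mi, res$mean_fmi, gain)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simple percent-bias chart of study results
#'
#' Base-graphics plot of mean percent bias against the fraction of missing
#' outcome data, one line per (method, sensitivity) with 1.96 x Monte Carlo
#' error bars.
#'
#' @param results a [run_study()] result (typically filtered to one
#'   Factor-3/Factor-4 stratum).
#' @param main plot title.
#' @return Invisibly, the plotted data.
#' @export
plot_percent_bias <- function(results, main = "Percent bias in log OR") {
  stopifnot(all(c("factor1", "percent_bias", "mc_error", "method")
                %in% names(results)))
  grp <- interaction(results$method, results$factor2, drop = TRUE)
  half <- 1.96 * 100 * results$mc_error / abs(results$mean_log_or -
                                              results$bias)
  ylim <- range(results$percent_bias - half, results$percent_bias + half)
  plot(NULL, xlim = range(results$factor1), ylim = ylim,
       xlab = "fraction of missing outcome data",
       ylab = "mean percent bias in log OR", main = main)
  cols <- seq_along(levels(grp))
  for (i in seq_along(levels(grp))) {
    sub <- results[grp == levels(grp)[i], ]
    sub <- sub[order(sub$factor1), ]
    h <- half[grp == levels(grp)[i]][order(sub$factor1)]
    graphics::lines(sub$factor1, sub$percent_bias, type = "b", col = cols[i])
    graphics::arrows(sub$factor1, sub$percent_bias - h, sub$factor1,
                     sub$percent_bias + h, angle = 90, code = 3,
                     length = 0.03, col = cols[i])
  }
  graphics::legend("topleft", legend = levels(grp), col = cols, lty = 1,
                   bty = "n")
  invisible(results)
}
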